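# Coevolution-contact satisfaction scoring against the assembled scene:
# line widths grow with residue-residue distance (thin = satisfied).

#' Score predicted residue contacts against a scene
#'
#' Each contact resolves to one bead per residue (sidechain bead if present,
#' else backbone) in the scene's world coordinates. The display width is
#' `w_min + slope * max(0, d - d_sat)` so satisfied contacts stay thin, and
#' a contact is satisfied when `d <= d_sat`.
#'
#' @param contacts a [read_contact_table()] result (or data.frame with its
#'   columns).
#' @param scene a [mol_scene()] whose molecules carry bead models.
#' @param d_sat satisfaction cutoff, Angstrom (default 8, the usual
#'   coevolution-contact convention between sidechain centres).
#' @param w_min,slope width mapping parameters (display units, units/A).
#' @return list of class `contact_report`: `per_contact` data.frame
#'   (`chain_a`, `res_a`, `chain_b`, `res_b`, `tier`, `distance`, `width`,
#'   `satisfied`), ordered high, intermediate, low; `summary` fraction
#'   satisfied per tier.
#' @export
score_contacts <- function(contacts, scene, d_sat = 8, w_min = 1,
                           slope = 0.25) {
  stopifnot(inherits(scene, "mol_scene"))
  tab <- scene$table
  resolve <- function(chain, resno) {
    hit <- tab[tab$chain == chain & tab$resno == resno, , drop = FALSE]
    if (!nrow(hit))
      stop(sprintf("contact residue %s:%d not resolvable in the scene",
                   chain, resno))
    sc <- hit[hit$kind == "sidechain", , drop = FALSE]
    pick <- if (nrow(sc)) sc[1, ] else hit[1, ]
    c(pick$x, pick$y, pick$z)
  }
  n <- nrow(contacts)
  distance <- numeric(n)
  for (i in seq_len(n)) {
    pa <- resolve(contacts$chain_a[i], contacts$res_a[i])
    pb <- resolve(contacts$chain_b[i], contacts$res_b[i])
    distance[i] <- sqrt(sum((pa - pb)^2))
  }
  per <- data.frame(contacts[, c("chain_a", "res_a", "chain_b", "res_b",
                                 "tier")],
                    distance = distance,
                    width = w_min + slope * pmax(0, distance - d_sat),
                    satisfied = distance <= d_sat,
                    stringsAsFactors = FALSE)
  per <- per[order(match(per$tier, .contact_tiers), per$distance), ,
             drop = FALSE]
  rownames(per) <- NULL
  summary <- vapply(.contact_tiers, function(tr) {
    sel <- per$tier == tr
    if (!any(sel)) NA_real_ else mean(per$satisfied[sel])
  }, numeric(1))
  structure(list(per_contact = per, summary = summary, d_sat = d_sat),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("contact_report: %d contacts, satisfied at %g A:\n",
              nrow(x$per_contact), x$d_sat))
  for (tr in names(x$summary))
    if (!is.na(x$summary[tr]))
      cat(sprintf("  %-12s %.0f%%\n", tr, 100 * x$summary[tr]))
  invisible(x)
}
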