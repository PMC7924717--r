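# Residue-grained bead representation: one bead at the alpha carbon plus one
# at the sidechain centroid (glycine: alpha-carbon bead only), with radii
# proportional to the cube root of tabulated residue volumes.

.volume_env <- new.env(parent = emptyenv())

#' Residue volume / electron-count table
#'
#' Loads the bundled table of mean residue volumes (Angstrom^3) and electron
#' counts, or a user-supplied replacement in the same two-plus-column TSV
#' layout (`resname`, `volume_A3`, `electrons`).
#'
#' @param path optional path to an alternative table.
#' @return data.frame with columns `resname`, `volume_A3`, `electrons`.
#' @export
residue_volume_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.volume_env$table)) return(.volume_env$table)
    path <- system.file("extdata", "residue_volumes.tsv", package = "molscene")
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("resname", "volume_A3", "electrons"),
                           stringsAsFactors = FALSE)
  if (is.null(.volume_env$table)) .volume_env$table <- tab
  tab
}

#' Residue bead radius from tabulated volume
#'
#' The bead radius is the cube root of the residue's mean volume, times a
#' global scale factor. The raw cube roots (about 3.9-6.1 Angstrom) are
#' proportional sizes, not packing radii: at the 3.8 Angstrom alpha-carbon
#' spacing they would inter-penetrate, so the default display/collision
#' scale is 0.5 while `scale_factor = 1` returns the raw cube root.
#'
#' @param resname 3-letter residue code(s).
#' @param scale_factor multiplicative factor on the cube root, default 0.5.
#' @param table optional volume table (see [residue_volume_table()]).
#' @return radius (Angstrom), vectorised over `resname`.
#' @export
residue_radius <- function(resname, scale_factor = 0.5, table = NULL) {
  tab <- if (is.null(table)) residue_volume_table() else table
  resname <- toupper(resname)
  i <- match(resname, tab$resname)
  if (anyNA(i))
    stop("unknown residue code(s): ",
         paste(unique(resname[is.na(i)]), collapse = ", "),
         "; valid codes: ", paste(tab$resname, collapse = ", "))
  tab$volume_A3[i]^(1 / 3) * scale_factor
}

.class_sets <- list(
  negative = c("ASP", "GLU"),
  positive = c("LYS", "ARG", "HIS"),
  polar = c("SER", "THR", "ASN", "GLN", "TYR", "CYS")
)

#' Physicochemical colour class of a bead
#'
#' Backbone beads are their own class (rendered black); sidechain beads are
#' classed negative (ASP/GLU), positive (LYS/ARG/HIS), polar uncharged
#' (SER/THR/ASN/GLN/TYR/CYS) or hydrophobic (the remainder); linker beads
#' form a dedicated class.
#'
#' @param resname 3-letter residue code(s).
#' @param kind bead kind: `"backbone"`, `"sidechain"` or `"linker"`.
#' @return character class, one of `backbone`, `negative`, `positive`,
#'   `polar`, `hydrophobic`, `linker`.
#' @export
residue_class <- function(resname, kind = "sidechain") {
  resname <- toupper(resname)
  tab <- residue_volume_table()
  if (!all(resname %in% tab$resname))
    stop("unknown residue code(s): ",
         paste(setdiff(resname, tab$resname), collapse = ", "))
  kind <- rep_len(kind, length(resname))
  out <- ifelse(resname %in% .class_sets$negative, "negative",
         ifelse(resname %in% .class_sets$positive, "positive",
         ifelse(resname %in% .class_sets$polar, "polar", "hydrophobic")))
  out[kind == "backbone"] <- "backbone"
  out[kind == "linker"] <- "linker"
  out
}

#' Coarse-grained bead model container
#'
#' @param beads data.frame with columns `x`, `y`, `z`, `radius`, `kind`,
#'   `resname`, `resno`, `icode`, `chain`, `class`.
#' @param bonds optional 2-column bead-index matrix (consecutive-backbone
#'   links by default in [coarse_grain()]).
#' @param id source identifier.
#' @return object of class `bead_model`.
#' @export
bead_model <- function(beads, bonds = NULL, id = "beads") {
  need <- c("x", "y", "z", "radius", "kind", "resname", "resno", "icode",
            "chain", "class")
  miss <- setdiff(need, names(beads))
  if (length(miss)) stop("bead table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(beads$radius <= 0)) stop("bead radii must be positive")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  rownames(beads) <- NULL
  structure(list(beads = beads, bonds = matrix(as.integer(bonds), ncol = 2),
                 id = id),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model '%s': %d beads (%s)\n", x$id, nrow(x$beads),
              paste(names(table(x$beads$kind)), table(x$beads$kind),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3",
                     "HA2", "HA3")

#' Coarse-grain a structure to two beads per residue
#'
#' Every residue gets a backbone bead at its alpha carbon; non-glycine
#' residues additionally get a sidechain bead at the centroid of their
#' non-backbone heavy atoms (unweighted by default, optionally
#' mass-weighted). Glycine is a single alpha-carbon bead. Backbone beads use
#' the glycine-volume radius (backbone-sized); sidechain beads the residue's
#' own volume radius.
#'
#' @param structure a [mol_structure()] with a CA atom in every residue.
#' @param scale_factor radius scale, see [residue_radius()].
#' @param weighting `"unweighted"` (centroid) or `"mass"` for the sidechain
#'   centre.
#' @return a [bead_model()]; beads ordered by residue (backbone bead first
#'   within each residue), with backbone-backbone bonds between consecutive
#'   residues of the same chain.
#' @export
coarse_grain <- function(structure, scale_factor = 0.5,
                         weighting = c("unweighted", "mass")) {
  weighting <- match.arg(weighting)
  at <- structure$atoms
  keys <- residue_key(at)
  ukeys <- unique(keys)
  masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008,
              P = 30.974, SE = 78.97)
  rows <- list()
  for (k in ukeys) {
    res <- at[keys == k, , drop = FALSE]
    resname <- toupper(res$resname[1])
    ca <- res[res$name == "CA", , drop = FALSE]
    if (!nrow(ca))
      stop(sprintf("residue %s %d%s (chain %s) has no CA atom",
                   resname, res$resno[1], res$icode[1], res$chain[1]))
    ca <- ca[1, ]
    bb_radius <- residue_radius("GLY", scale_factor)
    rows[[length(rows) + 1L]] <- data.frame(
      x = ca$x, y = ca$y, z = ca$z, radius = bb_radius,
      kind = "backbone", resname = resname, resno = ca$resno,
      icode = ca$icode, chain = ca$chain,
      class = "backbone", stringsAsFactors = FALSE)
    if (resname == "GLY") next
    sc <- res[!(res$name %in% .backbone_atoms) & res$element != "H", ,
              drop = FALSE]
    if (!nrow(sc)) {
      warning(sprintf("residue %s %d (chain %s) has no sidechain atoms; %s",
                      resname, ca$resno, ca$chain, "backbone bead only"))
      next
    }
    w <- if (weighting == "mass") {
      m <- masses[sc$element]; m[is.na(m)] <- 12; m
    } else rep(1, nrow(sc))
    cen <- colSums(as.matrix(sc[, c("x", "y", "z")]) * w) / sum(w)
    rows[[length(rows) + 1L]] <- data.frame(
      x = cen[1], y = cen[2], z = cen[3],
      radius = residue_radius(resname, scale_factor),
      kind = "sidechain", resname = resname, resno = ca$resno,
      icode = ca$icode, chain = ca$chain,
      class = residue_class(resname, "sidechain"), stringsAsFactors = FALSE)
  }
  beads <- do.call(rbind, rows)
  bb <- which(beads$kind == "backbone")
  bonds <- NULL
  if (length(bb) > 1) {
    same_chain <- beads$chain[bb[-length(bb)]] == beads$chain[bb[-1]]
    bonds <- cbind(bb[-length(bb)][same_chain], bb[-1][same_chain])
  }
  # tether each sidechain bead to its backbone bead for display
  sc <- which(beads$kind == "sidechain")
  if (length(sc)) {
    owner <- vapply(sc, function(i) {
      bb[beads$resno[bb] == beads$resno[i] & beads$chain[bb] == beads$chain[i] &
           beads$icode[bb] == beads$icode[i]][1]
    }, integer(1))
    bonds <- rbind(bonds, cbind(owner, sc))
  }
  bead_model(beads, bonds, id = paste0(structure$id, "_cg"))
}
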