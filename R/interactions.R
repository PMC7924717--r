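# Real-time pairwise interaction rules between two pose-driven molecules:
# steric clash detection, Coulomb electrostatics, hydrogen-bond geometry and
# a stochastic two-state proton-transfer emulator.

#' Coulomb constant, kcal Angstrom / (mol e^2)
#' @export
K_COULOMB <- 332.0636

#' Detect steric clashes between two site sets
#'
#' In `center` mode (the atomistic rule) a pair clashes when the
#' centre-centre distance falls below `threshold` (default 3 Angstrom). In
#' `radius_sum` mode (for coarse beads of heterogeneous size) a pair clashes
#' below the sum of its two radii.
#'
#' @param coords_a,coords_b n x 3 matrices of positions (Angstrom).
#' @param radii_a,radii_b per-site radii, required for `radius_sum` mode.
#' @param threshold centre-centre cutoff in Angstrom (`center` mode).
#' @param mode `"center"` or `"radius_sum"`.
#' @return list of class `clash_report`: `pairs` data.frame (`a`, `b`,
#'   `distance`), `count`, plus the rule used.
#' @export
detect_clashes <- function(coords_a, coords_b, radii_a = NULL, radii_b = NULL,
                           threshold = 3.0,
                           mode = c("center", "radius_sum")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  coords_a <- as_points(coords_a); coords_b <- as_points(coords_b)
  if (!nrow(coords_a) || !nrow(coords_b)) stop("both site sets must be non-empty")
  d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * tcrossprod(coords_a, coords_b)
  d <- sqrt(pmax(d2, 0))
  cut <- if (mode == "center") {
    matrix(threshold, nrow(coords_a), nrow(coords_b))
  } else {
    if (is.null(radii_a) || is.null(radii_b))
      stop("radius_sum mode needs radii for both sets")
    outer(as.numeric(radii_a), as.numeric(radii_b), "+")
  }
  hit <- which(d < cut, arr.ind = TRUE)
  pairs <- data.frame(a = as.integer(hit[, 1]), b = as.integer(hit[, 2]),
                      distance = d[hit])
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, count = nrow(pairs), mode = mode,
                 threshold = if (mode == "center") threshold else NA_real_),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clash_report: %d clashing pairs (mode %s)\n", x$count, x$mode))
  invisible(x)
}

#' Coulomb interaction between two point charges
#'
#' `E = k_c q1 q2 / (eps r)` and `|F| = k_c |q1 q2| / (eps r^2)` with
#' `k_c = 332.0636 kcal Angstrom / (mol e^2)`; the pair is attractive when
#' the charges have opposite sign.
#'
#' @param q1,q2 charges in elementary-charge units.
#' @param r separation in Angstrom, > 0.
#' @param dielectric relative dielectric constant (default 1).
#' @return list `energy` (kcal/mol, signed), `force` (kcal/mol/Angstrom,
#'   magnitude), `attractive` (logical; FALSE for zero product).
#' @export
coulomb_interaction <- function(q1, q2, r, dielectric = 1) {
  if (!is.numeric(r) || any(r <= 0)) stop("r must be positive (singular at r = 0)")
  if (dielectric <= 0) stop("dielectric must be positive")
  e <- K_COULOMB * q1 * q2 / (dielectric * r)
  f <- K_COULOMB * abs(q1 * q2) / (dielectric * r^2)
  list(energy = e, force = f, attractive = (q1 * q2) < 0)
}

#' Hydrogen-bond geometry test
#'
#' A display bond is reported when the donor-acceptor heavy-atom distance
#' lies strictly inside the window (default 2-3 Angstrom, boundaries
#' exclusive); proton transfer is geometrically eligible when the proton is
#' within 2 Angstrom (inclusive) of the accepting heavy atom.
#'
#' @param donor_heavy,proton,acceptor_heavy positions (3-vectors, Angstrom).
#' @param window length-2 numeric, the exclusive display window on the
#'   heavy-heavy distance.
#' @param transfer_cutoff inclusive proton-acceptor cutoff (Angstrom).
#' @return list `display_bond`, `transfer_eligible`, `d_heavy`,
#'   `d_proton_acceptor`.
#' @export
detect_hbond <- function(donor_heavy, proton, acceptor_heavy,
                         window = c(2.0, 3.0), transfer_cutoff = 2.0) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(low, high) with low < high")
  p <- rbind(as.numeric(donor_heavy), as.numeric(proton),
             as.numeric(acceptor_heavy))
  if (!all(is.finite(p))) stop("positions must be finite")
  d_heavy <- sqrt(sum((p[1, ] - p[3, ])^2))
  d_pa <- sqrt(sum((p[2, ] - p[3, ])^2))
  list(display_bond = (d_heavy > window[1] && d_heavy < window[2]),
       transfer_eligible = (d_pa <= transfer_cutoff),
       d_heavy = d_heavy, d_proton_acceptor = d_pa)
}

#' Initial protonation state for the lysine/glutamate proton exchange
#'
#' @param holder `"LYS_N"` (protonated lysine, the default start) or
#'   `"GLU_O"`.
#' @param populations target stationary time-fractions for the two holders,
#'   must sum to 1; default 70% protonated lysine / 30% protonated
#'   glutamate.
#' @param site_positions named list with 3-vectors `LYS_N` and `GLU_O`; the
#'   proton snaps to the current holder's site.
#' @return list of class `protonation_state`.
#' @export
protonation_state <- function(holder = "LYS_N",
                              populations = c(LYS_N = 0.70, GLU_O = 0.30),
                              site_positions = list(LYS_N = c(0, 0, 0),
                                                    GLU_O = c(2.8, 0, 0))) {
  holder <- match.arg(holder, c("LYS_N", "GLU_O"))
  if (abs(sum(populations) - 1) > 1e-9) stop("populations must sum to 1")
  if (any(populations <= 0)) stop("populations must be positive")
  structure(list(holder = holder,
                 populations = populations,
                 site_positions = site_positions,
                 proton_position = site_positions[[holder]]),
            class = "protonation_state")
}

#' One tick of the stochastic proton-transfer emulator
#'
#' If the geometry does not permit transfer the state is returned unchanged.
#' Otherwise the proton hops from lysine to glutamate with per-tick
#' probability `p_forward`, and back with
#' `p_backward = p_forward * populations[LYS] / populations[GLU]`, the
#' detailed-balance rates whose stationary distribution is exactly the
#' target populations (default 0.70 / 0.30, ratio 2.33).
#'
#' @param state a [protonation_state()].
#' @param transfer_eligible logical, from [detect_hbond()].
#' @param p_forward per-tick LYS->GLU hop probability in (0, 1); default
#'   0.03 (exchanges visible on a seconds timescale at 200 ms ticks).
#' @return updated [protonation_state()]. Uses R's RNG; seed externally for
#'   reproducibility.
#' @export
proton_transfer_step <- function(state, transfer_eligible, p_forward = 0.03) {
  stopifnot(inherits(state, "protonation_state"))
  p_backward <- p_forward * state$populations[["LYS_N"]] /
    state$populations[["GLU_O"]]
  if (p_forward <= 0 || p_forward >= 1 || p_backward <= 0 || p_backward >= 1)
    stop("per-tick probabilities must lie in (0, 1)")
  if (!isTRUE(transfer_eligible)) return(state)
  p_hop <- if (state$holder == "LYS_N") p_forward else p_backward
  if (stats::runif(1) < p_hop) {
    state$holder <- if (state$holder == "LYS_N") "GLU_O" else "LYS_N"
    state$proton_position <- state$site_positions[[state$holder]]
  }
  state
}

#' Simulate the proton-transfer chain for many ticks
#'
#' Convenience driver around [proton_transfer_step()] recording the holder
#' at every tick.
#'
#' @param n_ticks number of ticks.
#' @param eligible logical vector (recycled) of per-tick transfer
#'   eligibility; default always eligible.
#' @param p_forward per-tick forward probability.
#' @param state starting [protonation_state()].
#' @param seed optional RNG seed.
#' @return list: `holders` (character per tick), `fraction_lys`,
#'   `ratio` (LYS ticks / GLU ticks), `n_transfers`.
#' @export
simulate_protonation <- function(n_ticks, eligible = TRUE, p_forward = 0.03,
                                 state = protonation_state(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eligible <- rep_len(eligible, n_ticks)
  p_backward <- p_forward * state$populations[["LYS_N"]] /
    state$populations[["GLU_O"]]
  holders <- character(n_ticks)
  holder <- state$holder
  # inline two-state chain (same rates as proton_transfer_step) for speed
  u <- stats::runif(n_ticks)
  for (i in seq_len(n_ticks)) {
    if (eligible[i]) {
      p_hop <- if (holder == "LYS_N") p_forward else p_backward
      if (u[i] < p_hop) holder <- if (holder == "LYS_N") "GLU_O" else "LYS_N"
    }
    holders[i] <- holder
  }
  n_lys <- sum(holders == "LYS_N")
  list(holders = holders,
       fraction_lys = n_lys / n_ticks,
       ratio = n_lys / max(1L, n_ticks - n_lys),
       n_transfers = sum(holders[-1] != holders[-n_ticks]))
}
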