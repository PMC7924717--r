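# Fixed-distance-constraint thermal mechanics: the plastic-modeling-kit
# analogue. Atoms/beads are spheres joined by rigid distance constraints
# (bonds and angles via 1-2 and 1-3 pairs; dihedrals stay free), propagated
# by position-based dynamics with a velocity-rescaling thermostat.

#' Constraint set container
#'
#' @param pairs data.frame (or 3-column matrix) with columns `i`, `j`,
#'   `target` (Angstrom, > 0).
#' @param topology tag: `"molecule_12_13"` or `"linker_chain"`.
#' @return data.frame of class `constraint_set`.
#' @export
constraint_set <- function(pairs, topology = "molecule_12_13") {
  pairs <- as.data.frame(pairs)
  names(pairs) <- c("i", "j", "target")
  pairs$i <- as.integer(pairs$i); pairs$j <- as.integer(pairs$j)
  if (nrow(pairs)) {
    if (any(pairs$target <= 0)) stop("constraint targets must be positive")
    if (any(pairs$i == pairs$j)) stop("constraints cannot be self-pairs")
    key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
    if (anyDuplicated(key)) stop("duplicate constraint pairs")
  }
  attr(pairs, "topology") <- topology
  class(pairs) <- c("constraint_set", "data.frame")
  pairs
}

#' Build 1-2 / 1-3 constraints from a bonded structure
#'
#' One fixed-distance constraint per bonded pair and per pair of atoms
#' sharing a bonded neighbour (angles), targets set to the current
#' distances. 1-4 pairs are left unconstrained so rotations about bonds
#' remain free, as in a plastic modeling kit.
#'
#' @param structure a [mol_structure()] with bonds.
#' @return a [constraint_set()] with topology `molecule_12_13`.
#' @export
build_molecule_constraints <- function(structure) {
  bonds <- structure$bonds
  n <- nrow(structure$atoms)
  if (!nrow(bonds)) {
    warning("structure has no bonds; empty constraint set")
    return(constraint_set(data.frame(i = integer(0), j = integer(0),
                                     target = numeric(0)),
                          topology = "molecule_12_13"))
  }
  xyz <- coords(structure)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lonely <- which(vapply(adj, length, integer(1)) == 0)
  if (length(lonely))
    warning("atoms with no bonds left unconstrained: ",
            paste(lonely, collapse = ", "))
  pairs <- list()
  add <- function(i, j) {
    pairs[[length(pairs) + 1L]] <<- c(min(i, j), max(i, j))
  }
  for (k in seq_len(nrow(bonds))) add(bonds[k, 1], bonds[k, 2])
  for (b in seq_len(n)) {
    nb <- adj[[b]]
    if (length(nb) < 2) next
    cmb <- utils::combn(sort(nb), 2)
    for (k in seq_len(ncol(cmb))) add(cmb[1, k], cmb[2, k])
  }
  m <- unique(do.call(rbind, pairs))
  target <- sqrt(rowSums((xyz[m[, 1], , drop = FALSE] -
                            xyz[m[, 2], , drop = FALSE])^2))
  constraint_set(data.frame(i = m[, 1], j = m[, 2], target = target),
                 topology = "molecule_12_13")
}

#' Build a flexible-linker constraint chain between two anchors
#'
#' Places `n_beads` beads between two anchor points and constrains
#' anchor-bead, consecutive bead-bead and bead-anchor distances to
#' `spacing` (n_beads + 1 constraints). Bead indices 1 and 2 are the fixed
#' anchors; the linker beads follow. Initial bead positions sit on (or are
#' folded around) the anchor-anchor segment and are then projected onto the
#' constraint manifold.
#'
#' @param anchor_a,anchor_b 3-vectors, Angstrom.
#' @param n_beads number of free linker beads (default 6, the hexaglycine
#'   linker).
#' @param spacing constraint target, Angstrom (default 3.8, the
#'   alpha-carbon spacing).
#' @return list: `positions` ((n_beads + 2) x 3 matrix, anchors first),
#'   `constraints` ([constraint_set()] with topology `linker_chain`),
#'   `fixed` logical mask (TRUE for the two anchors).
#' @export
build_linker_constraints <- function(anchor_a, anchor_b, n_beads = 6,
                                     spacing = 3.8) {
  anchor_a <- as.numeric(anchor_a); anchor_b <- as.numeric(anchor_b)
  if (n_beads < 1) stop("need at least one linker bead")
  contour <- (n_beads + 1) * spacing
  sep <- sqrt(sum((anchor_b - anchor_a)^2))
  if (sep > contour + 1e-9)
    stop(sprintf("anchors %.3f A apart exceed the %.3f A contour length",
                 sep, contour))
  # initial guess: evenly spread along the segment, zig-zag offset normal to
  # it when slack exists, then projected to the constraint manifold
  tfrac <- seq_len(n_beads) / (n_beads + 1)
  base <- outer(tfrac, anchor_b - anchor_a) + rep(anchor_a, each = n_beads)
  if (sep < contour - 1e-9) {
    axis <- if (sep > 1e-9) (anchor_b - anchor_a) / sep else c(1, 0, 0)
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    normal <- ref - sum(ref * axis) * axis
    normal <- normal / sqrt(sum(normal^2))
    amp <- 0.5 * sqrt(max(spacing^2 - (sep / (n_beads + 1))^2, 0.01))
    base <- base + outer((-1)^seq_len(n_beads) * amp, normal)
  }
  pos <- rbind(anchor_a, anchor_b, base)
  rownames(pos) <- NULL
  idx <- c(1L, seq.int(3L, length.out = n_beads), 2L)  # chain order
  cs <- constraint_set(data.frame(i = idx[-length(idx)], j = idx[-1],
                                  target = spacing),
                       topology = "linker_chain")
  fixed <- c(TRUE, TRUE, rep(FALSE, n_beads))
  pos <- project_constraints(pos, cs, fixed = fixed, tol = 1e-6,
                             max_iter = 500)$positions
  list(positions = pos, constraints = cs, fixed = fixed)
}

#' Dynamics state container
#'
#' @param positions n x 3 matrix, Angstrom.
#' @param velocities n x 3 matrix, Angstrom per tick (default zero).
#' @param radii per-bead radii for overlap resolution (default 0 = off).
#' @param temperature_target reduced-units temperature (k_B = mass = 1, so
#'   the per-bead kinetic-energy target is 3 T / 2).
#' @param fixed logical mask; fixed beads never move.
#' @return list of class `dynamics_state` (also carries `tick` and the last
#'   step's `max_violation` / `converged` diagnostics).
#' @export
dynamics_state <- function(positions, velocities = NULL, radii = NULL,
                           temperature_target = 1, fixed = NULL) {
  positions <- as_points(positions)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as_points(velocities)
  if (is.null(radii)) radii <- rep(0, n)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  stopifnot(nrow(velocities) == n, length(radii) == n, length(fixed) == n)
  structure(list(positions = positions, velocities = velocities,
                 radii = as.numeric(radii),
                 temperature_target = temperature_target,
                 fixed = as.logical(fixed),
                 tick = 0L, max_violation = 0, converged = TRUE),
            class = "dynamics_state")
}

# Gauss-Seidel projection of pairwise distance constraints (SHAKE-like).
project_constraints <- function(positions, constraints, fixed,
                                tol = 1e-3, max_iter = 300) {
  ci <- constraints$i; cj <- constraints$j; ct <- constraints$target
  nc <- length(ci)
  if (!nc) return(list(positions = positions, max_violation = 0,
                       converged = TRUE))
  inv_mass <- ifelse(fixed, 0, 1)
  current_violation <- function() {
    dd <- sqrt(rowSums((positions[cj, , drop = FALSE] -
                          positions[ci, , drop = FALSE])^2))
    max(abs(dd - ct) / ct)
  }
  for (iter in seq_len(max_iter)) {
    if (current_violation() < tol) break
    for (k in seq_len(nc)) {
      i <- ci[k]; j <- cj[k]
      dvec <- positions[j, ] - positions[i, ]
      d <- sqrt(sum(dvec^2))
      if (d < 1e-12) {  # degenerate overlap: nudge along x
        dvec <- c(1e-6, 0, 0); d <- 1e-6
      }
      wsum <- inv_mass[i] + inv_mass[j]
      if (wsum == 0) next
      corr <- (d - ct[k]) / d / wsum
      positions[i, ] <- positions[i, ] + inv_mass[i] * corr * dvec
      positions[j, ] <- positions[j, ] - inv_mass[j] * corr * dvec
    }
  }
  viol <- current_violation()
  list(positions = positions, max_violation = viol,
       converged = viol < tol)
}

# push non-constrained overlapping sphere pairs apart to contact
resolve_overlaps <- function(positions, radii, fixed, skip_pairs) {
  n <- nrow(positions)
  if (all(radii <= 0) || n < 2) return(positions)
  d <- as.matrix(stats::dist(positions))
  cut <- outer(radii, radii, "+")
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) && nrow(skip_pairs)) {
    key <- paste(hit[, 1], hit[, 2])
    skip <- paste(pmin(skip_pairs[, 1], skip_pairs[, 2]),
                  pmax(skip_pairs[, 1], skip_pairs[, 2]))
    hit <- hit[!key %in% skip, , drop = FALSE]
  }
  inv_mass <- ifelse(fixed, 0, 1)
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    dvec <- positions[j, ] - positions[i, ]
    dd <- sqrt(sum(dvec^2))
    if (dd < 1e-12) { dvec <- c(1e-6, 0, 0); dd <- 1e-6 }
    wsum <- inv_mass[i] + inv_mass[j]
    if (wsum == 0) next
    corr <- (dd - cut[i, j]) / dd / wsum
    positions[i, ] <- positions[i, ] + inv_mass[i] * corr * dvec
    positions[j, ] <- positions[j, ] - inv_mass[j] * corr * dvec
  }
  positions
}

kinetic_temperature <- function(velocities, fixed) {
  free <- !fixed
  if (!any(free)) return(0)
  mean(rowSums(velocities[free, , drop = FALSE]^2)) / 3  # k_B = m = 1
}

#' One position-based dynamics step
#'
#' Step order: (1) optional Andersen-style velocity redraws and a
#' Berendsen-style rescale of free-bead velocities toward the target
#' temperature; (2) unconstrained update `x <- x + v dt`; (3) Gauss-Seidel
#' distance-constraint projection (cap `max_iter` sweeps, relative
#' tolerance `tol`); (4) sphere-sphere overlap resolution between
#' non-constrained pairs; (5) fixed beads restored and velocities recomputed
#' as `(x_new - x_old) / dt`, then rescaled to the target temperature so
#' the thermostat contract holds on the stored velocities. Deterministic
#' for a fixed RNG seed.
#'
#' @param state a [dynamics_state()].
#' @param constraints a [constraint_set()].
#' @param dt tick length (time is measured in ticks; default 1).
#' @param params list: `coupling` (Berendsen factor weight in (0, 1], 1 =
#'   full rescale), `tol`, `max_iter`, `collision_prob` (per-bead Andersen
#'   redraw probability per tick), `resolve_overlaps` (logical).
#' @return updated `dynamics_state`; `$max_violation` and `$converged`
#'   report the projection outcome (non-convergence is flagged, positions
#'   still returned).
#' @export
dynamics_step <- function(state, constraints, dt = 1,
                          params = list()) {
  stopifnot(inherits(state, "dynamics_state"))
  p <- utils::modifyList(list(coupling = 1, tol = 1e-3, max_iter = 300,
                              collision_prob = 0.1,
                              resolve_overlaps = TRUE), params)
  pos0 <- state$positions
  vel <- state$velocities
  fixed <- state$fixed
  free <- which(!fixed)
  Tt <- state$temperature_target
  if (length(free) && Tt > 0) {
    if (p$collision_prob > 0) {
      hitn <- free[stats::runif(length(free)) < p$collision_prob]
      if (length(hitn))
        vel[hitn, ] <- matrix(stats::rnorm(3 * length(hitn), sd = sqrt(Tt)),
                              ncol = 3)
    }
    Tc <- kinetic_temperature(vel, fixed)
    if (Tc > 1e-12) {
      lambda <- sqrt(1 + p$coupling * (Tt / Tc - 1))
      vel[free, ] <- vel[free, ] * lambda
    } else if (all(vel[free, ] == 0) && p$collision_prob <= 0) {
      # cold start with no collisions: seed Maxwell velocities
      vel[free, ] <- matrix(stats::rnorm(3 * length(free), sd = sqrt(Tt)),
                            ncol = 3)
    }
  }
  pos <- pos0
  pos[free, ] <- pos0[free, ] + vel[free, , drop = FALSE] * dt
  proj <- project_constraints(pos, constraints, fixed,
                              tol = p$tol, max_iter = p$max_iter)
  pos <- proj$positions
  if (p$resolve_overlaps)
    pos <- resolve_overlaps(pos, state$radii, fixed,
                            skip_pairs = cbind(constraints$i, constraints$j))
  pos[fixed, ] <- pos0[fixed, , drop = FALSE]
  vel_new <- (pos - pos0) / dt
  if (length(free) && Tt > 0) {
    Tc <- kinetic_temperature(vel_new, fixed)
    if (Tc > 1e-12)
      vel_new[free, ] <- vel_new[free, ] *
        sqrt(1 + p$coupling * (Tt / Tc - 1))
  }
  state$positions <- pos
  state$velocities <- vel_new
  state$tick <- state$tick + 1L
  state$max_violation <- proj$max_violation
  state$converged <- proj$converged
  state
}

#' Run constrained dynamics for many steps
#'
#' @param state a [dynamics_state()].
#' @param constraints a [constraint_set()].
#' @param n_steps number of ticks.
#' @param dt tick length.
#' @param params see [dynamics_step()].
#' @param seed optional RNG seed (set once before the run).
#' @param record_every store a trajectory snapshot every k ticks (0 = none).
#' @return list: `state` (final), `trajectory` (list of position matrices),
#'   `kinetic_temperature` (per recorded tick), `max_violation` (per tick
#'   max over the run), `violations` (per recorded tick).
#' @export
run_dynamics <- function(state, constraints, n_steps, dt = 1,
                         params = list(), seed = NULL, record_every = 10) {
  if (!is.null(seed)) set.seed(seed)
  traj <- list(); kT <- numeric(0); viol <- numeric(0)
  worst <- 0
  for (s in seq_len(n_steps)) {
    state <- dynamics_step(state, constraints, dt = dt, params = params)
    if (state$max_violation > worst) worst <- state$max_violation
    if (record_every > 0 && s %% record_every == 0) {
      traj[[length(traj) + 1L]] <- state$positions
      kT <- c(kT, kinetic_temperature(state$velocities, state$fixed))
      viol <- c(viol, state$max_violation)
    }
  }
  list(state = state, trajectory = traj, kinetic_temperature = kT,
       violations = viol, max_violation = worst)
}

#' Worm-like-chain entropy of a linker extension
#'
#' Relative configurational entropy `S(r) = ln P(r)` (in k_B, additive
#' constant dropped) of the end-to-end distance of a worm-like chain, using
#' the Gaussian-limit radial density with a finite-extensibility
#' denominator: `S(r) = ln r^2 - 3 r^2 / (4 p L (1 - (r/L)^2))`. The form
#' reduces to the Gaussian chain at low extension and diverges to -Inf as
#' `r` approaches the contour length.
#'
#' @param end_to_end extension r, Angstrom, `0 <= r < contour`.
#' @param contour contour length L, Angstrom.
#' @param persistence persistence length p, Angstrom (default 4, a
#'   disordered-polypeptide scale).
#' @return entropy in k_B units (relative), vectorised over `end_to_end`.
#' @export
wlc_entropy <- function(end_to_end, contour, persistence = 4.0) {
  r <- as.numeric(end_to_end)
  if (any(r < 0) || any(r >= contour))
    stop("end_to_end must satisfy 0 <= r < contour")
  x2 <- (r / contour)^2
  ifelse(r == 0, -Inf,
         log(r^2) - 3 * r^2 / (4 * persistence * contour * (1 - x2)))
}

#' Linker strain
#'
#' `strain = sum_i ((d_i - target) / target)^2` over consecutive-bead
#' distances: zero exactly when every link sits at its equilibrium spacing.
#'
#' @param bond_distances consecutive-bead distances, Angstrom.
#' @param target equilibrium spacing, Angstrom, > 0.
#' @return dimensionless strain.
#' @export
linker_strain <- function(bond_distances, target) {
  if (!length(bond_distances)) stop("need at least one bond distance")
  if (target <= 0) stop("target spacing must be positive")
  sum(((bond_distances - target) / target)^2)
}

#' Maximum relaxed extension of a linker
#'
#' The anchor-to-anchor separation at which the chain is straight and every
#' constraint exactly satisfied: the sum of the constraint targets. When
#' domain geometry is supplied (anchor offsets from each domain centre, in
#' world orientation), also reports the centre-to-centre maximum: an upper
#' bound `anchor_max + |offset_a| + |offset_b|` and the pose-constrained
#' exact value found by 1-D root finding along the separation axis.
#'
#' @param constraints a linker [constraint_set()] (topology
#'   `linker_chain`).
#' @param offset_a,offset_b optional 3-vectors: anchor position minus domain
#'   centre for each domain, in the current (fixed) orientations.
#' @param axis separation axis for the pose-constrained value (default x).
#' @return list: `anchor_anchor` (Angstrom); with offsets also
#'   `center_center_bound` and `center_center` (exact along `axis`).
#' @export
max_extension <- function(constraints, offset_a = NULL, offset_b = NULL,
                          axis = c(1, 0, 0)) {
  if (!identical(attr(constraints, "topology"), "linker_chain"))
    stop("max_extension needs a linker_chain constraint set")
  L <- sum(constraints$target)
  out <- list(anchor_anchor = L)
  if (!is.null(offset_a) && !is.null(offset_b)) {
    offset_a <- as.numeric(offset_a); offset_b <- as.numeric(offset_b)
    axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
    out$center_center_bound <- L + sqrt(sum(offset_a^2)) +
      sqrt(sum(offset_b^2))
    # centres at 0 and D*axis with fixed orientations: anchor separation
    # |D*axis + offset_b - offset_a| = L; solve for the largest D >= 0
    w <- offset_b - offset_a
    uw <- sum(axis * w)
    disc <- uw^2 + L^2 - sum(w^2)
    if (disc < 0)
      stop("linker cannot span the anchor offsets along this axis")
    out$center_center <- -uw + sqrt(disc)
  }
  out
}

#' Per-tick linker report
#'
#' The real-time readout for a two-domain + flexible-linker scene: domain
#' centre-centre distance, worm-like-chain entropy of the current
#' anchor-anchor extension, strain over the linker links, and the per-link
#' distances.
#'
#' @param positions current (n_beads + 2) x 3 positions from
#'   [build_linker_constraints()] ordering (anchors first).
#' @param constraints the linker [constraint_set()].
#' @param center_a,center_b domain centres (default: the anchors).
#' @param persistence worm-like-chain persistence length, Angstrom.
#' @return list of class `linker_report`: `center_distance`, `entropy`,
#'   `strain`, `bond_distances`, `end_to_end`.
#' @export
linker_report <- function(positions, constraints, center_a = NULL,
                          center_b = NULL, persistence = 4.0) {
  positions <- as_points(positions)
  if (is.null(center_a)) center_a <- positions[1, ]
  if (is.null(center_b)) center_b <- positions[2, ]
  dd <- sqrt(rowSums((positions[constraints$j, , drop = FALSE] -
                        positions[constraints$i, , drop = FALSE])^2))
  target <- constraints$target[1]
  contour <- sum(constraints$target)
  r <- sqrt(sum((positions[2, ] - positions[1, ])^2))
  entropy <- if (r < contour) {
    wlc_entropy(r, contour, persistence)
  } else -Inf  # at/beyond full stretch
  structure(list(
    center_distance = sqrt(sum((as.numeric(center_b) -
                                  as.numeric(center_a))^2)),
    entropy = entropy,
    strain = linker_strain(dd, target),
    bond_distances = dd,
    end_to_end = r), class = "linker_report")
}
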