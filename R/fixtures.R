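# Programmatic test fixtures with idealized geometry (tetrahedral angles,
# 1.5 A C-C bonds, 3.8 A alpha-carbon spacing). They stand in for the
# demo structures so that everything runs without external downloads.

zigzag_chain <- function(n, bond = 1.5, origin = c(0, 0, 0)) {
  theta <- 109.47 * pi / 180
  step_x <- bond * sin(theta / 2)
  step_z <- bond * cos(theta / 2)
  t(vapply(seq_len(n) - 1L, function(i)
    origin + c(i * step_x, 0, (i %% 2) * step_z), numeric(3)))
}

make_atoms <- function(names, elements, resname, resno, chain, xyz,
                       charge = 0) {
  data.frame(serial = seq_along(names), name = names, element = elements,
             resname = resname, resno = resno, icode = "", chain = chain,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, length(names)),
             occ = 1, stringsAsFactors = FALSE)
}

fixture_lys_glu_pair <- function(params = list()) {
  # lysine sidechain fragment: CA-CB-CG-CD-CE-NZ with three amine protons
  # (HZ1 is the titratable one); NZ carries +1
  lys_heavy <- zigzag_chain(6)
  nz <- lys_heavy[6, ]
  hz <- rbind(nz + c(0.59, 0.81, 0), nz + c(0.59, -0.81, 0),
              nz + c(0.4, 0, 0.92))
  lys <- make_atoms(
    c("CA", "CB", "CG", "CD", "CE", "NZ", "HZ1", "HZ2", "HZ3"),
    c("C", "C", "C", "C", "C", "N", "H", "H", "H"),
    "LYS", 1L, "A", rbind(lys_heavy, hz),
    charge = c(0, 0, 0, 0, 0, 1, 0, 0, 0))
  lys_bonds <- rbind(cbind(1:5, 2:6), c(6, 7), c(6, 8), c(6, 9))
  # glutamate sidechain fragment: CA-CB-CG-CD with carboxylate OE1/OE2,
  # each oxygen carrying -0.5
  glu_heavy <- zigzag_chain(4)
  cd <- glu_heavy[4, ]
  oe <- rbind(cd + c(0.64, 1.06, 0), cd + c(0.64, -1.06, 0))
  glu <- make_atoms(
    c("CA", "CB", "CG", "CD", "OE1", "OE2"),
    c("C", "C", "C", "C", "O", "O"),
    "GLU", 1L, "B", rbind(glu_heavy, oe),
    charge = c(0, 0, 0, 0, -0.5, -0.5))
  glu_bonds <- rbind(cbind(1:3, 2:4), c(4, 5), c(4, 6))
  list(lys = mol_structure(lys, lys_bonds, id = "lys_frag"),
       glu = mol_structure(glu, glu_bonds, id = "glu_frag"),
       titratable = list(lys_proton = 7L, lys_site = 6L, glu_site = 5L))
}

fixture_hexaglycine <- function(params = list()) {
  n <- params$n_res %||% 6L
  spacing <- params$spacing %||% 3.8
  xyz <- cbind((seq_len(n) - 1L) * spacing, 0, 0)
  atoms <- make_atoms(rep("CA", n), rep("C", n), "GLY", seq_len(n), "L", xyz)
  mol_structure(atoms, cbind(seq_len(n - 1L), seq.int(2L, n)),
                id = "hexaglycine")
}

default_helix_seq <- c("ALA", "LEU", "GLU", "LYS", "SER", "VAL", "PHE",
                       "GLY", "ASP", "ARG")

fixture_toy_helix <- function(params = list()) {
  n <- params$n_res %||% 10L
  sequence <- toupper(params$sequence %||%
                        rep_len(default_helix_seq, n))
  n <- length(sequence)
  chain <- params$chain %||% "A"
  # ideal alpha-helix CA trace: 2.3 A radius, 1.5 A rise, 100 deg/residue
  ang <- (seq_len(n) - 1L) * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1L) * 1.5)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      serial = serial, name = "CA", element = "C", resname = sequence[i],
      resno = i, icode = "", chain = chain,
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], charge = 0, occ = 1,
      stringsAsFactors = FALSE)
    if (sequence[i] != "GLY") {
      out <- ca[i, ] + c(ca[i, 1], ca[i, 2], 0) /
        sqrt(sum(ca[i, 1:2]^2)) * 1.53
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = "CB", element = "C", resname = sequence[i],
        resno = i, icode = "", chain = chain,
        x = out[1], y = out[2], z = out[3], charge = 0, occ = 1,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  ca_idx <- which(atoms$name == "CA")
  bonds <- cbind(ca_idx[-length(ca_idx)], ca_idx[-1])
  cb_idx <- which(atoms$name == "CB")
  if (length(cb_idx))
    bonds <- rbind(bonds, cbind(cb_idx - 1L, cb_idx))
  mol_structure(atoms, bonds, id = params$id %||% "toy_helix")
}

fixture_two_domain <- function(params = list()) {
  na <- params$n_res_a %||% 8L
  nb <- params$n_res_b %||% 6L
  a <- fixture_toy_helix(list(n_res = na, chain = "A", id = "domain_a"))
  b <- fixture_toy_helix(list(n_res = nb, chain = "B", id = "domain_b"))
  # anchors: the last CA of domain A, the first CA of domain B
  anchor_a <- max(which(a$atoms$name == "CA"))
  anchor_b <- min(which(b$atoms$name == "CA"))
  list(domain_a = a, domain_b = b,
       anchor_a = anchor_a, anchor_b = anchor_b,
       linker = list(n_beads = params$n_beads %||% 6L,
                     spacing = params$spacing %||% 3.8))
}

fixture_synthetic_saxs <- function(params = list()) {
  q_grid <- params$q_grid %||% seq(0.01, 0.5, length.out = 50)
  sigma <- params$sigma %||% 0
  displacement <- params$displacement %||% 25
  fx <- fixture_two_domain(params)
  cga <- coarse_grain(fx$domain_a)
  cgb <- coarse_grain(fx$domain_b)
  qrot <- drop(random_quaternion(1))
  true_pose <- pose(rotation = qrot,
                    translation = displacement *
                      c(1, 0, 0) + stats::rnorm(3, sd = 1))
  scene <- assemble_scene(list(
    anchored_molecule(cga, anchor_index = 1L, id = "A"),
    anchored_molecule(cgb, anchor_index = 1L, pose = true_pose, id = "B")))
  prof <- saxs_debye(scene, q_grid)
  intensity <- prof$intensity
  if (sigma > 0) intensity <- intensity + stats::rnorm(length(q_grid),
                                                       sd = sigma)
  list(profile = saxs_profile(q_grid, intensity,
                              sigma = rep(max(sigma, 1e-6), length(q_grid))),
       noiseless = prof, true_pose = true_pose,
       domain_a = cga, domain_b = cgb, scene = scene, q_grid = q_grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a deterministic test fixture
#'
#' Self-contained geometric stand-ins for the demo systems (all idealized
#' geometry; no downloads). Kinds:
#' \describe{
#'   \item{lys_glu_pair}{lysine + glutamate sidechain fragments with charged
#'     N/O atoms and a titratable proton (`$titratable` gives indices).}
#'   \item{hexaglycine_linker}{six glycine alpha carbons at 3.8 A spacing
#'     (params `n_res`, `spacing`).}
#'   \item{toy_helix}{ideal helix with CA + CB pseudo-sidechains (params
#'     `n_res`, `sequence`, `chain`).}
#'   \item{two_domain_linker}{two toy-helix domains plus linker metadata
#'     (params `n_res_a`, `n_res_b`, `n_beads`, `spacing`).}
#'   \item{synthetic_saxs_target}{coarse-grained two-domain scene at a
#'     random (seeded) pose, its Debye profile with Gaussian noise of the
#'     stated `sigma` (params also `q_grid`, `displacement`).}
#' }
#'
#' @param kind fixture kind, see above.
#' @param params list of kind-specific parameters.
#' @param seed RNG seed; for a fixed seed the output is identical.
#' @return kind-dependent: a [mol_structure()] or a list (see above).
#' @export
generate_fixture <- function(kind = c("lys_glu_pair", "hexaglycine_linker",
                                      "toy_helix", "two_domain_linker",
                                      "synthetic_saxs_target"),
                             params = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
         lys_glu_pair = fixture_lys_glu_pair(params),
         hexaglycine_linker = fixture_hexaglycine(params),
         toy_helix = fixture_toy_helix(params),
         two_domain_linker = fixture_two_domain(params),
         synthetic_saxs_target = fixture_synthetic_saxs(params))
}
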