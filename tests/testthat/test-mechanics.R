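linear_chain_structure <- function(n = 4, bond = 1.5) {
  theta <- 109.47 * pi / 180
  xyz <- t(vapply(seq_len(n) - 1L, function(i)
    c(i * bond * sin(theta / 2), 0, (i %% 2) * bond * cos(theta / 2)),
    numeric(3)))
  atoms <- data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                      element = "C", resname = "LIG", resno = 1L, icode = "",
                      chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = 0, occ = 1, stringsAsFactors = FALSE)
  mol_structure(atoms, cbind(seq_len(n - 1), seq.int(2, n)), id = "chain")
}

test_that("1-2/1-3 constraint topology leaves dihedrals free", {
  cs <- build_molecule_constraints(linear_chain_structure(4))
  key <- paste(cs$i, cs$j)
  expect_setequal(key, c("1 2", "2 3", "3 4", "1 3", "2 4"))
  expect_false("1 4" %in% key)   # the dihedral pair stays unconstrained

  # methane-like star: 4 bonds + 6 H-H angle pairs
  xyz <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
               c(-1, -1, 1)) * 0.63
  atoms <- data.frame(serial = 1:5, name = c("C", "H1", "H2", "H3", "H4"),
                      element = c("C", "H", "H", "H", "H"), resname = "CH4",
                      resno = 1L, icode = "", chain = "A",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      charge = 0, occ = 1, stringsAsFactors = FALSE)
  star <- mol_structure(atoms, cbind(1, 2:5), id = "ch4")
  cs2 <- build_molecule_constraints(star)
  expect_equal(nrow(cs2), 10)

  lone <- mol_structure(atoms[1, ], NULL, id = "atom")
  expect_warning(cs3 <- build_molecule_constraints(lone), "no bonds")
  expect_equal(nrow(cs3), 0)
})

test_that("linker construction satisfies its constraints at any feasible gap", {
  b6 <- build_linker_constraints(c(0, 0, 0), c(20, 0, 0))
  expect_equal(nrow(b6$constraints), 7)
  expect_equal(b6$constraints$target, rep(3.8, 7))

  # fully stretched: collinear chain, zero strain
  full <- build_linker_constraints(c(0, 0, 0), c(26.6, 0, 0))
  rep0 <- linker_report(full$positions, full$constraints)
  expect_equal(rep0$strain, 0, tolerance = 1e-8)
  expect_lt(max(abs(full$positions[, 2:3])), 1e-6)

  # nearly coincident anchors remain feasible
  tight <- build_linker_constraints(c(0, 0, 0), c(1, 0, 0))
  dd <- linker_report(tight$positions, tight$constraints)$bond_distances
  expect_lt(max(abs(dd - 3.8) / 3.8), 1e-5)

  expect_error(build_linker_constraints(c(0, 0, 0), c(40, 0, 0)),
               "contour")
})

test_that("a cold start without thermal noise does not move", {
  b <- build_linker_constraints(c(0, 0, 0), c(20, 0, 0))
  st <- dynamics_state(b$positions, temperature_target = 0, fixed = b$fixed)
  st2 <- dynamics_step(st, b$constraints)
  expect_equal(st2$positions, st$positions, tolerance = 1e-12)
})

test_that("constraints stay satisfied through long thermal runs", {
  b <- build_linker_constraints(c(0, 0, 0), c(18, 0, 0))
  st <- dynamics_state(b$positions, temperature_target = 1, fixed = b$fixed)
  run <- run_dynamics(st, b$constraints, n_steps = 2000, seed = 71,
                      record_every = 20)
  expect_lt(run$max_violation, 1e-3)
  expect_true(run$state$converged)
  # fixed anchors never moved
  expect_equal(run$state$positions[1, ], c(0, 0, 0))
  expect_equal(run$state$positions[2, ], c(18, 0, 0))
})

test_that("bonds and angles are conserved while the dihedral explores", {
  mol <- linear_chain_structure(4)
  cs <- build_molecule_constraints(mol)
  st <- dynamics_state(as.matrix(mol$atoms[, c("x", "y", "z")]),
                       temperature_target = 0.5)
  run <- run_dynamics(st, cs, n_steps = 10000, seed = 13, record_every = 25)
  expect_lt(run$max_violation, 1e-3)
  dihedrals <- vapply(run$trajectory, function(p)
    dihedral_deg(p[1, ], p[2, ], p[3, ], p[4, ]), numeric(1))
  # unwrapped range of the torsion exceeds 90 degrees
  expect_gt(diff(range(dihedrals)), 90)
  # per-snapshot 1-2 and 1-3 distances against their targets
  worst <- max(vapply(run$trajectory, function(p) {
    d <- sqrt(rowSums((p[cs$j, , drop = FALSE] - p[cs$i, , drop = FALSE])^2))
    max(abs(d - cs$target) / cs$target)
  }, numeric(1)))
  expect_lt(worst, 1e-3)
})

test_that("the thermostat delivers equipartition on free beads", {
  b <- build_linker_constraints(c(0, 0, 0), c(15, 0, 0))
  st <- dynamics_state(b$positions, temperature_target = 2, fixed = b$fixed)
  run <- run_dynamics(st, b$constraints, n_steps = 3000, seed = 5,
                      record_every = 5)
  burn <- ceiling(length(run$kinetic_temperature) / 5)
  mean_T <- mean(run$kinetic_temperature[-seq_len(burn)])
  expect_lt(abs(mean_T - 2) / 2, 0.10)
})

test_that("linker samples never exceed the maximal relaxed extension", {
  b <- build_linker_constraints(c(0, 0, 0), c(24, 0, 0))
  ext <- max_extension(b$constraints)
  expect_equal(ext$anchor_anchor, 26.6)
  st <- dynamics_state(b$positions, temperature_target = 1.5,
                       fixed = b$fixed)
  run <- run_dynamics(st, b$constraints, n_steps = 2000, seed = 9,
                      record_every = 10)
  # walk the chain: bead k can sit at most k links from anchor a
  chain_idx <- c(1L, 3:8, 2L)
  bound_ok <- vapply(run$trajectory, function(p) {
    d_from_a <- sqrt(rowSums(sweep(p[chain_idx, ], 2, p[1, ])^2))
    all(d_from_a <= 3.8 * (seq_along(chain_idx) - 1) * (1 + 2e-3) + 1e-9)
  }, logical(1))
  expect_true(all(bound_ok))
})

test_that("worm-like-chain entropy has the stated limits", {
  L <- 26.6; p <- 4
  expect_lt(wlc_entropy(0.9 * L, L, p), wlc_entropy(0.5 * L, L, p))
  # Gaussian-chain limit at low extension (matching additive constants)
  r <- seq(0.05, 0.3, by = 0.05) * L
  gauss <- log(r^2) - 3 * r^2 / (4 * p * L)
  dev <- wlc_entropy(r, L, p) - gauss
  expect_lt(max(abs(dev - dev[1])) / max(abs(gauss)), 0.02)
  # finite extensibility: unbounded decrease approaching the contour
  expect_lt(wlc_entropy(0.999 * L, L, p), wlc_entropy(0.99 * L, L, p) - 1)
  expect_error(wlc_entropy(L, L, p), "contour")
  # pure function
  expect_identical(wlc_entropy(10, L, p), wlc_entropy(10, L, p))
})

test_that("linker strain is the summed squared relative deviation", {
  expect_equal(linker_strain(rep(3.8, 7), 3.8), 0)
  expect_equal(linker_strain(c(3.8 * 1.1, rep(3.8, 6)), 3.8), 0.01,
               tolerance = 1e-12)
  lambda <- 1.07; n <- 7
  expect_equal(linker_strain(rep(3.8 * lambda, n), 3.8), n * (lambda - 1)^2,
               tolerance = 1e-12)
  expect_error(linker_strain(numeric(0), 3.8), "at least one")
  expect_error(linker_strain(3.8, 0), "positive")
})

test_that("maximal extension handles chains and anchored domain offsets", {
  single <- constraint_set(data.frame(i = 1L, j = 2L, target = 3.8),
                           topology = "linker_chain")
  expect_equal(max_extension(single)$anchor_anchor, 3.8)
  b <- build_linker_constraints(c(0, 0, 0), c(10, 0, 0))
  expect_equal(max_extension(b$constraints)$anchor_anchor, 7 * 3.8)
  expect_error(max_extension(constraint_set(
    data.frame(i = 1L, j = 2L, target = 1), topology = "molecule_12_13")),
    "linker_chain")

  # pose-constrained centre-centre maximum vs a brute-force grid search
  off_a <- c(2, 1, -0.5); off_b <- c(-1.5, 2, 1)
  got <- max_extension(b$constraints, offset_a = off_a, offset_b = off_b)
  expect_gte(got$center_center_bound, got$center_center)
  L <- 7 * 3.8
  Ds <- seq(0, got$center_center_bound, by = 0.001)
  sep <- vapply(Ds, function(D)
    sqrt(sum((D * c(1, 0, 0) + off_b - off_a)^2)), numeric(1))
  grid_best <- max(Ds[sep <= L])
  expect_equal(got$center_center, grid_best, tolerance = 0.1)
})
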