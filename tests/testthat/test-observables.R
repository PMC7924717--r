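# brute-force Debye oracle: naive triple loop, independent of the package path
debye_oracle <- function(pos, q, f = rep(1, nrow(pos))) {
  vapply(q, function(qq) {
    s <- 0
    for (i in seq_len(nrow(pos))) for (j in seq_len(nrow(pos))) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      x <- qq * r
      s <- s + f[i] * f[j] * if (x < 1e-12) 1 else sin(x) / x
    }
    s
  }, numeric(1))
}

test_that("Debye intensities match closed forms and the brute-force oracle", {
  one <- saxs_debye(matrix(c(0, 0, 0), 1), c(0.05, 0.2, 0.5))
  expect_equal(one$intensity, rep(1, 3))

  two <- saxs_debye(rbind(c(0, 0, 0), c(3.8, 0, 0)), 0.5)
  expect_equal(two$intensity, 2 * (1 + sin(1.9) / 1.9), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:3) {
    pos <- random_points(10, spread = 15)
    q <- seq(0.02, 0.6, length.out = 12)
    f <- runif(10, 0.5, 2)
    got <- saxs_debye(pos, q, form_factors = f)
    expect_equal(got$intensity, debye_oracle(pos, q, f), tolerance = 1e-10)
  }
  expect_error(saxs_debye(matrix(0, 1, 3), c(0.1, -0.2)), "positive")
})

test_that("I(q -> 0) approaches the squared total form factor", {
  set.seed(32)
  pos <- random_points(25, spread = 12)
  f <- runif(25, 0.5, 3)
  I0 <- saxs_debye(pos, 1e-6, form_factors = f)$intensity
  expect_equal(I0, sum(f)^2, tolerance = 1e-6)
})

test_that("the Debye profile is invariant under isometries", {
  set.seed(33)
  pos <- random_points(15)
  q <- seq(0.05, 0.5, length.out = 10)
  base <- saxs_debye(pos, q)$intensity
  p <- pose(rotation = drop(random_quaternion(1)), translation = c(12, -7, 3))
  moved <- apply_pose(pos, p)
  expect_equal(saxs_debye(moved, q)$intensity, base, tolerance = 1e-10)
})

test_that("chi-square fitting recovers scale and vanishes on self-fits", {
  q <- seq(0.02, 0.4, length.out = 20)
  set.seed(34)
  calc <- saxs_debye(random_points(12), q)
  self <- fit_saxs(calc, calc)
  expect_equal(self$chi2, 0, tolerance = 1e-12)
  expect_equal(self$scale, 1, tolerance = 1e-12)
  doubled <- saxs_profile(q, 2 * calc$intensity)
  fit2 <- fit_saxs(calc, doubled)
  expect_equal(fit2$chi2, 0, tolerance = 1e-12)
  expect_equal(fit2$scale, 2, tolerance = 1e-12)

  # frozen hand evaluation of the closed form: calc (1,2,3), exp (2,3,4)
  cp <- saxs_profile(c(0.1, 0.2, 0.3), c(1, 2, 3))
  ep <- saxs_profile(c(0.1, 0.2, 0.3), c(2, 3, 4), sigma = c(1, 1, 1))
  fit <- fit_saxs(cp, ep)
  expect_equal(fit$scale, 20 / 14, tolerance = 1e-12)
  expect_equal(fit$chi2,
               sum((20 / 14 * c(1, 2, 3) - c(2, 3, 4))^2) / 2,
               tolerance = 1e-12)

  expect_error(fit_saxs(cp, saxs_profile(0.1, 5)), "at least 2")
  zero <- saxs_profile(c(0.1, 0.2, 0.3), c(0, 0, 0))
  expect_error(fit_saxs(zero, ep), "scale undefined")
})

test_that("pseudocontact shifts follow the dipolar closed form", {
  ctr <- paramagnetic_center(delta_chi_ax = 2.0, delta_chi_rh = 0)
  # oracle: 1/(12 pi r^3) * dchi_ax * 2 * 1e6 at theta = 0, r = 10 A
  expect_equal(pcs_shift(c(0, 0, 10), ctr),
               (1 / (12 * pi * (1e-9)^3)) * 2e-32 * 2 * 1e6,
               tolerance = 1e-12)
  expect_equal(pcs_shift(c(0, 0, 10), ctr), 1.061, tolerance = 1e-3)
  # magic angle zero
  th <- 54.7356103 * pi / 180
  expect_lt(abs(pcs_shift(10 * c(sin(th), 0, cos(th)), ctr)), 1e-9)
  # r^-3 law
  expect_equal(pcs_shift(c(0, 0, 10), ctr) / pcs_shift(c(0, 0, 20), ctr), 8,
               tolerance = 1e-12)
  expect_error(pcs_shift(c(0, 0, 0), ctr), "coincides")
})

test_that("the shift tensor is traceless on angular average", {
  ctr <- paramagnetic_center(delta_chi_ax = 2.0, delta_chi_rh = 0.8)
  set.seed(35)
  n <- 4000
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  shifts <- apply(10 * dirs, 1, pcs_shift, center = ctr)
  expect_lt(abs(mean(shifts)), 3 * sd(shifts) / sqrt(n))
})

test_that("rhombic tensors beyond the axial bound warn", {
  expect_warning(paramagnetic_center(delta_chi_ax = 1, delta_chi_rh = 2),
                 "unconventional")
})

test_that("spectrum traces are unit-area Lorentzians centred on the shift", {
  grid <- seq(-5, 5, length.out = 2001)
  tr <- pcs_spectrum(0, linewidth = 0.1, ppm_grid = grid)
  expect_equal(tr$intensity, rev(tr$intensity), tolerance = 1e-12)
  area <- sum(diff(grid) * (tr$intensity[-1] + tr$intensity[-2001]) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  for (shift in c(-2.2, -0.4, 1.3)) {
    tr <- pcs_spectrum(shift, linewidth = 0.1, ppm_grid = grid)
    expect_equal(grid[which.max(tr$intensity)], shift, tolerance = 0.006)
  }
  expect_error(pcs_spectrum(0, 0.1, numeric(0)), "non-empty")
  expect_error(pcs_spectrum(0, -1, grid), "> 0")
})

test_that("contact scoring maps distance to width and satisfaction", {
  hx <- coarse_grain(generate_fixture("toy_helix", list(chain = "A")))
  hy <- coarse_grain(generate_fixture("toy_helix", list(chain = "B",
                                                        id = "helix_b")))
  mk_scene <- function(sep) assemble_scene(list(
    anchored_molecule(hx, id = "A"),
    anchored_molecule(hy, pose = pose(translation = c(sep, 0, 0)), id = "B")))
  contacts <- data.frame(chain_a = "A", res_a = c(1L, 2L, 3L),
                         chain_b = "B", res_b = c(1L, 2L, 3L),
                         tier = c("low", "high", "intermediate"),
                         score = NA_real_)
  near <- score_contacts(contacts, mk_scene(5), d_sat = 8, w_min = 1)
  expect_true(all(near$per_contact$satisfied |
                    near$per_contact$distance > 8))
  sat <- near$per_contact[near$per_contact$satisfied, ]
  expect_true(all(sat$width == 1))
  # report ordering: high, intermediate, low
  expect_equal(unique(near$per_contact$tier)[
    order(match(unique(near$per_contact$tier),
                c("high", "intermediate", "low")))],
    unique(near$per_contact$tier))
  far <- score_contacts(contacts, mk_scene(30), d_sat = 8, w_min = 1)
  expect_true(all(far$per_contact$width >= near$per_contact$width))
  expect_true(all(diff(order(far$per_contact$distance)) != 0))
  mid <- score_contacts(contacts, mk_scene(18))
  expect_true(all(mid$per_contact$width <= far$per_contact$width))
  bad <- data.frame(chain_a = "Z", res_a = 1L, chain_b = "B", res_b = 1L,
                    tier = "high", score = NA_real_)
  expect_error(score_contacts(bad, mk_scene(5)), "Z:1")
})

test_that("a noiseless synthetic target is recovered only at its pose", {
  fx <- generate_fixture("synthetic_saxs_target", list(sigma = 0), seed = 17)
  chi_true <- fit_saxs(saxs_debye(fx$scene, fx$q_grid), fx$profile)$chi2
  expect_lt(chi_true, 1e-10)
  for (shift in list(c(5, 0, 0), c(0, 7, 0), c(-6, 3, 2))) {
    disp <- pose(rotation = fx$true_pose$q,
                 translation = fx$true_pose$translation + shift)
    sc <- assemble_scene(list(
      anchored_molecule(fx$domain_a, 1L, id = "A"),
      anchored_molecule(fx$domain_b, 1L, pose = disp, id = "B")))
    chi_disp <- fit_saxs(saxs_debye(sc, fx$q_grid), fx$profile)$chi2
    expect_gt(chi_disp, chi_true + 1e-6)
  }
})
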