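coords_of <- function(s, i) as.numeric(s$atoms[i, c("x", "y", "z")])

test_that("read_pdb reads atoms back identically, in file order", {
  path <- write_fixture_pdb(c(
    pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "C2", "LIG", "A", 1, 1.5, 0, 0)))
  s <- read_pdb(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(0, 1.5))
  expect_equal(s$atoms$serial, c(1, 2))
  expect_equal(sqrt(sum((coords_of(s, 2) - coords_of(s, 1))^2)), 1.5)
})

test_that("altloc policies keep one conformer", {
  path <- write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.5, 0, 0, occ = 0.6, alt = "B")))
  first <- read_pdb(path, altloc = "first")
  expect_equal(nrow(first$atoms), 1)
  expect_equal(first$atoms$x, 0)
  best <- read_pdb(path, altloc = "occupancy")
  expect_equal(nrow(best$atoms), 1)
  expect_equal(best$atoms$x, 0.5)
  expect_equal(nrow(read_pdb(path, altloc = "all")$atoms), 2)
})

test_that("hexaglycine fixture round-trips through the PDB layer", {
  hexa <- generate_fixture("hexaglycine_linker")
  path <- tempfile(fileext = ".pdb")
  write_pdb(hexa, path)
  back <- read_pdb(path)
  expect_equal(nrow(back$atoms), 6)
  expect_equal(back$atoms$resno, 1:6)
  d <- diff(back$atoms$x)
  expect_equal(d, rep(3.8, 5), tolerance = 1e-6)
})

test_that("read_pdb errors are specific", {
  expect_error(read_pdb(tempfile()), "not found")
  empty <- write_fixture_pdb("REMARK nothing here")
  expect_error(read_pdb(empty), "no ATOM/HETATM")
  bad <- write_fixture_pdb(c(
    pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0),
    sub("   0.000", "  xx.yyy", pdb_atom_line(2, "C2", "LIG", "A", 1, 0, 0, 0))))
  expect_error(read_pdb(bad), "line")
})

test_that("CONECT records define bonds; otherwise bonds are inferred", {
  fx <- generate_fixture("lys_glu_pair")
  path <- tempfile(fileext = ".pdb")
  write_pdb(fx$lys, path, conect = TRUE)
  back <- read_pdb(path)
  expect_equal(nrow(back$bonds), nrow(fx$lys$bonds))
  # without CONECT, the 1.5 A chain is recovered from covalent radii
  write_pdb(fx$glu, path, conect = FALSE)
  inferred <- read_pdb(path)
  expect_true(all(apply(fx$glu$bonds, 1, function(b)
    any(inferred$bonds[, 1] == b[1] & inferred$bonds[, 2] == b[2]))))
})

test_that("apply_pose matches its defining formula and is an isometry", {
  pts <- rbind(c(0, 0, 0), c(1, 2, 3), c(-2, 1, 0.5))
  expect_equal(apply_pose(pts, pose()), pts)
  shifted <- apply_pose(pts, pose(translation = c(10, 0, 0)))
  expect_equal(shifted, sweep(pts, 2, c(10, 0, 0), "+"))
  set.seed(42)
  for (rep in 1:10) {
    q <- drop(random_quaternion(1))
    p <- pose(rotation = q, translation = rnorm(3))
    pts <- random_points(20)
    out <- apply_pose(pts, p, anchor = rnorm(3))
    expect_lt(max(abs(pairwise_dists(out) - pairwise_dists(pts))), 1e-9)
  }
  # pairwise distances scale by exactly `scale`
  p2 <- pose(scale = 2.5)
  expect_equal(pairwise_dists(apply_pose(pts, p2)),
               2.5 * pairwise_dists(pts), tolerance = 1e-12)
  expect_error(pose(rotation = c(1, 1, 0, 0)), "unit")
})

test_that("interpolate_pose hits its endpoints and midpoints", {
  set.seed(1)
  a <- pose(rotation = drop(random_quaternion(1)), translation = c(0, 0, 0))
  b <- pose(rotation = drop(random_quaternion(1)), translation = c(10, 0, 0))
  expect_equal(interpolate_pose(a, b, 0)$translation, a$translation)
  expect_equal(max(abs(interpolate_pose(a, b, 0)$R - a$R)), 0, tolerance = 1e-12)
  expect_equal(max(abs(interpolate_pose(a, b, 1)$R - b$R)), 0, tolerance = 1e-12)
  mid <- interpolate_pose(a, a, 0.5)
  expect_equal(mid$translation, a$translation)
  eqrot <- interpolate_pose(pose(translation = c(0, 0, 0)),
                            pose(translation = c(10, 0, 0)), 0.5)
  expect_equal(eqrot$translation, c(5, 0, 0))
  expect_error(interpolate_pose(a, b, 1.2), "\\[0, 1\\]")
})

test_that("assemble_scene pins anchors to pose translations", {
  hx <- generate_fixture("toy_helix")
  p <- pose(rotation = drop(random_quaternion(1)), translation = c(5, -3, 2))
  scene <- assemble_scene(anchored_molecule(hx, anchor_index = 3L, pose = p))
  anchor_world <- as.numeric(scene$table[scene$table$site == 3,
                                         c("x", "y", "z")])
  expect_lt(max(abs(anchor_world - p$translation)), 1e-9)

  # two molecules 40 A apart cannot approach closer than 40 minus the radii
  s2 <- assemble_scene(list(
    anchored_molecule(hx, id = "a"),
    anchored_molecule(hx, pose = pose(translation = c(40, 0, 0)), id = "b")))
  ca <- as.matrix(s2$table[s2$table$molecule == "a", c("x", "y", "z")])
  cb <- as.matrix(s2$table[s2$table$molecule == "b", c("x", "y", "z")])
  diam <- 2 * max(sqrt(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  mind <- min(as.matrix(dist(rbind(ca, cb)))[seq_len(nrow(ca)),
                                             nrow(ca) + seq_len(nrow(cb))])
  expect_gte(mind, 40 - diam)

  # continuity under a 1e-12 pose perturbation
  p_eps <- pose(rotation = p$q, translation = p$translation + 1e-12)
  s_eps <- assemble_scene(anchored_molecule(hx, anchor_index = 3L,
                                            pose = p_eps))
  expect_lt(max(abs(as.matrix(s_eps$table[, c("x", "y", "z")]) -
                      as.matrix(scene$table[, c("x", "y", "z")]))), 1e-9)
  expect_error(anchored_molecule(hx, anchor_index = 999L), "out of range")
})

test_that("SAXS profile text IO round-trips", {
  path <- tempfile()
  writeLines(c("# q I sigma", "0.01 100 1", "0.02 90 1", "0.03 80 1"), path)
  prof <- read_saxs_profile(path)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$q, c(0.01, 0.02, 0.03))
  expect_equal(prof$sigma, rep(1, 3))

  out <- saxs_profile(seq(0.02, 0.4, length.out = 25),
                      exp(-seq(0.02, 0.4, length.out = 25)) * 100)
  p2 <- tempfile()
  write_saxs_profile(out, p2, header = "round trip")
  back <- read_saxs_profile(p2)
  expect_equal(back$q, out$q, tolerance = 1e-12)
  expect_equal(back$intensity, out$intensity, tolerance = 1e-12)

  writeLines(c("-0.01 5", "0.01 100", "0.03 80", "0.02 90"), path)
  expect_warning(expect_message(prof <- read_saxs_profile(path), "dropped 1"),
                 "sorting")
  expect_equal(prof$q, c(0.01, 0.02, 0.03))
  writeLines("0.01", path)
  expect_error(read_saxs_profile(path), "2 numeric columns")
})

test_that("contact tables parse labels and bin scores", {
  path <- tempfile()
  writeLines("A\t10\tB\t20\thigh", path)
  ct <- read_contact_table(path)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$tier, "high")
  expect_equal(ct$res_a, 10L)

  writeLines(character(0), path)
  expect_equal(nrow(read_contact_table(path)), 0)

  writeLines(c("A 1 B 2 0.95", "A 3 B 4 0.85", "A 5 B 6 0.5"), path)
  ct <- read_contact_table(path)
  expect_equal(sum(ct$tier == "high"), 2)
  expect_equal(sum(ct$tier != "high"), 1)

  writeLines("A 1 B 2 bogus_tier", path)
  expect_error(read_contact_table(path), "unknown contact tier")
})

test_that("pose trajectories round-trip", {
  traj <- data.frame(frame = c(1L, 1L, 2L), molecule = c("a", "b", "a"),
                     qw = 1, qx = 0, qy = 0, qz = 0,
                     tx = c(0, 40, 1), ty = 0, tz = 0, scale = 1)
  path <- tempfile()
  write_pose_trajectory(traj, path)
  back <- read_pose_trajectory(path)
  expect_equal(back$tx, traj$tx, tolerance = 1e-12)
  expect_equal(back$molecule, traj$molecule)
})

test_that("fixtures are deterministic under a fixed seed", {
  a <- generate_fixture("synthetic_saxs_target", seed = 11)
  b <- generate_fixture("synthetic_saxs_target", seed = 11)
  expect_identical(a$profile$intensity, b$profile$intensity)
  expect_identical(a$true_pose$q, b$true_pose$q)
  expect_error(generate_fixture("not_a_kind"), "arg")
})
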