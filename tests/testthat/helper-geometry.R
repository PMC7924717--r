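# shared geometric helpers for the suite

random_points <- function(n, spread = 10) {
  matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
}

pairwise_dists <- function(p) as.numeric(dist(p))

# torsion angle (degrees) of four points; independent of the package code
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# minimal hand-rolled PDB writer for parser fixtures (independent of the
# package's write_pdb)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, x, y, z, occ, 0, element)
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
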