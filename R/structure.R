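#' Atomistic structure container
#'
#' A light S3 container for an atomistic molecule: an ordered atom table
#' (order preserved from the source file) plus an explicit bond list.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `icode`, `chain`, `x`, `y`, `z`, `charge`, `occ`.
#' @param bonds two-column integer matrix of atom indices (1-based), or NULL.
#' @param id identifier string.
#' @return object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, bonds = NULL, id = "mol") {
  required <- c("serial", "name", "element", "resname", "resno", "icode",
                "chain", "x", "y", "z", "charge", "occ")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > n)) stop("bond indices out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, id = id),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("mol_structure '%s': %d atoms, %d bonds, %d residues\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              length(unique(residue_key(x$atoms)))))
  invisible(x)
}

coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
}

# Covalent radii (Angstrom) used for distance-based bond inference;
# Cordero et al. consensus values for the elements common in biomolecules.
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  FE = 1.32, ZN = 1.22, MG = 1.41, CA = 1.76, MN = 1.39, CU = 1.32,
  "NA" = 1.66, K = 2.03, B = 0.84
)

covalent_radius <- function(element) {
  r <- .covalent_radii[toupper(element)]
  r[is.na(r)] <- 0.77  # fall back to a carbon-like radius
  unname(r)
}

#' Infer bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of covalent
#' radii plus a 0.4 Angstrom slack. Used when a PDB file carries no CONECT
#' records.
#'
#' @param atoms atom table (see [mol_structure()]).
#' @param slack additive cutoff slack in Angstrom.
#' @return two-column integer matrix of bonded index pairs.
#' @export
infer_bonds <- function(atoms, slack = 0.4) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- covalent_radius(atoms$element)
  cutoff <- outer(r, r, "+") + slack
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  hit <- hit[d[hit] > 0.1, , drop = FALSE]  # guard against duplicated atoms
  matrix(as.integer(hit), ncol = 2)
}

#' Read a PDB file
#'
#' Parses ATOM and HETATM records (through bio3d) into a [mol_structure()],
#' preserving file order and coordinates exactly as written. CONECT records,
#' when present, define the bond list; otherwise bonds are inferred from an
#' element-dependent distance cutoff (see [infer_bonds()]).
#'
#' @param path PDB file path.
#' @param altloc policy for alternate locations: `"occupancy"` keeps the
#'   highest-occupancy conformer (ties broken by file order), `"first"` keeps
#'   the first conformer seen, `"all"` keeps everything.
#' @param hydrogens keep hydrogen atoms (default TRUE).
#' @param infer_bonds_if_missing infer bonds when no CONECT records exist.
#' @return a [mol_structure()].
#' @export
read_pdb <- function(path, altloc = c("occupancy", "first", "all"),
                     hydrogens = TRUE, infer_bonds_if_missing = TRUE) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(atom_lines))
    stop("no ATOM/HETATM records in ", path)
  # coordinate sanity check with line provenance before handing to bio3d
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop(sprintf("truncated atom record at line %d", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("non-numeric coordinate field at line %d: '%s'", i, ln))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) elem[blank] <- guess_element(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = toupper(trimws(elem)),
    resname = trimws(at$resid),
    resno = at$resno,
    icode = ifelse(is.na(at$insert) | !nzchar(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), "", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge = 0,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | !nzchar(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  if (altloc != "all" && any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
    keep <- rep(TRUE, nrow(atoms))
    for (k in unique(key[nzchar(atoms$alt)])) {
      idx <- which(key == k)
      if (length(idx) < 2) next
      pick <- if (altloc == "occupancy") idx[which.max(atoms$occ[idx])] else idx[1]
      keep[setdiff(idx, pick)] <- FALSE
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (!hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  rownames(atoms) <- NULL

  conect <- grep("^CONECT", lines, value = TRUE)
  bonds <- NULL
  if (length(conect)) {
    serial_to_idx <- stats::setNames(seq_len(nrow(atoms)), atoms$serial)
    pairs <- list()
    for (ln in conect) {
      f <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", ln)),
                                                "\\s+")[[1]]))
      f <- f[!is.na(f)]
      if (length(f) < 2) next
      a <- serial_to_idx[as.character(f[1])]
      b <- serial_to_idx[as.character(f[-1])]
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) pairs[[length(pairs) + 1L]] <- cbind(a, b[ok])
    }
    if (length(pairs)) bonds <- do.call(rbind, pairs)
  } else if (infer_bonds_if_missing) {
    bonds <- infer_bonds(atoms)
  }
  atoms$alt <- NULL
  mol_structure(atoms, bonds,
                id = sub("\\.pdb$", "", basename(path), ignore.case = TRUE))
}

guess_element <- function(name) {
  name <- trimws(name)
  two <- toupper(substr(name, 1, 2))
  one <- toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "CL", "BR", "SE"), two,
         ifelse(nzchar(one), one, "C"))
}

#' Write a minimal PDB file
#'
#' Writes ATOM records (and CONECT records for explicit bonds) for a
#' [mol_structure()]. Intended for fixtures and round-trip tests, not as a
#' full-dialect PDB writer.
#'
#' @param structure a [mol_structure()].
#' @param path output file path.
#' @param conect write CONECT records for the bond list.
#' @export
write_pdb <- function(structure, path, conect = TRUE) {
  at <- structure$atoms
  fmt <- "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  name4 <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
  recs <- sprintf(fmt, at$serial, name4, at$resname,
                  ifelse(nzchar(at$chain), at$chain, "A"),
                  at$resno, ifelse(nzchar(at$icode), at$icode, " "),
                  at$x, at$y, at$z, at$occ, 0, at$element)
  if (conect && nrow(structure$bonds)) {
    nb <- split(c(structure$bonds[, 2], structure$bonds[, 1]),
                c(structure$bonds[, 1], structure$bonds[, 2]))
    crecs <- vapply(names(nb), function(i) {
      paste0("CONECT", sprintf("%5d", at$serial[as.integer(i)]),
             paste(sprintf("%5d", at$serial[sort(nb[[i]])]), collapse = ""))
    }, character(1))
    recs <- c(recs, crecs)
  }
  writeLines(c(recs, "END"), path)
  invisible(path)
}
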