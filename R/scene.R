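# van der Waals radii (Angstrom, Bondi-style) for display/clash radii of
# atomistic models.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                FE = 1.40, ZN = 1.39, MG = 1.73)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Tabular view of a molecule's sites
#'
#' Returns one row per renderable/physical site: atoms for a
#' [mol_structure()] (with van der Waals radii), beads for a [bead_model()].
#'
#' @param x a `mol_structure` or `bead_model`.
#' @return data.frame with columns `x`, `y`, `z`, `radius`, `name`,
#'   `element`, `resname`, `resno`, `icode`, `chain`, `kind`, `class`,
#'   `charge`.
#' @export
model_frame <- function(x) UseMethod("model_frame")

#' @export
model_frame.mol_structure <- function(x) {
  at <- x$atoms
  data.frame(x = at$x, y = at$y, z = at$z,
             radius = vdw_radius(at$element),
             name = at$name, element = at$element,
             resname = at$resname, resno = at$resno, icode = at$icode,
             chain = at$chain, kind = "atom",
             class = tolower(at$element), charge = at$charge,
             stringsAsFactors = FALSE)
}

#' @export
model_frame.bead_model <- function(x) {
  b <- x$beads
  data.frame(x = b$x, y = b$y, z = b$z, radius = b$radius,
             name = paste0(b$kind, "_", b$resno),
             element = "", resname = b$resname, resno = b$resno,
             icode = b$icode, chain = b$chain, kind = b$kind,
             class = b$class, charge = 0,
             stringsAsFactors = FALSE)
}

model_bonds <- function(x) {
  if (inherits(x, "mol_structure")) x$bonds else
    if (inherits(x, "bead_model")) x$bonds else matrix(integer(0), ncol = 2)
}

#' Anchor a molecule to a pose
#'
#' Ties a molecule to a 6-DOF pose through one of its sites (typically the
#' alpha carbon): after scene assembly the anchor site sits exactly at the
#' pose translation.
#'
#' @param molecule a [mol_structure()] or [bead_model()].
#' @param anchor_index 1-based site index used as the anchor.
#' @param pose a [pose()].
#' @param id molecule identifier within the scene.
#' @return object of class `anchored_molecule`.
#' @export
anchored_molecule <- function(molecule, anchor_index = 1L,
                              pose = molscene::pose(), id = NULL) {
  mf <- model_frame(molecule)
  anchor_index <- as.integer(anchor_index)
  if (anchor_index < 1L || anchor_index > nrow(mf))
    stop(sprintf("anchor index %d out of range (1..%d)", anchor_index, nrow(mf)))
  if (is.null(id)) id <- if (!is.null(molecule$id)) molecule$id else "mol"
  structure(list(molecule = molecule, anchor_index = anchor_index,
                 pose = pose, id = id),
            class = "anchored_molecule")
}

#' Assemble a multi-molecule scene
#'
#' Applies each molecule's pose (rotation + translation; the zoom factor is
#' deliberately not applied, so downstream physics and observables always see
#' world coordinates in Angstrom) with the molecule's anchor site as the
#' rotation centre.
#'
#' @param molecules list of [anchored_molecule()] objects.
#' @return object of class `mol_scene`: `$table` is one data.frame over all
#'   molecules with world coordinates, radii and site labels (column
#'   `molecule` identifies the source), `$molecules` keeps the inputs.
#' @export
assemble_scene <- function(molecules) {
  if (inherits(molecules, "anchored_molecule")) molecules <- list(molecules)
  if (!length(molecules)) stop("scene needs at least one molecule")
  parts <- lapply(molecules, function(am) {
    stopifnot(inherits(am, "anchored_molecule"))
    mf <- model_frame(am$molecule)
    local <- as.matrix(mf[, c("x", "y", "z")])
    anchor <- local[am$anchor_index, ]
    world <- apply_pose(local, am$pose, anchor = anchor, apply_scale = FALSE)
    mf$x <- world[, 1]; mf$y <- world[, 2]; mf$z <- world[, 3]
    cbind(molecule = am$id, site = seq_len(nrow(mf)), mf,
          stringsAsFactors = FALSE)
  })
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("molecule ids within a scene must be unique")
  names(molecules) <- ids
  structure(list(molecules = molecules, table = do.call(rbind, parts)),
            class = "mol_scene")
}

#' @export
print.mol_scene <- function(x, ...) {
  cat(sprintf("mol_scene: %d molecules, %d sites\n",
              length(x$molecules), nrow(x$table)))
  invisible(x)
}

scene_coords <- function(scene, molecule = NULL) {
  tab <- scene$table
  if (!is.null(molecule)) tab <- tab[tab$molecule == molecule, , drop = FALSE]
  as.matrix(tab[, c("x", "y", "z")])
}
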