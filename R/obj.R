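# Wavefront OBJ+MTL export of ball-and-stick scenes: one icosphere per
# site, one open cylinder per bond, one material per colour class. This is
# the only place where a pose's zoom factor is honoured.

.class_palette <- list(
  backbone = c(0.05, 0.05, 0.05),
  hydrophobic = c(0.6, 0.6, 0.6),
  negative = c(0.85, 0.1, 0.1),
  positive = c(0.1, 0.2, 0.85),
  polar = c(0.1, 0.7, 0.2),
  linker = c(0.95, 0.55, 0.1),
  bond = c(0.4, 0.4, 0.4),
  # element classes for atomistic models
  c = c(0.35, 0.35, 0.35), n = c(0.2, 0.2, 0.9), o = c(0.9, 0.15, 0.15),
  h = c(0.95, 0.95, 0.95), s = c(0.9, 0.8, 0.15), p = c(1.0, 0.5, 0.0),
  fe = c(0.8, 0.45, 0.1)
)

icosphere_mesh <- function(center = c(0, 0, 0), radius = 1, subdivisions = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  if (subdivisions > 0) {
    for (s in seq_len(subdivisions)) {
      midpoint <- new.env(parent = emptyenv())
      get_mid <- function(a, b) {
        key <- paste(min(a, b), max(a, b))
        if (!is.null(midpoint[[key]])) return(midpoint[[key]])
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        midpoint[[key]] <- nrow(v)
        nrow(v)
      }
      nf <- matrix(0L, 0, 3)
      for (k in seq_len(nrow(f))) {
        a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
        ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
        nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
      }
      f <- nf
    }
  }
  list(vertices = sweep(v * radius, 2, center, "+"), normals = v, faces = f)
}

cylinder_mesh <- function(p1, p2, radius = 0.2, segments = 12) {
  axis <- p2 - p1
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) stop("degenerate cylinder")
  az <- axis / len
  ref <- if (abs(az[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ax <- ref - sum(ref * az) * az; ax <- ax / sqrt(sum(ax^2))
  ay <- c(az[2] * ax[3] - az[3] * ax[2],
          az[3] * ax[1] - az[1] * ax[3],
          az[1] * ax[2] - az[2] * ax[1])
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- t(vapply(th, function(a) cos(a) * ax + sin(a) * ay, numeric(3)))
  v <- rbind(sweep(ring * radius, 2, p1, "+"),
             sweep(ring * radius, 2, p2, "+"))
  n <- rbind(ring, ring)
  f <- matrix(0L, 0, 3)
  for (k in seq_len(segments)) {
    k2 <- if (k == segments) 1L else k + 1L
    f <- rbind(f,
               c(k, k + segments, k2),
               c(k2, k + segments, k2 + segments))
  }
  list(vertices = v, normals = n, faces = f)
}

#' Export a scene as Wavefront OBJ + MTL ball-and-stick meshes
#'
#' Writes `<path_prefix>.obj` (icosphere per site, open cylinder per bond,
#' one `o` object per primitive) and `<path_prefix>.mtl` (one material per
#' colour class). Poses' zoom factors are applied here, scaling positions
#' and radii about each molecule's anchor; everything upstream of export
#' stays in Angstrom.
#'
#' @param scene a [mol_scene()].
#' @param path_prefix output path without extension.
#' @param subdivisions icosphere subdivision level (0 = icosahedron,
#'   12 vertices / 20 faces).
#' @param bond_radius cylinder radius (pre-zoom), Angstrom.
#' @param segments cylinder cross-section segments.
#' @return (invisibly) list `obj`, `mtl` (paths), `vertices`, `faces`,
#'   `objects` (totals written) -- the writer's report used in round-trip
#'   checks.
#' @export
write_obj_ballstick <- function(scene, path_prefix, subdivisions = 1,
                                bond_radius = 0.25, segments = 12) {
  stopifnot(inherits(scene, "mol_scene"))
  obj_path <- paste0(path_prefix, ".obj")
  mtl_path <- paste0(path_prefix, ".mtl")
  lines <- c("# molscene ball-and-stick export",
             paste0("mtllib ", basename(mtl_path)))
  used_mat <- character(0)
  v_off <- 0L; n_obj <- 0L; n_face <- 0L
  emit <- function(mesh, name, material) {
    lines <<- c(lines, paste0("o ", name))
    lines <<- c(lines, sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                               mesh$vertices[, 2], mesh$vertices[, 3]))
    lines <<- c(lines, sprintf("vn %.6f %.6f %.6f", mesh$normals[, 1],
                               mesh$normals[, 2], mesh$normals[, 3]))
    lines <<- c(lines, paste0("usemtl ", material))
    fidx <- mesh$faces + v_off
    lines <<- c(lines, sprintf("f %d//%d %d//%d %d//%d",
                               fidx[, 1], fidx[, 1], fidx[, 2], fidx[, 2],
                               fidx[, 3], fidx[, 3]))
    v_off <<- v_off + nrow(mesh$vertices)
    n_obj <<- n_obj + 1L
    n_face <<- n_face + nrow(mesh$faces)
    used_mat <<- union(used_mat, material)
  }
  for (am in scene$molecules) {
    mf <- model_frame(am$molecule)
    local <- as.matrix(mf[, c("x", "y", "z")])
    anchor <- local[am$anchor_index, ]
    world <- apply_pose(local, am$pose, anchor = anchor, apply_scale = TRUE)
    zoom <- am$pose$scale
    for (i in seq_len(nrow(mf))) {
      cls <- mf$class[i]
      if (!cls %in% names(.class_palette)) cls <- "hydrophobic"
      emit(icosphere_mesh(world[i, ], mf$radius[i] * zoom, subdivisions),
           sprintf("%s_site%d", am$id, i), cls)
    }
    bonds <- model_bonds(am$molecule)
    for (k in seq_len(nrow(bonds))) {
      emit(cylinder_mesh(world[bonds[k, 1], ], world[bonds[k, 2], ],
                         radius = bond_radius * zoom, segments = segments),
           sprintf("%s_bond%d", am$id, k), "bond")
    }
  }
  writeLines(lines, obj_path)
  mtl <- unlist(lapply(used_mat, function(m) {
    rgb <- .class_palette[[m]]
    c(paste0("newmtl ", m),
      sprintf("Kd %.3f %.3f %.3f", rgb[1], rgb[2], rgb[3]),
      "Ka 0.05 0.05 0.05", "Ks 0.2 0.2 0.2", "Ns 40", "")
  }))
  writeLines(mtl, mtl_path)
  invisible(list(obj = obj_path, mtl = mtl_path, vertices = v_off,
                 faces = n_face, objects = n_obj))
}
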