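# Pseudocontact shifts from a paramagnetic centre with an anisotropic
# magnetic susceptibility tensor, plus a Lorentzian spectrum trace.

#' Paramagnetic centre definition
#'
#' @param position 3-vector, Angstrom (e.g. the heme iron).
#' @param frame 3x3 orthonormal matrix whose columns are the susceptibility
#'   tensor axes (third column = unique z axis).
#' @param delta_chi_ax,delta_chi_rh axial and rhombic anisotropies of the
#'   magnetic susceptibility tensor, in units of 1e-32 m^3 (the conventional
#'   literature scale).
#' @return list of class `paramagnetic_center`.
#' @export
paramagnetic_center <- function(position = c(0, 0, 0), frame = diag(3),
                                delta_chi_ax = 2.0, delta_chi_rh = 0) {
  frame <- as.matrix(frame)
  if (!all(dim(frame) == c(3, 3)) || max(abs(crossprod(frame) - diag(3))) > 1e-9)
    stop("frame must be a 3x3 orthonormal axis matrix")
  if (abs(delta_chi_rh) > 1.5 * abs(delta_chi_ax) + 1e-12)
    warning("|delta_chi_rh| exceeds (3/2)|delta_chi_ax|; unconventional tensor")
  structure(list(position = as.numeric(position), frame = frame,
                 delta_chi_ax = delta_chi_ax, delta_chi_rh = delta_chi_rh),
            class = "paramagnetic_center")
}

#' Pseudocontact shift at a probe position
#'
#' Standard dipolar equation: with `(r, theta, phi)` the probe's spherical
#' coordinates in the tensor frame (theta from the unique axis),
#' `d_delta = 1/(12 pi r^3) * (dchi_ax (3 cos^2 theta - 1)
#'  + 3/2 dchi_rh sin^2 theta cos 2 phi)`, reported in ppm (r in metres,
#' anisotropies in m^3).
#'
#' @param probe 3-vector probe position, Angstrom.
#' @param center a [paramagnetic_center()].
#' @return shift in ppm.
#' @export
pcs_shift <- function(probe, center) {
  stopifnot(inherits(center, "paramagnetic_center"))
  v <- as.numeric(probe) - center$position
  r_A <- sqrt(sum(v^2))
  if (r_A < 1e-9) stop("probe coincides with the paramagnetic centre")
  u <- drop(crossprod(center$frame, v))   # tensor-frame coordinates
  r_m <- r_A * 1e-10
  cos_t <- u[3] / r_A
  sin2_t <- max(0, 1 - cos_t^2)
  phi <- atan2(u[2], u[1])
  ax <- center$delta_chi_ax * 1e-32
  rh <- center$delta_chi_rh * 1e-32
  (1 / (12 * pi * r_m^3)) *
    (ax * (3 * cos_t^2 - 1) + 1.5 * rh * sin2_t * cos(2 * phi)) * 1e6
}

#' Lorentzian spectrum trace for a shifted resonance
#'
#' Unit-area Lorentzian centred at `reference_shift + shift`, evaluated on a
#' ppm grid: the real-time "spectrum" panel fed by [pcs_shift()].
#'
#' @param shift pseudocontact shift, ppm.
#' @param linewidth full width at half maximum, ppm, > 0.
#' @param ppm_grid numeric grid of chemical-shift values.
#' @param reference_shift diamagnetic reference position, ppm (default 0).
#' @return data.frame `ppm`, `intensity` (unit area under the full line).
#' @export
pcs_spectrum <- function(shift, linewidth, ppm_grid, reference_shift = 0) {
  if (!length(ppm_grid)) stop("ppm grid must be non-empty")
  if (!is.numeric(linewidth) || linewidth <= 0) stop("linewidth must be > 0")
  x0 <- reference_shift + shift
  gamma <- linewidth / 2
  y <- (1 / pi) * gamma / ((ppm_grid - x0)^2 + gamma^2)
  data.frame(ppm = ppm_grid, intensity = y)
}
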