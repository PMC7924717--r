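#' SAXS profile container
#'
#' @param q scattering vector grid, Angstrom^-1, strictly increasing, > 0.
#' @param intensity intensities, arbitrary units, same length as `q`.
#' @param sigma optional per-point errors (same units as intensity).
#' @return data.frame of class `saxs_profile` with columns `q`, `intensity`
#'   and optionally `sigma`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q grid must be finite and positive")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  out <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length differs from q")
    out$sigma <- sigma
  }
  class(out) <- c("saxs_profile", "data.frame")
  out
}

#' Read a plain-text SAXS profile
#'
#' Accepts whitespace- or comma-delimited text with 2 or 3 numeric columns
#' (q, I and optionally sigma); lines starting with `#` are comments. Rows
#' with non-positive q are dropped (with a message); a non-ascending grid is
#' sorted with a warning.
#'
#' @param path file path.
#' @return a [saxs_profile()].
#' @export
read_saxs_profile <- function(path) {
  if (!file.exists(path)) stop("SAXS profile not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no data rows in ", path)
  rows <- lapply(lines, function(ln) {
    suppressWarnings(as.numeric(strsplit(ln, "[,[:space:]]+")[[1]]))
  })
  ncols <- vapply(rows, length, integer(1))
  if (any(ncols < 2)) stop("SAXS profile needs at least 2 numeric columns")
  k <- min(ncols, 3)
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(k)]))
  if (any(is.na(m))) stop("non-numeric field in SAXS profile ", path)
  drop <- m[, 1] <= 0
  if (any(drop)) {
    message(sprintf("read_saxs_profile: dropped %d rows with non-positive q",
                    sum(drop)))
    m <- m[!drop, , drop = FALSE]
  }
  if (is.unsorted(m[, 1], strictly = TRUE)) {
    warning("q grid not strictly ascending; sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
    m <- m[!duplicated(m[, 1]), , drop = FALSE]
  }
  saxs_profile(m[, 1], m[, 2], if (k == 3) m[, 3])
}

#' Write a SAXS profile as plain text
#'
#' @param profile a [saxs_profile()].
#' @param path output path.
#' @param header optional comment lines (written with `#` prefixes).
#' @export
write_saxs_profile <- function(profile, path, header = NULL) {
  cols <- c("q", "intensity", if ("sigma" %in% names(profile)) "sigma")
  body <- do.call(paste, c(lapply(cols, function(cn)
    sprintf("%.17g", profile[[cn]])), sep = "\t"))
  lines <- c(if (!is.null(header)) paste0("# ", header),
             paste0("# ", paste(cols, collapse = "\t")), body)
  writeLines(lines, path)
  invisible(path)
}

.contact_tiers <- c("high", "intermediate", "low")

#' Read a residue-pair contact table
#'
#' Tab/whitespace-separated rows `chain_a res_a chain_b res_b tier_or_score`,
#' as exported from coevolution servers. A fifth column holding a number is
#' binned into confidence tiers by `thresholds`; an explicit tier label
#' (`high`/`intermediate`/`low`) passes through.
#'
#' @param path file path.
#' @param thresholds named vector `c(high =, intermediate =)`: a score `>=`
#'   `high` is high tier, `>=` `intermediate` is intermediate, else low.
#' @return data.frame of class `contact_table` with columns `chain_a`,
#'   `res_a`, `chain_b`, `res_b`, `tier`, `score` (NA when a label was
#'   given).
#' @export
read_contact_table <- function(path, thresholds = c(high = 0.8,
                                                    intermediate = 0.4)) {
  if (!file.exists(path)) stop("contact table not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(chain_a = character(0), res_a = integer(0),
                      chain_b = character(0), res_b = integer(0),
                      tier = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("contact_table", "data.frame")
  if (!length(lines)) return(empty)
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(f) < 5)
      stop(sprintf("contact row %d has %d fields (5 needed)", i, length(f)))
    score <- suppressWarnings(as.numeric(f[5]))
    if (is.na(score)) {
      tier <- tolower(f[5])
      if (!tier %in% .contact_tiers)
        stop(sprintf("unknown contact tier '%s' in row %d (valid: %s)",
                     f[5], i, paste(.contact_tiers, collapse = ", ")))
    } else {
      tier <- if (score >= thresholds[["high"]]) "high"
        else if (score >= thresholds[["intermediate"]]) "intermediate"
        else "low"
    }
    data.frame(chain_a = f[1], res_a = as.integer(f[2]),
               chain_b = f[3], res_b = as.integer(f[4]),
               tier = tier, score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Read a pose trajectory
#'
#' Plain-text format (markerless stand-in for live marker tracking): one
#' frame-molecule record per line,
#' `frame molecule_id qw qx qy qz tx ty tz [scale]`, `#` comments allowed.
#'
#' @param path file path.
#' @return data.frame with columns `frame`, `molecule`, `qw`..`qz`,
#'   `tx`..`tz`, `scale`.
#' @export
read_pose_trajectory <- function(path) {
  if (!file.exists(path)) stop("pose trajectory not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no frames in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[\t ]+")[[1]]
    if (length(f) < 9)
      stop(sprintf("pose record %d has %d fields (9 needed)", i, length(f)))
    v <- suppressWarnings(as.numeric(f[c(1, 3:length(f))]))
    if (any(is.na(v))) stop(sprintf("non-numeric field in pose record %d", i))
    data.frame(frame = as.integer(v[1]), molecule = f[2],
               qw = v[2], qx = v[3], qy = v[4], qz = v[5],
               tx = v[6], ty = v[7], tz = v[8],
               scale = if (length(v) >= 9) v[9] else 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a pose trajectory
#'
#' @param traj data.frame as returned by [read_pose_trajectory()].
#' @param path output path.
#' @export
write_pose_trajectory <- function(traj, path) {
  lines <- c("# frame molecule qw qx qy qz tx ty tz scale",
             sprintf("%d %s %.12g %.12g %.12g %.12g %.12g %.12g %.12g %.12g",
                     traj$frame, traj$molecule, traj$qw, traj$qx, traj$qy,
                     traj$qz, traj$tx, traj$ty, traj$tz,
                     if (is.null(traj$scale)) rep(1, nrow(traj)) else traj$scale))
  writeLines(lines, path)
  invisible(path)
}

pose_from_row <- function(row) {
  pose(rotation = c(row$qw, row$qx, row$qy, row$qz),
       translation = c(row$tx, row$ty, row$tz),
       scale = if (is.null(row$scale)) 1 else row$scale)
}
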