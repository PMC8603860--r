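#' A landmark trajectory recording from one device
#'
#' Columnar container for one device's capture of one subject: strictly
#' increasing timestamps, a per-frame validity flag (FALSE marks a tracking
#' dropout) and an `n x 3` coordinate matrix (mm) per named landmark.
#'
#' @param device_id device label, conventionally `"emt"` (electromagnetic
#'   tracker) or `"depth"` (depth camera).
#' @param nominal_rate nominal sampling rate, frames per second.
#' @param time_s numeric vector of frame timestamps (seconds), strictly
#'   increasing.
#' @param valid logical vector, `FALSE` for dropout frames.
#' @param landmarks named list of `n x 3` numeric matrices (columns x, y, z
#'   in mm). Coordinates of invalid frames may be `NA`.
#' @param subject_id optional subject label.
#' @return An object of class `recording`.
#' @export
recording <- function(device_id, nominal_rate, time_s, valid, landmarks,
                      subject_id = NA_character_) {
  n <- length(time_s)
  stopifnot(is.numeric(nominal_rate), nominal_rate > 0,
            is.logical(valid), length(valid) == n, n >= 1L)
  if (any(diff(time_s) <= 0)) {
    stop("recording timestamps must be strictly increasing", call. = FALSE)
  }
  missing <- setdiff(HEAD_LANDMARKS, names(landmarks))
  if (length(missing) > 0L) {
    stop("recording lacks landmark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(landmarks)) {
    m <- landmarks[[nm]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L) {
      stop("landmark '", nm, "' must be an n x 3 matrix", call. = FALSE)
    }
    bad <- valid & !apply(is.finite(m), 1L, all)
    if (any(bad)) {
      stop("non-finite coordinates on valid frame(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           " of landmark '", nm, "'", call. = FALSE)
    }
  }
  structure(list(device_id = device_id, nominal_rate = nominal_rate,
                 time_s = as.numeric(time_s), valid = valid,
                 landmarks = landmarks, subject_id = subject_id),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> device=%s subject=%s  %d frames @ %g fps  %.2f s  %d dropout\n",
    x$device_id, x$subject_id, length(x$time_s), x$nominal_rate,
    max(x$time_s) - min(x$time_s), sum(!x$valid)))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec a [recording()].
#' @param valid_only count only non-dropout frames.
#' @return Integer frame count.
#' @export
n_frames <- function(rec, valid_only = FALSE) {
  if (valid_only) sum(rec$valid) else length(rec$time_s)
}

# Per-frame head orientation matrices for the valid frames of a recording.
# Returns list(time_s, X, Y, Z) with n_valid rows.
recording_orientations <- function(rec, area_tol_mm2 = 1) {
  keep <- rec$valid
  h <- tryCatch(
    head_frames(rec$landmarks$right_canthus[keep, , drop = FALSE],
                rec$landmarks$left_canthus[keep, , drop = FALSE],
                rec$landmarks$sublip[keep, , drop = FALSE],
                area_tol_mm2 = area_tol_mm2),
    error = function(e) {
      stop("in recording '", rec$device_id, "': ", conditionMessage(e),
           call. = FALSE)
    })
  c(list(time_s = rec$time_s[keep]), h)
}
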