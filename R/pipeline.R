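#' Neutral reference orientation of a recording
#'
#' The chordal mean head orientation over a time window, used as the
#' neutral (central-fixation) reference that all angles are expressed
#' against. By default the window is the middle portion of the leading
#' central hold.
#'
#' @param rec a [recording()].
#' @param window numeric `c(start, end)` seconds (half-open interval); by
#'   default the middle 8 s of `[0, 10)`.
#' @return A 3x3 orientation matrix.
#' @export
neutral_reference <- function(rec, window = c(1, 9)) {
  o <- recording_orientations(rec)
  keep <- o$time_s >= window[1] & o$time_s < window[2]
  if (!any(keep)) stop("no valid frames in the neutral window", call. = FALSE)
  M <- cbind(colMeans(o$X[keep, , drop = FALSE]),
             colMeans(o$Y[keep, , drop = FALSE]),
             colMeans(o$Z[keep, , drop = FALSE]))
  project_rotation(M)
}

#' Euler-angle time series of a recording
#'
#' For every non-dropout frame: build the head frame from the landmarks,
#' express it relative to the neutral reference orientation, and decompose
#' into xyz Euler angles. Dropout frames yield gaps (they are absent from
#' the output; no interpolation).
#'
#' @param rec a [recording()].
#' @param neutral_ref a 3x3 orientation matrix, e.g. from
#'   [neutral_reference()].
#' @return A data frame with columns `time_s`, `x`, `y`, `z` (degrees),
#'   one row per valid frame.
#' @export
angles_timeseries <- function(rec, neutral_ref) {
  check_rotation(neutral_ref, tol = 1e-6)
  o <- recording_orientations(rec)
  # R_rel = t(neutral_ref) %*% R_t, elementwise over frames:
  # row i of R_rel = neutral axis i dotted with each head axis.
  el <- list()
  cols <- list(o$X, o$Y, o$Z)
  for (i in 1:3) {
    for (j in 1:3) {
      el[[paste0("r", i, j)]] <- drop(cols[[j]] %*% neutral_ref[, i])
    }
  }
  ang <- euler_from_elements(el)
  data.frame(time_s = o$time_s, x = ang[, 1], y = ang[, 2], z = ang[, 3])
}

#' Segment a recording into fixation holds
#'
#' Schedule mode (an annotation is supplied): hold boundaries come from
#' the protocol timeline. Automatic mode: holds are maximal intervals
#' where the angular speed (central difference of the angle series,
#' degrees/s) stays below a threshold for at least a minimum duration;
#' the detected holds are labelled by the protocol's fixed movement order
#' and must number `2 * n_movements + 1` (alternating central/eccentric).
#'
#' Every hold gets a middle analysis window: `(duration - window_s) / 2`
#' is trimmed from each end, i.e. the window is `min(window_s, duration)`
#' seconds centred in the hold. Intervals are half-open `[start, end)`.
#'
#' @param rec a [recording()].
#' @param annotation an [protocol_annotation()] (or `NULL` for automatic
#'   segmentation).
#' @param window_s analysis window length, seconds (default 8: the middle
#'   8 s of a 10 s hold).
#' @param movements movement order used to label automatic holds.
#' @param speed_threshold automatic mode: angular speed threshold, deg/s.
#' @param min_hold_s automatic mode: minimum hold duration, seconds.
#' @param hysteresis_s automatic mode: brief above-threshold excursions
#'   shorter than this are absorbed into the surrounding hold, seconds.
#' @return A data frame with columns `label`, `hold_start`, `hold_end`,
#'   `window_start`, `window_end`, `sample_count` (valid frames whose
#'   timestamp falls in `[window_start, window_end)`).
#' @export
segment_holds <- function(rec, annotation = NULL, window_s = 8,
                          movements = MOVEMENTS, speed_threshold = 5,
                          min_hold_s = 4, hysteresis_s = 0.5) {
  if (!is.null(annotation)) {
    holds <- annotation$holds
  } else {
    holds <- detect_holds(rec, movements, speed_threshold, min_hold_s,
                          hysteresis_s)
  }
  dur <- holds$end_s - holds$start_s
  trim <- pmax(0, (dur - window_s) / 2)
  ws <- holds$start_s + trim
  we <- holds$end_s - trim
  tv <- rec$time_s[rec$valid]
  count <- vapply(seq_along(ws), function(i) {
    sum(tv >= ws[i] & tv < we[i])
  }, integer(1))
  data.frame(label = holds$label, hold_start = holds$start_s,
             hold_end = holds$end_s, window_start = ws, window_end = we,
             sample_count = count)
}

# Velocity-threshold hold detection on the angle time series.
detect_holds <- function(rec, movements, speed_threshold, min_hold_s,
                         hysteresis_s) {
  ref <- neutral_reference(rec, window = c(0, 1))
  a <- angles_timeseries(rec, ref)
  n <- nrow(a)
  if (n < 3L) stop("recording too short for automatic segmentation",
                   call. = FALSE)
  # central-difference angular speed, componentwise, then magnitude
  dt <- a$time_s[3:n] - a$time_s[1:(n - 2)]
  dv <- sqrt(((a$x[3:n] - a$x[1:(n - 2)]) / dt)^2 +
               ((a$y[3:n] - a$y[1:(n - 2)]) / dt)^2 +
               ((a$z[3:n] - a$z[1:(n - 2)]) / dt)^2)
  t_mid <- a$time_s[2:(n - 1)]
  slow <- dv < speed_threshold
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # absorb brief fast excursions (hysteresis)
  fast <- which(!r$values)
  for (k in fast) {
    if (t_mid[ends[k]] - t_mid[starts[k]] < hysteresis_s) r$values[k] <- TRUE
  }
  slow2 <- inverse.rle(r)
  r2 <- rle(slow2)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  keep <- r2$values &
    (t_mid[ends2] - t_mid[starts2]) >= min_hold_s
  hs <- t_mid[starts2[keep]]
  he <- t_mid[ends2[keep]]
  expected <- 2L * length(movements) + 1L
  if (length(hs) != expected) {
    stop("automatic segmentation found ", length(hs), " holds; protocol ",
         "expects ", expected, " (", length(movements) + 1L, " central + ",
         length(movements), " eccentric)", call. = FALSE)
  }
  labels <- character(expected)
  labels[seq(1L, expected, by = 2L)] <-
    paste0("central_", seq_len(length(movements) + 1L) - 1L)
  labels[seq(2L, expected, by = 2L)] <- movements
  data.frame(label = labels, start_s = hs, end_s = he)
}

# Primary reporting axis of a movement under an axis-label mapping.
# turn_axis = "z" is the geometric mapping (turn is a rotation about the
# vertical head axis); turn_axis = "y" is the alternative labelling that
# assigns turn to the y Euler component and tilt to z.
primary_axis <- function(movement, turn_axis = c("z", "y")) {
  turn_axis <- match.arg(turn_axis)
  tilt_axis <- if (turn_axis == "z") "y" else "z"
  kind <- sub("_(up|down|right|left)$", "", movement)
  switch(kind,
         chin = "x",
         turn = turn_axis,
         tilt = tilt_axis,
         stop("unknown movement label: ", movement, call. = FALSE))
}

#' Range and stability of one movement
#'
#' The two study metrics for a single movement: range of movement is the
#' absolute difference between the mean primary-axis angle over the
#' eccentric-hold analysis window and the mean over the preceding
#' central-hold window (baseline subtraction); stability is the sample SD
#' (n-1 denominator) of the primary-axis angle over the eccentric window.
#'
#' @param central,eccentric data frames with columns `x`, `y`, `z`
#'   (degrees): the angle samples inside the two analysis windows.
#' @param movement movement label (one of [MOVEMENTS]).
#' @param turn_axis axis-label mapping: `"z"` (geometric, default) or
#'   `"y"` (assign turn to the y Euler component).
#' @return A one-row data frame: `movement`, `axis`, `range_deg`,
#'   `stability_sd_deg`.
#' @export
measure_movement <- function(central, eccentric, movement,
                             turn_axis = c("z", "y")) {
  if (nrow(central) < 2L || nrow(eccentric) < 2L) {
    stop("insufficient samples: need >= 2 in both windows (central ",
         nrow(central), ", eccentric ", nrow(eccentric), ")", call. = FALSE)
  }
  axis <- primary_axis(movement, turn_axis)
  data.frame(movement = movement, axis = axis,
             range_deg = abs(mean(eccentric[[axis]]) - mean(central[[axis]])),
             stability_sd_deg = stats::sd(eccentric[[axis]]))
}

# Longest gap (in missing nominal frame periods) in the valid timestamps
# of rec inside the half-open window [ws, we). Leading and trailing gaps
# count. Returns 0 for a gapless stream.
max_missing_frames <- function(rec, ws, we) {
  period <- 1 / rec$nominal_rate
  tv <- rec$time_s[rec$valid]
  tv <- tv[tv >= ws & tv < we]
  if (length(tv) == 0L) return(Inf)
  gaps <- diff(c(ws - period / 2, tv, we - period / 2))
  max(0, round(max(gaps) / period) - 1)
}

#' Analyse one recording into per-movement measurements
#'
#' Full single-recording pipeline: establish the neutral reference from
#' the leading central hold, compute the angle time series, segment holds,
#' and measure range and stability for each movement against its
#' immediately preceding central hold. A movement whose eccentric analysis
#' window contains a tracking gap longer than `gap_frames` missing nominal
#' frame periods, or too few samples, is flagged excluded and carries no
#' metric values.
#'
#' @param rec a [recording()].
#' @param annotation a [protocol_annotation()] (or `NULL` for automatic
#'   segmentation).
#' @param turn_axis axis-label mapping, see [measure_movement()].
#' @param window_s analysis window length, seconds.
#' @param gap_frames dropout gap threshold: a movement is excluded when
#'   more than this many consecutive nominal frames are missing inside its
#'   eccentric window.
#' @param ... further arguments to [segment_holds()].
#' @return A data frame of measurement rows: `subject`, `device`,
#'   `movement`, `axis`, `range_deg`, `stability_sd_deg`, `excluded`,
#'   `reason`.
#' @export
analyze_recording <- function(rec, annotation = NULL,
                              turn_axis = c("z", "y"), window_s = 8,
                              gap_frames = 2, ...) {
  turn_axis <- match.arg(turn_axis)
  holds <- segment_holds(rec, annotation, window_s = window_s, ...)
  i0 <- match("central_0", holds$label)
  ref <- neutral_reference(
    rec, window = c(holds$window_start[i0], holds$window_end[i0]))
  ang <- angles_timeseries(rec, ref)

  window_angles <- function(i) {
    ang[ang$time_s >= holds$window_start[i] &
          ang$time_s < holds$window_end[i], , drop = FALSE]
  }
  ecc <- which(holds$label %in% MOVEMENTS)
  rows <- lapply(ecc, function(i) {
    m <- holds$label[i]
    base <- data.frame(subject = rec$subject_id, device = rec$device_id,
                       movement = m,
                       axis = primary_axis(m, turn_axis),
                       range_deg = NA_real_, stability_sd_deg = NA_real_,
                       excluded = TRUE, reason = NA_character_)
    gap <- max_missing_frames(rec, holds$window_start[i],
                              holds$window_end[i])
    if (gap > gap_frames) {
      base$reason <- "tracking_lost"
      return(base)
    }
    prev_central <- max(which(holds$label[seq_len(i - 1L)] %in%
                                paste0("central_", 0:9)))
    res <- tryCatch(
      measure_movement(window_angles(prev_central), window_angles(i), m,
                       turn_axis),
      error = function(e) NULL)
    if (is.null(res)) {
      base$reason <- "insufficient_samples"
      return(base)
    }
    base$range_deg <- res$range_deg
    base$stability_sd_deg <- res$stability_sd_deg
    base$excluded <- FALSE
    base
  })
  do.call(rbind, rows)
}

#' Pair two devices' measurements with the exclusion rule
#'
#' Applies the paired-exclusion rule: when a movement is unusable in the
#' depth stream (tracking lost in its eccentric window) it is excluded for
#' BOTH devices, so the comparison always uses the same movements on both
#' sides. A movement flagged on either device is dropped from the paired
#' data; exclusions are recorded, not fatal.
#'
#' @param measurements_emt,measurements_depth measurement data frames from
#'   [analyze_recording()] (any number of subjects row-bound together).
#' @return A data frame of complete pairs: `subject`, `movement`, `axis`,
#'   `range_emt`, `range_depth`, `sd_emt`, `sd_depth`, with an
#'   `"exclusions"` attribute listing the excluded subject x movement
#'   combinations and reasons.
#' @export
paired_exclusion <- function(measurements_emt, measurements_depth) {
  key <- c("subject", "movement")
  m <- merge(measurements_emt, measurements_depth, by = key,
             suffixes = c("_emt", "_depth"))
  bad <- m$excluded_emt | m$excluded_depth
  excl <- data.frame(subject = m$subject[bad], movement = m$movement[bad],
                     reason = ifelse(is.na(m$reason_depth[bad]),
                                     m$reason_emt[bad], m$reason_depth[bad]))
  ok <- m[!bad, , drop = FALSE]
  out <- data.frame(subject = ok$subject, movement = ok$movement,
                    axis = ok$axis_emt,
                    range_emt = ok$range_deg_emt,
                    range_depth = ok$range_deg_depth,
                    sd_emt = ok$stability_sd_deg_emt,
                    sd_depth = ok$stability_sd_deg_depth)
  out <- out[order(match(out$movement, MOVEMENTS), out$subject), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Analyse a simulated cohort end to end
#'
#' Runs [analyze_recording()] on both devices of every subject and applies
#' [paired_exclusion()].
#'
#' @param cohort a [generate_cohort()] result.
#' @param ... arguments passed to [analyze_recording()].
#' @return A list with `measurements_emt`, `measurements_depth` and the
#'   `paired` data frame.
#' @export
analyze_cohort <- function(cohort, ...) {
  emt <- do.call(rbind, lapply(cohort$subjects, function(s) {
    analyze_recording(s$rec_emt, s$annotation, ...)
  }))
  depth <- do.call(rbind, lapply(cohort$subjects, function(s) {
    analyze_recording(s$rec_depth, s$annotation, ...)
  }))
  list(measurements_emt = emt, measurements_depth = depth,
       paired = paired_exclusion(emt, depth))
}
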