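#' Canonical movement labels
#'
#' The six eccentric head movements in their fixed protocol order.
#' @export
MOVEMENTS <- c("chin_up", "chin_down", "turn_right", "turn_left",
               "tilt_right", "tilt_left")

# Geometric axis and direction sign of each movement's primary rotation,
# in the head frame (x mediolateral/right, y anteroposterior, z superior).
MOVEMENT_AXIS <- c(chin_up = "x", chin_down = "x",
                   turn_right = "z", turn_left = "z",
                   tilt_right = "y", tilt_left = "y")
MOVEMENT_SIGN <- c(chin_up = 1, chin_down = -1,
                   turn_right = -1, turn_left = 1,
                   tilt_right = -1, tilt_left = 1)

#' Movement protocol specification
#'
#' The fixation protocol: a leading central hold, then for each movement a
#' smooth transition to the eccentric target, an eccentric hold, a
#' transition back, and a central hold. Defaults follow the study design:
#' six movements toward 30-degree targets, 10-second holds, performed in
#' the order chin up, chin down, turn right, turn left, tilt right,
#' tilt left.
#'
#' @param movements character vector of movement labels (subset of
#'   [MOVEMENTS], in execution order).
#' @param target_deg target amplitude in degrees, in (0, 90).
#' @param hold_s duration of every hold (central and eccentric), seconds.
#' @param transition_s duration of each movement transition, seconds.
#' @param lead_s duration of the leading central hold, seconds.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(movements = MOVEMENTS, target_deg = 30,
                          hold_s = 10, transition_s = 2, lead_s = 10) {
  stopifnot(all(movements %in% MOVEMENTS), length(movements) >= 1L,
            target_deg > 0, target_deg < 90,
            hold_s > 0, transition_s > 0, lead_s > 0)
  structure(list(movements = movements, target_deg = target_deg,
                 hold_s = hold_s, transition_s = transition_s,
                 lead_s = lead_s),
            class = "protocol_spec")
}

#' Total duration of a protocol
#' @param protocol a [protocol_spec()].
#' @return Duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  protocol$lead_s + length(protocol$movements) *
    (2 * protocol$transition_s + 2 * protocol$hold_s)
}

#' Hold timeline of a protocol
#'
#' Expands a protocol into its hold schedule: alternating central and
#' eccentric holds with half-open intervals `[start_s, end_s)`.
#'
#' @param protocol a [protocol_spec()].
#' @return A data frame with columns `label`, `start_s`, `end_s`. Central
#'   holds are labelled `central_0`, `central_1`, ... in order.
#' @export
protocol_holds <- function(protocol) {
  labels <- "central_0"
  starts <- 0
  ends <- protocol$lead_s
  t <- protocol$lead_s
  for (i in seq_along(protocol$movements)) {
    t <- t + protocol$transition_s
    labels <- c(labels, protocol$movements[i])
    starts <- c(starts, t)
    t <- t + protocol$hold_s
    ends <- c(ends, t)
    t <- t + protocol$transition_s
    labels <- c(labels, paste0("central_", i))
    starts <- c(starts, t)
    t <- t + protocol$hold_s
    ends <- c(ends, t)
  }
  data.frame(label = labels, start_s = starts, end_s = ends)
}

#' Protocol annotation for one subject
#'
#' The annotation that accompanies each recording pair: movement order,
#' per-hold start/end times and the target amplitude. Written to / read
#' from JSON by [write_annotation()] / [read_annotation()].
#'
#' @param protocol a [protocol_spec()].
#' @param subject_id subject label.
#' @return An object of class `annotation`: list with `subject_id`,
#'   `target_deg`, `movements` and a `holds` data frame.
#' @export
protocol_annotation <- function(protocol, subject_id = NA_character_) {
  structure(list(subject_id = subject_id,
                 target_deg = protocol$target_deg,
                 movements = protocol$movements,
                 holds = protocol_holds(protocol)),
            class = "annotation")
}
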