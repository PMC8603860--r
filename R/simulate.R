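#' Subject population model
#'
#' Between-subject variation for the simulator. Each simulated subject
#' draws one undershoot factor (achieved amplitude = target x factor, with
#' additional per-movement noise) and holds their head with autocorrelated
#' postural jitter of a given stationary SD.
#'
#' @param undershoot_mean mean undershoot factor (unitless; subjects
#'   fixating eccentric targets typically fall short of the nominal
#'   amplitude).
#' @param undershoot_sd between-subject SD of the undershoot factor.
#' @param movement_sd_deg per-movement SD of achieved amplitude about the
#'   subject's mean, degrees.
#' @param jitter_sd_deg stationary SD of hold jitter on each axis, degrees.
#' @param jitter_tau_s autocorrelation time of the jitter process, seconds.
#' @return An object of class `population_model`.
#' @export
population_model <- function(undershoot_mean = 0.93, undershoot_sd = 0.05,
                             movement_sd_deg = 0.5, jitter_sd_deg = 0.8,
                             jitter_tau_s = 0.5) {
  stopifnot(undershoot_mean > 0, undershoot_sd >= 0, movement_sd_deg >= 0,
            jitter_sd_deg >= 0, jitter_tau_s > 0)
  structure(list(undershoot_mean = undershoot_mean,
                 undershoot_sd = undershoot_sd,
                 movement_sd_deg = movement_sd_deg,
                 jitter_sd_deg = jitter_sd_deg,
                 jitter_tau_s = jitter_tau_s),
            class = "population_model")
}

#' Draw one subject from the population model
#'
#' @param protocol a [protocol_spec()].
#' @param population a [population_model()].
#' @param seed integer seed (deterministic draw).
#' @return An object of class `subject_model`: per-movement achieved
#'   amplitudes (deg, positive) plus the jitter parameters.
#' @export
subject_model <- function(protocol, population = population_model(), seed) {
  withr::with_seed(seed, {
    factor <- stats::rnorm(1, population$undershoot_mean,
                           population$undershoot_sd)
    amps <- protocol$target_deg * factor +
      stats::rnorm(length(protocol$movements), 0, population$movement_sd_deg)
  })
  amps <- pmax(amps, 1)  # achieved amplitude must stay positive
  names(amps) <- protocol$movements
  structure(list(amplitudes_deg = amps,
                 jitter_sd_deg = population$jitter_sd_deg,
                 jitter_tau_s = population$jitter_tau_s),
            class = "subject_model")
}

#' Device forward model
#'
#' Parameterises how a capture device measures the true head motion:
#' sampling rate, per-axis multiplicative angular attenuation (systematic
#' underestimation of angular displacement), isotropic landmark position
#' noise, and a two-state dropout process (per-frame probability of
#' entering a dropout burst, geometric burst length). The device also has
#' its own world frame (rotation + offset): the pipeline must be invariant
#' to it.
#'
#' @param device_id device label.
#' @param rate sampling rate, frames per second.
#' @param attenuation named numeric `c(x=, y=, z=)`, each in (0, 1].
#' @param noise_sd_mm landmark position noise SD (mm, isotropic white).
#' @param dropout_prob per-frame probability of entering a dropout burst,
#'   in `[0, 1)`.
#' @param dropout_burst mean dropout burst length, frames (>= 1).
#' @param world_rotation 3x3 rotation of the device world frame.
#' @param world_offset_mm numeric xyz offset of the head origin in the
#'   device world frame (mm).
#' @return An object of class `device_model`.
#' @export
device_model <- function(device_id, rate,
                         attenuation = c(x = 1, y = 1, z = 1),
                         noise_sd_mm = 0, dropout_prob = 0,
                         dropout_burst = 5,
                         world_rotation = diag(3),
                         world_offset_mm = c(0, 0, 0)) {
  stopifnot(rate > 0, all(attenuation > 0), all(attenuation <= 1),
            noise_sd_mm >= 0, dropout_prob >= 0, dropout_prob < 1,
            dropout_burst >= 1)
  check_rotation(world_rotation)
  att <- attenuation[c("x", "y", "z")]
  stopifnot(!anyNA(att))
  structure(list(device_id = device_id, rate = rate, attenuation = att,
                 noise_sd_mm = noise_sd_mm, dropout_prob = dropout_prob,
                 dropout_burst = dropout_burst,
                 world_rotation = world_rotation,
                 world_offset_mm = world_offset_mm),
            class = "device_model")
}

#' Default electromagnetic-tracker device model
#'
#' High rate (240 fps), no attenuation, sub-millimetre noise, no
#' dropouts: the reference device.
#' @param ... overrides passed to [device_model()].
#' @export
device_model_emt <- function(...) {
  args <- utils::modifyList(
    list(device_id = "emt", rate = 240, noise_sd_mm = 0.05), list(...))
  do.call(device_model, args)
}

#' Default depth-camera device model
#'
#' Low rate (30 fps), per-axis angular attenuation strongest on the pitch
#' (chin up/down) axis, millimetre-scale landmark noise, occasional
#' tracking dropouts, and its own world frame.
#' @param ... overrides passed to [device_model()].
#' @export
device_model_depth <- function(...) {
  args <- utils::modifyList(
    list(device_id = "depth", rate = 30,
         attenuation = c(x = 0.70, y = 0.98, z = 0.85),
         noise_sd_mm = 1.3, dropout_prob = 5e-4, dropout_burst = 6,
         world_rotation = rot_y(170) %*% rot_x(5),
         world_offset_mm = c(0, 0, 1500)),
    list(...))
  do.call(device_model, args)
}

# Quintic smoothstep (minimum-jerk shape): s(0)=0, s(1)=1, zero first and
# second derivatives at both ends; s(1/2) = 1/2.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (u * (u * 6 - 15) + 10)
}

# Deterministic (jitter-free) Euler angle profile of a protocol run.
# t: numeric vector of times; returns n x 3 matrix (x, y, z degrees).
protocol_angles <- function(t, protocol, amplitudes_deg) {
  ang <- matrix(0, length(t), 3, dimnames = list(NULL, c("x", "y", "z")))
  t0 <- protocol$lead_s
  tt <- protocol$transition_s
  hh <- protocol$hold_s
  for (m in protocol$movements) {
    a <- MOVEMENT_SIGN[[m]] * amplitudes_deg[[m]]
    axis <- MOVEMENT_AXIS[[m]]
    rise <- t >= t0 & t < t0 + tt
    hold <- t >= t0 + tt & t < t0 + tt + hh
    fall <- t >= t0 + tt + hh & t < t0 + 2 * tt + hh
    ang[rise, axis] <- ang[rise, axis] + a * smoothstep((t[rise] - t0) / tt)
    ang[hold, axis] <- ang[hold, axis] + a
    ang[fall, axis] <- ang[fall, axis] +
      a * (1 - smoothstep((t[fall] - (t0 + tt + hh)) / tt))
    t0 <- t0 + 2 * tt + 2 * hh
  }
  ang
}

# First-order autocorrelated (AR(1)/Ornstein-Uhlenbeck) noise with
# stationary SD sigma and correlation time tau_s, sampled on a grid at
# grid_rate. Returns a numeric vector of length n.
ar1_noise <- function(n, sigma, tau_s, grid_rate) {
  if (sigma == 0 || n == 0L) return(numeric(n))
  phi <- exp(-1 / (grid_rate * tau_s))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  e[1] <- stats::rnorm(1, 0, sigma)  # start at stationarity
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' True head-orientation trajectory of one simulated subject
#'
#' Builds the continuous orientation-versus-time function a protocol run
#' produces: neutral and eccentric holds connected by quintic smoothstep
#' (minimum-jerk) single-axis transitions, plus zero-mean first-order
#' autocorrelated hold jitter on all three axes with the subject's
#' stationary jitter SD. The jitter process is realised once on a fixed
#' 240 Hz grid and linearly interpolated, so the same trajectory can be
#' sampled consistently by devices with different frame rates, and the
#' function is deterministic given the seed.
#'
#' @param protocol a [protocol_spec()].
#' @param subject a [subject_model()].
#' @param seed integer seed for the jitter realisation.
#' @param grid_rate jitter grid rate, Hz.
#' @return A function `f(t)` mapping a numeric time vector to an
#'   `n x 3` matrix of Euler angles (degrees, xyz sequence, relative to
#'   the neutral pose). Attributes `protocol` and `subject` are attached.
#' @export
true_orientation_fn <- function(protocol, subject, seed, grid_rate = 240) {
  dur <- protocol_duration(protocol)
  n_grid <- ceiling(dur * grid_rate) + 1L
  t_grid <- (seq_len(n_grid) - 1L) / grid_rate
  jit <- withr::with_seed(seed, {
    vapply(1:3, function(i) {
      ar1_noise(n_grid, subject$jitter_sd_deg, subject$jitter_tau_s,
                grid_rate)
    }, numeric(n_grid))
  })
  amps <- subject$amplitudes_deg
  fn <- function(t) {
    ang <- protocol_angles(t, protocol, amps)
    if (subject$jitter_sd_deg > 0) {
      for (i in 1:3) {
        ang[, i] <- ang[, i] +
          stats::approx(t_grid, jit[, i], xout = t, rule = 2)$y
      }
    }
    ang
  }
  attr(fn, "protocol") <- protocol
  attr(fn, "subject") <- subject
  fn
}

# Alternating valid/dropout run lengths for a two-state process:
# valid -> dropout with prob p per frame; dropout length 1 + Geom with
# mean burst_len. Returns a logical validity vector of length n.
dropout_flags <- function(n, p, burst_len) {
  if (p <= 0 || n == 0L) return(rep(TRUE, n))
  valid <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    run <- stats::rgeom(1, p)            # valid frames before next burst
    i <- i + run
    if (i > n) break
    len <- 1L + stats::rgeom(1, 1 / burst_len)
    valid[i:min(n, i + len - 1L)] <- FALSE
    i <- i + len
  }
  valid
}

#' Render a recording of a trajectory through a device model
#'
#' The device forward model: sample the true orientation function at the
#' device rate; scale each Euler component by the device's per-axis
#' attenuation and recompose to a rotation; rotate the rigid face template
#' and place it in the device's world frame; add isotropic landmark noise;
#' mark dropout bursts as invalid frames (their coordinates are dropped).
#' Deterministic given the seed.
#'
#' @param fn a trajectory function from [true_orientation_fn()].
#' @param template a [face_template()].
#' @param device a [device_model()].
#' @param seed integer seed for noise and dropouts.
#' @param duration_s recording length, seconds; defaults to the protocol
#'   duration attached to `fn`.
#' @param subject_id subject label stored in the recording.
#' @return A [recording()].
#' @export
render_recording <- function(fn, template, device, seed,
                             duration_s = NULL, subject_id = NA_character_) {
  if (is.null(duration_s)) {
    duration_s <- protocol_duration(attr(fn, "protocol"))
  }
  n <- floor(duration_s * device$rate)
  t <- (seq_len(n) - 1L) / device$rate
  ang <- fn(t)
  ang <- sweep(ang, 2L, device$attenuation, `*`)
  e <- euler_elements(ang[, 1], ang[, 2], ang[, 3])

  # head frame of the neutral template (template coords -> head axes)
  H0 <- build_head_frame(unclass(template))
  B <- device$world_rotation %*% H0   # constant left factor
  landmarks <- lapply(unclass(template), function(p) {
    q <- crossprod(H0, p)  # template point in head-axis coordinates
    # per-frame rotated point r = Rxyz %*% q, then world = B %*% r + offset
    r1 <- e$r11 * q[1] + e$r12 * q[2] + e$r13 * q[3]
    r2 <- e$r21 * q[1] + e$r22 * q[2] + e$r23 * q[3]
    r3 <- e$r31 * q[1] + e$r32 * q[2] + e$r33 * q[3]
    w <- cbind(r1, r2, r3) %*% t(B)
    sweep(w, 2L, device$world_offset_mm, `+`)
  })

  withr::with_seed(seed, {
    if (device$noise_sd_mm > 0) {
      landmarks <- lapply(landmarks, function(m) {
        m + matrix(stats::rnorm(length(m), 0, device$noise_sd_mm), nrow(m), 3)
      })
    }
    valid <- dropout_flags(n, device$dropout_prob, device$dropout_burst)
  })
  for (nm in names(landmarks)) {
    landmarks[[nm]][!valid, ] <- NA_real_
    colnames(landmarks[[nm]]) <- c("x", "y", "z")
  }
  recording(device$device_id, device$rate, t, valid, landmarks,
            subject_id = subject_id)
}

# Deterministic counter-based child-seed derivation from the master seed,
# so adding a subject never perturbs earlier subjects' data. Streams:
# 1 subject draw, 2 trajectory jitter, 3 emt render, 4 depth render.
derive_seed <- function(master, subject, stream) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
                subject * 1299709 + stream * 7919) %% 2147483629 + 1)
}

#' Simulate a paired two-device cohort
#'
#' For each subject: draw an achieved-amplitude profile from the
#' population model, realise one true head trajectory, and render it once
#' per device from the SAME trajectory (the two devices record
#' simultaneously). Per-subject seeds are derived deterministically from
#' the master seed by a counter scheme, so the cohort is fully reproducible
#' and extending it does not perturb existing subjects.
#'
#' @param n_subjects number of subjects (default 20, the study size).
#' @param protocol a [protocol_spec()].
#' @param population a [population_model()].
#' @param device_emt,device_depth [device_model()]s for the two devices.
#' @param template a [face_template()].
#' @param seed master integer seed.
#' @return An object of class `cohort`: list with `subjects` (each holding
#'   `subject_id`, `subject` model, `annotation`, `rec_emt`, `rec_depth`)
#'   and the generating parameters.
#' @export
generate_cohort <- function(n_subjects = 20, protocol = protocol_spec(),
                            population = population_model(),
                            device_emt = device_model_emt(),
                            device_depth = device_model_depth(),
                            template = face_template(), seed = 1) {
  stopifnot(n_subjects >= 1)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("S%02d", i)
    subj <- subject_model(protocol, population, derive_seed(seed, i, 1))
    fn <- true_orientation_fn(protocol, subj, derive_seed(seed, i, 2))
    list(subject_id = sid,
         subject = subj,
         annotation = protocol_annotation(protocol, sid),
         rec_emt = render_recording(fn, template, device_emt,
                                    derive_seed(seed, i, 3),
                                    subject_id = sid),
         rec_depth = render_recording(fn, template, device_depth,
                                      derive_seed(seed, i, 4),
                                      subject_id = sid))
  })
  structure(list(subjects = subjects, protocol = protocol,
                 population = population, device_emt = device_emt,
                 device_depth = device_depth, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d movements, seed %d\n",
              length(x$subjects), length(x$protocol$movements), x$seed))
  invisible(x)
}
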