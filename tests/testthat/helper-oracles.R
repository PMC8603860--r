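# Shared fixtures and independent oracles for the test suite.

# Random rotation matrix via QR of a Gaussian matrix (sign-fixed).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

neutral_template_points <- function() {
  list(right_canthus = c(45, 0, 0), left_canthus = c(-45, 0, 0),
       sublip = c(0, -70, 0))
}

# Brute-force Wilcoxon signed-rank oracle: literally enumerate all 2^n
# sign assignments of the ranked |d| and count assignments with a
# positive-rank sum at least as extreme as observed (two-sided, doubled
# smaller tail, capped at 1). Independent of the package's convolution.
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  min(1, 2 * min(sum(w_all <= w_obs), sum(w_all >= w_obs)) / 2^n)
}

# A quick single-subject ideal (noise-free, jitter-free, unattenuated)
# simulated pair of recordings for pipeline tests.
ideal_subject <- function(protocol = protocol_spec(), amplitude = 30,
                          rate = 30, seed = 1) {
  subj <- structure(list(
    amplitudes_deg = setNames(rep(amplitude, length(protocol$movements)),
                              protocol$movements),
    jitter_sd_deg = 0, jitter_tau_s = 0.5), class = "subject_model")
  fn <- true_orientation_fn(protocol, subj, seed = seed)
  dev <- device_model("ideal", rate = rate)
  render_recording(fn, face_template(), dev, seed = seed,
                   subject_id = "S01")
}
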