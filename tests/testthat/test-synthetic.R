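test_that("protocol timeline has the study structure", {
  p <- protocol_spec()
  h <- protocol_holds(p)
  expect_equal(nrow(h), 13)
  expect_equal(h$label[1:3], c("central_0", "chin_up", "central_1"))
  expect_equal(h$start_s[2], 12)  # lead 10 s + 2 s transition
  expect_equal(h$end_s[2] - h$start_s[2], 10)
  expect_equal(protocol_duration(p), 154)
  expect_error(protocol_spec(target_deg = 95), "target_deg")
})

test_that("jitter-free trajectories hold exactly at the achieved amplitude", {
  p <- protocol_spec()
  subj <- structure(list(
    amplitudes_deg = setNames(c(28, 27, 29, 26, 30, 25), MOVEMENTS),
    jitter_sd_deg = 0, jitter_tau_s = 0.5), class = "subject_model")
  fn <- true_orientation_fn(p, subj, seed = 5)
  # mid-hold of chin_up (hold [12, 22)): constant +28 on x
  ang <- fn(c(13, 17, 21.5))
  expect_equal(ang[, "x"], rep(28, 3))
  expect_equal(ang[, "y"], rep(0, 3))
  # turn_right hold [60, 70): -29 on z (rightward turn is negative)
  expect_equal(unname(fn(65)[, "z"]), -29)
  # transition midpoint of the chin_up rise [10, 12): half amplitude
  expect_equal(unname(fn(11)[, "x"]), 14)
  # neutral holds return to zero
  expect_equal(max(abs(fn(c(5, 30, 150)))), 0)
})

test_that("trajectories are deterministic given the seed", {
  p <- protocol_spec()
  subj <- subject_model(p, population_model(), seed = 9)
  t <- seq(0, 150, by = 0.37)
  a1 <- true_orientation_fn(p, subj, seed = 7)(t)
  a2 <- true_orientation_fn(p, subj, seed = 7)(t)
  a3 <- true_orientation_fn(p, subj, seed = 8)(t)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
})

test_that("hold jitter has the configured stationary SD", {
  p <- protocol_spec(movements = "chin_up")
  subj <- structure(list(
    amplitudes_deg = c(chin_up = 30), jitter_sd_deg = 0.8,
    jitter_tau_s = 0.02), class = "subject_model")
  fn <- true_orientation_fn(p, subj, seed = 3)
  t <- seq(13, 21, by = 1 / 240)  # within the eccentric hold
  ang <- fn(t)
  expect_equal(sd(ang[, "x"]), 0.8, tolerance = 0.08)
  expect_equal(mean(ang[, "x"]), 30, tolerance = 0.05)
})

test_that("attenuation scales recovered ranges multiplicatively", {
  p <- protocol_spec()
  subj <- structure(list(
    amplitudes_deg = setNames(rep(30, 6), MOVEMENTS),
    jitter_sd_deg = 0, jitter_tau_s = 0.5), class = "subject_model")
  fn <- true_orientation_fn(p, subj, seed = 1)
  dev <- device_model("depth", rate = 30,
                      attenuation = c(x = 0.62, y = 1, z = 1))
  rec <- render_recording(fn, face_template(), dev, seed = 1,
                          subject_id = "S01")
  m <- analyze_recording(rec, protocol_annotation(p, "S01"))
  expect_equal(m$range_deg[m$movement == "chin_up"], 18.6,
               tolerance = 1e-6)
  expect_equal(m$range_deg[m$movement == "turn_left"], 30, tolerance = 1e-6)
})

test_that("rendering is invariant to the device world frame", {
  p <- protocol_spec(movements = c("chin_up", "turn_left"))
  subj <- structure(list(
    amplitudes_deg = c(chin_up = 27, turn_left = 24),
    jitter_sd_deg = 0, jitter_tau_s = 0.5), class = "subject_model")
  fn <- true_orientation_fn(p, subj, seed = 2)
  base <- device_model("a", rate = 30)
  moved <- device_model("b", rate = 30,
                        world_rotation = rot_z(123) %*% rot_x(-31),
                        world_offset_mm = c(500, -200, 1800))
  ann <- protocol_annotation(p, "S01")
  m1 <- analyze_recording(render_recording(fn, face_template(), base, 1,
                                           subject_id = "S01"), ann)
  m2 <- analyze_recording(render_recording(fn, face_template(), moved, 1,
                                           subject_id = "S01"), ann)
  expect_equal(m1$range_deg, m2$range_deg, tolerance = 1e-9)
  expect_equal(m1$stability_sd_deg, m2$stability_sd_deg, tolerance = 1e-9)
})

test_that("dropout process obeys its probability settings", {
  p <- protocol_spec(movements = "chin_up")
  subj <- subject_model(p, population_model(), seed = 4)
  fn <- true_orientation_fn(p, subj, seed = 4)
  none <- render_recording(fn, face_template(),
                           device_model("d", 30, dropout_prob = 0), 1)
  expect_true(all(none$valid))
  some <- render_recording(
    fn, face_template(),
    device_model("d", 30, dropout_prob = 0.05, dropout_burst = 8), 1)
  expect_gt(sum(!some$valid), 0)
  # dropout frames carry no coordinates
  expect_true(all(is.na(some$landmarks$sublip[!some$valid, ])))
})

test_that("cohorts pair one trajectory across both devices", {
  p <- protocol_spec(movements = c("chin_up", "turn_left"))
  ideal <- device_model("emt", rate = 240)
  ideal30 <- device_model("depth", rate = 30)
  co <- generate_cohort(2, protocol = p,
                        population = population_model(jitter_sd_deg = 0,
                                                      movement_sd_deg = 0),
                        device_emt = ideal, device_depth = ideal30, seed = 6)
  expect_equal(length(co$subjects), 2)
  s <- co$subjects[[1]]
  # identical ideal device models: recordings differ only in sampling
  m_emt <- analyze_recording(s$rec_emt, s$annotation)
  m_dep <- analyze_recording(s$rec_depth, s$annotation)
  expect_equal(m_emt$range_deg, m_dep$range_deg, tolerance = 1e-6)
  # same master seed reproduces the cohort; subjects differ between them
  co2 <- generate_cohort(2, protocol = p,
                         population = population_model(jitter_sd_deg = 0,
                                                       movement_sd_deg = 0),
                         device_emt = ideal, device_depth = ideal30,
                         seed = 6)
  expect_equal(co$subjects[[2]]$rec_depth$landmarks,
               co2$subjects[[2]]$rec_depth$landmarks)
  expect_false(isTRUE(all.equal(co$subjects[[1]]$subject$amplitudes_deg,
                                co$subjects[[2]]$subject$amplitudes_deg)))
})

test_that("extending a cohort does not perturb existing subjects", {
  p <- protocol_spec(movements = "chin_up")
  co2 <- generate_cohort(2, protocol = p, seed = 10)
  co3 <- generate_cohort(3, protocol = p, seed = 10)
  expect_equal(co2$subjects[[2]]$rec_emt$landmarks,
               co3$subjects[[2]]$rec_emt$landmarks)
})

test_that("heavy depth dropout triggers paired exclusions", {
  p <- protocol_spec()
  co <- generate_cohort(
    2, protocol = p,
    device_depth = device_model_depth(dropout_prob = 0.05,
                                      dropout_burst = 15),
    seed = 13)
  res <- analyze_cohort(co)
  excl <- attr(res$paired, "exclusions")
  expect_gt(nrow(excl), 0)
  # exclusion symmetry: no movement present for only one device
  expect_equal(nrow(res$paired) + nrow(excl),
               2 * length(p$movements))
})
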