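test_that("head frame of the neutral template is the expected basis", {
  f <- landmark_frame(0, neutral_template_points())
  R <- build_head_frame(f)
  expect_true(is_rotation(R, tol = 1e-12))
  expect_equal(R[, 1], c(1, 0, 0), tolerance = 1e-12)   # x toward right canthus
  expect_equal(R[, 2], c(0, 0, -1), tolerance = 1e-12)  # facial-plane normal
  expect_equal(R[, 3], c(0, 1, 0), tolerance = 1e-12)   # z toward world up
})

test_that("a rigidly rotated template yields Q times the neutral frame", {
  pts <- neutral_template_points()
  R0 <- build_head_frame(landmark_frame(0, pts))
  set.seed(11)
  for (i in 1:20) {
    Q <- random_rotation()
    rotated <- lapply(pts, function(p) drop(Q %*% p))
    R <- build_head_frame(landmark_frame(0, rotated))
    expect_equal(R, Q %*% R0, tolerance = 1e-9)
  }
})

test_that("frame construction is invariant to translation", {
  pts <- neutral_template_points()
  R0 <- build_head_frame(landmark_frame(0, pts))
  set.seed(12)
  for (i in 1:10) {
    shift <- rnorm(3, sd = 500)
    moved <- lapply(pts, function(p) p + shift)
    expect_equal(build_head_frame(landmark_frame(0, moved)), R0,
                 tolerance = 1e-12)
  }
})

test_that("degenerate landmark geometry is rejected", {
  pts <- neutral_template_points()
  pts$left_canthus <- pts$right_canthus
  expect_error(build_head_frame(pts), "degenerate")
  pts2 <- neutral_template_points()
  pts2$sublip <- c(0, 0, 0)  # collinear with the canthal line
  expect_error(build_head_frame(pts2), "degenerate")
  expect_error(build_head_frame(list(right_canthus = c(1, 0, 0))), "missing")
})

test_that("dropout frames are refused by frame construction", {
  f <- landmark_frame(0, list(), dropout = TRUE)
  expect_error(build_head_frame(f), "dropout")
})

test_that("euler_xyz inverts euler_to_matrix on simple and composed cases", {
  expect_equal(euler_xyz(diag(3)), c(x = 0, y = 0, z = 0))
  expect_equal(euler_xyz(rot_x(30)), c(x = 30, y = 0, z = 0),
               tolerance = 1e-12)
  expect_equal(euler_xyz(euler_to_matrix(10, 20, 30)),
               c(x = 10, y = 20, z = 30), tolerance = 1e-9)
})

test_that("euler round-trip recovers random angles to 1e-8 degrees", {
  set.seed(21)
  n <- 500
  a <- runif(n, -89, 89)
  b <- runif(n, -88, 88)
  g <- runif(n, -89, 89)
  for (i in seq_len(n)) {
    ang <- euler_xyz(euler_to_matrix(a[i], b[i], g[i]))
    expect_true(all(abs(ang - c(a[i], b[i], g[i])) < 1e-8))
  }
})

test_that("gimbal lock sets z to 0, warns, and still reproduces the matrix", {
  R <- euler_to_matrix(25, 90, 40)
  expect_warning(ang <- euler_xyz(R), "gimbal")
  expect_identical(unname(ang["z"]), 0)
  expect_equal(euler_to_matrix(ang["x"], ang["y"], ang["z"]), R,
               tolerance = 1e-7)
})

test_that("relative orientation matches numerically composed rotations", {
  set.seed(31)
  R <- random_rotation()
  expect_equal(relative_orientation(R, R), diag(3), tolerance = 1e-12)
  expect_equal(relative_orientation(R, diag(3)), R, tolerance = 1e-12)
  ang <- euler_xyz(relative_orientation(rot_x(40), rot_x(10)))
  expect_equal(ang, c(x = 30, y = 0, z = 0), tolerance = 1e-9)
})

test_that("mean orientation averages rotations on the rotation group", {
  R <- random_rotation()
  expect_equal(mean_orientation(rep(list(R), 5)), R, tolerance = 1e-12)
  expect_equal(mean_orientation(list(rot_x(10), rot_x(-10))), diag(3),
               tolerance = 1e-9)
  expect_equal(mean_orientation(list(rot_x(10), rot_x(20))), rot_x(15),
               tolerance = 1e-6)
  set.seed(41)
  for (i in 1:10) {
    Rs <- replicate(4, random_rotation(), simplify = FALSE)
    expect_true(is_rotation(mean_orientation(Rs), tol = 1e-9))
  }
  expect_error(mean_orientation(list()), "empty")
})

test_that("rotation validity checks catch non-rotations", {
  expect_false(is_rotation(diag(3) * 2))
  M <- diag(3); M[1, 1] <- -1  # det -1 reflection
  expect_false(is_rotation(M))
  expect_error(check_rotation(M), "orientation matrix")
  expect_error(euler_xyz(matrix(1, 3, 3)), "orientation matrix")
})
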