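test_that("wilcoxon signed-rank reproduces hand-computable cases", {
  # 6 pairs, all differences positive and distinct: 2 of 64 assignments
  # are as extreme, so exact two-sided p = 0.03125
  w <- wilcoxon_signed_rank(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.03125)
  # perfectly symmetric differences: W+ = W-, p = 1
  w2 <- wilcoxon_signed_rank(rep(0, 4), c(1, -1, 2, -2))
  expect_equal(w2$p_value, 1)
  # all-zero differences: undefined
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("exact wilcoxon p equals the 2^n enumeration oracle", {
  set.seed(101)
  for (rep in 1:120) {
    n <- sample(2:12, 1)
    d <- round(rnorm(n, sd = 3), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    # force distinct magnitudes (tie-free case)
    while (any(duplicated(abs(d)))) d <- d + rnorm(length(d), sd = 1e-3)
    got <- wilcoxon_signed_rank(rep(0, length(d)), d)
    expect_equal(got$p_value, wilcoxon_enumeration_p(d), tolerance = 1e-12)
  }
})

test_that("exact wilcoxon p with tied magnitudes matches enumeration", {
  set.seed(102)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)  # many ties
    got <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(got$p_value, wilcoxon_enumeration_p(d), tolerance = 1e-12)
  }
})

test_that("exact wilcoxon p agrees with stats::wilcox.test on tie-free data", {
  set.seed(103)
  for (rep in 1:40) {
    n <- sample(6:20, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0.3)
    got <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n wilcoxon uses a corrected normal approximation", {
  set.seed(104)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.2)
  got <- wilcoxon_signed_rank(x, y)
  expect_false(got$exact)
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon p is invariant under monotone transforms and swaps", {
  set.seed(105)
  x <- rnorm(10)
  y <- x + rnorm(10, 0.5)
  d <- y - x
  base <- wilcoxon_signed_rank(x, y)
  # strictly monotone transform of |d| preserving rank order and signs
  d2 <- sign(d) * (abs(d)^3 + abs(d))
  expect_equal(wilcoxon_signed_rank(rep(0, 10), d2)$p_value, base$p_value)
  # swapping device order flips the median difference, not p
  swapped <- wilcoxon_signed_rank(y, x)
  expect_equal(swapped$p_value, base$p_value)
  expect_equal(swapped$estimate, -base$estimate)
  expect_true(base$p_value >= 0 && base$p_value <= 1)
})

test_that("paired t-test matches its closed form and degenerate rules", {
  # differences (1, 2, 3): t = mean/(sd/sqrt(n)) = 2*sqrt(3)
  tt <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(tt$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_value, 0.0741799002, tolerance = 1e-9)
  expect_equal(tt$estimate, 2)
  # symmetric differences: t = 0, p = 1
  t0 <- paired_t(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero variance")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t equals a one-sample t on the differences", {
  set.seed(106)
  x <- rnorm(15)
  y <- x + rnorm(15, 0.4)
  got <- paired_t(x, y)
  ref <- stats::t.test(y - x)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

fake_paired <- function(movements, n, f) {
  do.call(rbind, lapply(movements, function(m) {
    v <- f(m, n)
    data.frame(subject = sprintf("S%02d", seq_len(n)), movement = m,
               axis = "x", range_emt = v$re, range_depth = v$rd,
               sd_emt = v$se, sd_depth = v$sd)
  }))
}

test_that("range summaries follow the type-7 quantile rule", {
  p <- fake_paired("chin_up", 5, function(m, n) {
    list(re = 1:5, rd = 1:5, se = rep(1, 5), sd = rep(1, 5))
  })
  s <- summarize_ranges(p)
  emt <- s[s$device == "emt", ]
  expect_equal(emt$median, 3)
  expect_equal(emt$q1, 2)
  expect_equal(emt$q3, 4)
  expect_equal(emt$whisker_low, 2 - 3)
  expect_equal(emt$whisker_high, 4 + 3)
  expect_equal(unique(s$mean_diff_emt_minus_depth), 0)
  # single subject: median is the value, IQR 0
  p1 <- fake_paired("turn_left", 1, function(m, n) {
    list(re = 27, rd = 23, se = 1, sd = 1)
  })
  s1 <- summarize_ranges(p1)
  expect_equal(s1$median, c(27, 23))
  expect_equal(s1$q3 - s1$q1, c(0, 0))
  expect_equal(unique(s1$mean_diff_emt_minus_depth), 4)
})

test_that("stability summaries report mean SD, SE and paired tests", {
  p <- fake_paired(c("chin_down", "turn_left"), 4, function(m, n) {
    list(re = rep(30, n), rd = rep(25, n),
         se = rep(1, n), sd = c(1.5, 1.6, 1.4, 1.5))
  })
  s <- summarize_stability(p, tested_movements = "chin_down")
  tab <- s$table
  expect_equal(tab$mean_sd[tab$device == "emt"], c(1, 1))
  expect_equal(tab$se[tab$device == "emt"], c(0, 0))
  expect_equal(s$tests$movement, "chin_down")
  expect_equal(s$tests$mean_diff_depth_minus_emt, 0.5)
  # per-subject SDs all equal: mean that value, SE 0
  expect_equal(tab$mean_sd[tab$movement == "chin_down" &
                             tab$device == "depth"], 1.5)
  # single subject: SE undefined, reported missing
  p1 <- fake_paired("tilt_left", 1, function(m, n) {
    list(re = 30, rd = 28, se = 0.9, sd = 1.4)
  })
  s1 <- summarize_stability(p1, tested_movements = character())
  expect_true(all(is.na(s1$table$se)))
})

test_that("device mean stability difference is reported on the depth-emt scale", {
  # device means 0.74 (emt) and 1.49 (depth): difference 0.75
  p <- fake_paired("chin_down", 2, function(m, n) {
    list(re = rep(28, n), rd = rep(24, n),
         se = c(0.70, 0.78), sd = c(1.45, 1.53))
  })
  s <- summarize_stability(p, tested_movements = character())
  expect_equal(unique(s$table$mean_sd_diff_depth_minus_emt), 0.75)
})
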