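#' Matched-pairs Wilcoxon signed-rank test
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on paired device
#' measurements, with differences `d = depth - emt`. Zero differences are
#' dropped (the classic Wilcoxon convention); tied absolute differences
#' receive mid-ranks. The statistic reported is `W = min(W+, W-)`. For
#' `n <= exact_limit` the two-sided p-value is exact, computed from the
#' full null distribution of the signed-rank sum over all `2^n` equally
#' likely sign assignments (evaluated by convolution over the rank
#' multiset, which enumerates the same distribution without materialising
#' the assignments); for larger n a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param emt,depth paired numeric vectors (degrees), same length.
#' @param exact_limit largest n (after zero removal) for which the exact
#'   distribution is used.
#' @return An `agreement_test` object: list with `method`, `statistic`
#'   (W), `df` (NA), `p_value`, `n` (pairs used), `estimate` (median
#'   difference, depth - emt) and `exact` flag.
#' @export
wilcoxon_signed_rank <- function(emt, depth, exact_limit = 25) {
  stopifnot(length(emt) == length(depth))
  d <- depth - emt
  d <- d[!is.na(d)]
  med <- stats::median(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= exact_limit) {
    p <- signed_rank_exact_p(r, w_pos)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w_pos - mu) * 0.5
    z <- (w_pos - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(method = "wilcoxon_signed_rank", statistic = w,
                 df = NA_real_, p_value = p, n = n, estimate = med,
                 exact = exact),
            class = "agreement_test")
}

# Exact two-sided p for the signed-rank statistic. r: mid-ranks of |d|
# (may be half-integers); w_pos: observed positive-rank sum. The null
# distribution of W+ is built by convolving the two-point distributions
# {0, r_i} over all ranks (doubled to keep integer support), which is the
# distribution of W+ over all 2^n sign assignments.
signed_rank_exact_p <- function(r, w_pos) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)  # f[k+1] = #assignments with 2*W+ == k
  f[1L] <- 1
  for (w in r2) {
    g <- f
    g[(w + 1L):(total + 1L)] <- g[(w + 1L):(total + 1L)] + f[1L:(total - w + 1L)]
    f <- g
  }
  w2 <- as.integer(round(2 * w_pos))
  n_le <- sum(f[seq_len(w2 + 1L)])
  n_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(n_le, n_ge) / 2^length(r))
}

#' Paired t-test on device measurements
#'
#' Two-sided paired t-test on `d = depth - emt`, used to compare the
#' per-subject stability SDs of the two devices. Delegates to
#' [stats::t.test()] after checking the degenerate cases the pairing can
#' produce.
#'
#' @param emt,depth paired numeric vectors, same length.
#' @return An `agreement_test` object with `statistic` (t), `df`,
#'   `p_value`, `n` and `estimate` (mean difference, depth - emt).
#' @export
paired_t <- function(emt, depth) {
  stopifnot(length(emt) == length(depth))
  d <- depth - emt
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences: t-test undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(d)
  structure(list(method = "paired_t", statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value, n = n,
                 estimate = mean(d), exact = FALSE),
            class = "agreement_test")
}

#' @export
print.agreement_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g%s, n=%d, p=%.4g%s, estimate=%.4g\n",
              x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df=%g", x$df),
              x$n, x$p_value, if (isTRUE(x$exact)) " (exact)" else "",
              x$estimate))
  invisible(x)
}

#' Per-movement summary of movement ranges
#'
#' The distributional summary behind a Tukey box plot of per-subject
#' movement ranges: per movement and device the median, quartiles
#' (linear-interpolation quantile rule, [stats::quantile()] type 7),
#' Tukey whisker bounds at 1.5 IQR, and the per-movement mean device
#' difference (emt - depth).
#'
#' @param paired a paired data frame from [paired_exclusion()].
#' @return A data frame, one row per movement x device.
#' @export
summarize_ranges <- function(paired) {
  stopifnot(nrow(paired) > 0)
  rows <- list()
  for (m in unique(paired$movement)) {
    sub <- paired[paired$movement == m, , drop = FALSE]
    mean_diff <- mean(sub$range_emt - sub$range_depth)
    for (dev in c("emt", "depth")) {
      v <- sub[[paste0("range_", dev)]]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      rows[[length(rows) + 1L]] <- data.frame(
        movement = m, device = dev, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr,
        mean_diff_emt_minus_depth = mean_diff)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-movement summary and tests of positional stability
#'
#' Per movement and device: the mean of the per-subject stability SDs and
#' the standard error of that mean (`sd/sqrt(n)`, `NA` for a single
#' subject), plus [paired_t()] results for the tested movements (by
#' default chin up, chin down, turn left and tilt left, the four
#' positions compared in the study).
#'
#' @param paired a paired data frame from [paired_exclusion()].
#' @param tested_movements movements on which to run the paired t-test.
#' @return A list with `table` (movement x device rows: `n`, `mean_sd`,
#'   `se`, and the device difference of mean SDs) and `tests` (one row
#'   per tested movement: t, df, p, mean difference).
#' @export
summarize_stability <- function(paired,
                                tested_movements = c("chin_up", "chin_down",
                                                     "turn_left",
                                                     "tilt_left")) {
  stopifnot(nrow(paired) > 0)
  rows <- list()
  tests <- list()
  for (m in unique(paired$movement)) {
    sub <- paired[paired$movement == m, , drop = FALSE]
    means <- numeric(2)
    for (dev in c("emt", "depth")) {
      v <- sub[[paste0("sd_", dev)]]
      means[[match(dev, c("emt", "depth"))]] <- mean(v)
      rows[[length(rows) + 1L]] <- data.frame(
        movement = m, device = dev, n = length(v), mean_sd = mean(v),
        se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
        mean_sd_diff_depth_minus_emt = NA_real_)
    }
    diff_m <- means[2] - means[1]
    rows[[length(rows) - 1L]]$mean_sd_diff_depth_minus_emt <- diff_m
    rows[[length(rows)]]$mean_sd_diff_depth_minus_emt <- diff_m
    if (m %in% tested_movements && nrow(sub) >= 2L) {
      tt <- paired_t(sub$sd_emt, sub$sd_depth)
      tests[[length(tests) + 1L]] <- data.frame(
        movement = m, t = tt$statistic, df = tt$df, p_value = tt$p_value,
        n = tt$n, mean_diff_depth_minus_emt = tt$estimate)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(movement = character(), t = numeric(), df = numeric(),
               p_value = numeric(), n = integer(),
               mean_diff_depth_minus_emt = numeric())
  rownames(tests) <- NULL
  list(table = table, tests = tests)
}

#' Device-agreement analysis of a paired dataset
#'
#' The full between-device comparison: per-movement Wilcoxon signed-rank
#' tests on movement ranges, paired t-tests on stability SDs (tested
#' movements only), and the two summary tables.
#'
#' @param paired a paired data frame from [paired_exclusion()].
#' @param tested_movements see [summarize_stability()].
#' @return A list: `ranges` (summary table), `range_tests` (one row per
#'   movement: W, p, n, median difference), `stability` (summary table)
#'   and `stability_tests`.
#' @export
device_agreement <- function(paired,
                             tested_movements = c("chin_up", "chin_down",
                                                  "turn_left", "tilt_left")) {
  range_tests <- do.call(rbind, lapply(unique(paired$movement), function(m) {
    sub <- paired[paired$movement == m, , drop = FALSE]
    wt <- wilcoxon_signed_rank(sub$range_emt, sub$range_depth)
    data.frame(movement = m, W = wt$statistic, p_value = wt$p_value,
               n = wt$n, exact = wt$exact,
               median_diff_depth_minus_emt = wt$estimate)
  }))
  stab <- summarize_stability(paired, tested_movements)
  list(ranges = summarize_ranges(paired), range_tests = range_tests,
       stability = stab$table, stability_tests = stab$tests)
}
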