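#' Box plot of movement ranges by device
#'
#' Tukey box-and-whisker plot of per-subject movement ranges, one pair of
#' boxes (reference device, evaluated device) per movement, with a dashed
#' line at the protocol target amplitude. A plotting convenience over the
#' paired dataset; the numbers behind it come from [summarize_ranges()].
#'
#' @param paired a paired data frame from [paired_exclusion()].
#' @param target_deg target amplitude for the dashed reference line.
#' @return Invisibly, the list returned by [graphics::boxplot()].
#' @export
plot_ranges <- function(paired, target_deg = 30) {
  movements <- intersect(MOVEMENTS, unique(paired$movement))
  values <- list()
  for (m in movements) {
    sub <- paired[paired$movement == m, , drop = FALSE]
    values[[paste0(m, "\nemt")]] <- sub$range_emt
    values[[paste0(m, "\ndepth")]] <- sub$range_depth
  }
  b <- graphics::boxplot(values, range = 1.5, las = 2,
                         col = rep(c("grey80", "grey50"),
                                   length(movements)),
                         ylab = "range of movement (deg)",
                         cex.axis = 0.7)
  graphics::abline(h = target_deg, lty = 2)
  invisible(b)
}

#' Bar chart of stability SDs by device
#'
#' Mean per-subject stability SD per movement and device, with standard
#' error bars; the numbers come from [summarize_stability()].
#'
#' @param paired a paired data frame from [paired_exclusion()].
#' @return Invisibly, the summary table plotted.
#' @export
plot_stability <- function(paired) {
  tab <- summarize_stability(paired)$table
  tab <- tab[order(match(tab$movement, MOVEMENTS)), , drop = FALSE]
  h <- matrix(tab$mean_sd, nrow = 2,
              dimnames = list(c("emt", "depth"), unique(tab$movement)))
  mid <- graphics::barplot(h, beside = TRUE, las = 2,
                           col = c("grey80", "grey50"),
                           ylab = "stability SD (deg)",
                           ylim = c(0, max(tab$mean_sd + 2 * tab$se,
                                           na.rm = TRUE)),
                           legend.text = TRUE, cex.names = 0.7)
  se <- matrix(tab$se, nrow = 2)
  ok <- is.finite(se)
  graphics::arrows(mid[ok], h[ok] - se[ok], mid[ok], h[ok] + se[ok],
                   angle = 90, code = 3, length = 0.03)
  invisible(tab)
}
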