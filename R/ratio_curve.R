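#' Enhanced/repressed ratio over sliding windows of p-ranked intervals
#'
#' The genome-wide-effect statistic: intervals are ranked by increasing
#' p-value and, over sliding windows of `W` intervals, the ratio
#' r = (#FC > 1) / (#FC < 1) is computed and attached to the p-value of the
#' first (lowest-p) interval of the window. Under no genotype effect r
#' fluctuates around 1 at every p; a sustained r < 1 at low p indicates a
#' genome-wide loss of accessibility in the mutant (r > 1, a gain).
#'
#' Ranking ties on p are broken by decreasing |log2 FC|, then by genomic
#' position (bin index), giving a deterministic order. Intervals with
#' FC exactly 1 stay inside the window but are counted in neither the
#' numerator nor the denominator; intervals with undefined FC (zero control
#' mean) are dropped before ranking.
#'
#' @param x a [diff_accessibility()] fit, or a data.frame with columns
#'   `fold_change`, `p_value` (and optionally `bin`, `chrom`, `start`,
#'   `end`).
#' @param W window size in intervals (default 1000).
#' @param step window start increment (default 1, a fully sliding window).
#' @return object of class `ratio_curve`: list with `points` (data.frame:
#'   `start_rank`, `leading_p`, `ratio`, `n_enhanced`, `n_repressed`,
#'   `n_ties`), `ranked` (the p-ranked interval table), `W`, `step`.
#' @seealso [select_by_ratio()], [plot.ratio_curve()]
#' @export
ratio_curve <- function(x, W = 1000L, step = 1L) {
  stats_df <- if (inherits(x, "diff_access")) x$intervals else as.data.frame(x)
  if (!all(c("fold_change", "p_value") %in% names(stats_df)))
    stop("need columns fold_change and p_value")
  stats_df <- stats_df[!is.na(stats_df$fold_change), , drop = FALSE]
  n <- nrow(stats_df)
  if (n < W)
    stop("only ", n, " intervals with defined fold change; ",
         "need at least W = ", W, " (use a smaller W)")
  if (step < 1L) stop("step must be >= 1")

  pos <- if ("bin" %in% names(stats_df)) stats_df$bin else seq_len(n)
  o <- order(stats_df$p_value, -abs(log2(stats_df$fold_change)), pos)
  ranked <- stats_df[o, , drop = FALSE]
  rownames(ranked) <- NULL

  enh <- cumsum(c(0L, as.integer(ranked$fold_change > 1)))
  rep_ <- cumsum(c(0L, as.integer(ranked$fold_change < 1)))
  starts <- seq.int(1L, n - W + 1L, by = step)
  n_enh <- enh[starts + W] - enh[starts]
  n_rep <- rep_[starts + W] - rep_[starts]
  ratio <- ifelse(n_rep > 0, n_enh / n_rep, NA_real_)

  points <- data.frame(start_rank = starts,
                       leading_p = ranked$p_value[starts],
                       ratio = ratio,
                       n_enhanced = n_enh,
                       n_repressed = n_rep,
                       n_ties = W - n_enh - n_rep)
  structure(list(points = points, ranked = ranked, W = W, step = step),
            class = "ratio_curve")
}

#' @export
print.ratio_curve <- function(x, ...) {
  p <- x$points
  cat(sprintf("ratio_curve: %d windows of %d p-ranked intervals (step %d)\n",
              nrow(p), x$W, x$step))
  cat(sprintf("  ratio at lowest p: %.3f; range %.3f - %.3f\n",
              p$ratio[1], min(p$ratio, na.rm = TRUE),
              max(p$ratio, na.rm = TRUE)))
  invisible(x)
}

#' Plot the enhanced/repressed ratio curve
#'
#' Ratio against the leading window p-value on a log10 x-axis, with a
#' reference line at 1.
#'
#' @param x a `ratio_curve` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ratio_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$leading_p, p$ratio, log = "x", type = "l",
                 xlab = "first window p-value",
                 ylab = "enhanced / repressed ratio", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Select intervals at a ratio cutoff
#'
#' The low-p prefix of the ranked interval list captures the directional
#' effect; its extent is delimited by the first sliding window whose ratio
#' exceeds the cutoff `r_star`. Two selection rules are offered:
#' `"prefix"` (default) selects every interval ranked before the start of
#' the first window with ratio > `r_star`; `"windows"` selects the union of
#' intervals belonging to windows with ratio <= `r_star`.
#'
#' @param curve a [ratio_curve()] built with `step = 1`.
#' @param r_star ratio cutoff (default 0.60).
#' @param mode `"prefix"` or `"windows"`.
#' @return object of class `ratio_selection`: list with `intervals`
#'   (selected rows of the ranked table), `r_star`, `mode`, `boundary_p`
#'   (p-value at the selection boundary, NA if empty).
#' @export
select_by_ratio <- function(curve, r_star = 0.60,
                            mode = c("prefix", "windows")) {
  stopifnot(inherits(curve, "ratio_curve"))
  mode <- match.arg(mode)
  if (curve$step != 1L)
    stop("select_by_ratio requires a curve built with step = 1")
  p <- curve$points
  below <- !is.na(p$ratio) & p$ratio <= r_star
  if (!any(below)) {
    warning("no window ratio <= ", r_star, "; empty selection")
    sel <- integer(0)
  } else if (mode == "prefix") {
    over <- which(is.na(p$ratio) | p$ratio > r_star)
    cut_rank <- if (length(over)) p$start_rank[min(over)] else
      nrow(curve$ranked) + 1L
    sel <- seq_len(cut_rank - 1L)
  } else {
    idx <- which(below)
    sel <- sort(unique(unlist(lapply(idx, function(i)
      seq.int(p$start_rank[i], p$start_rank[i] + curve$W - 1L)))))
  }
  structure(list(
    intervals = curve$ranked[sel, , drop = FALSE],
    r_star = r_star, mode = mode,
    boundary_p = if (length(sel)) max(curve$ranked$p_value[sel]) else NA_real_),
    class = "ratio_selection")
}

#' @export
print.ratio_selection <- function(x, ...) {
  cat(sprintf("ratio_selection: %d intervals at ratio cutoff %.2f (%s rule)",
              nrow(x$intervals), x$r_star, x$mode))
  if (!is.na(x$boundary_p))
    cat(sprintf("; boundary p = %.3g", x$boundary_p))
  cat("\n")
  invisible(x)
}

#' Write curve points or a selection as TSV / BED-compatible text
#'
#' @param x a `ratio_curve` or `ratio_selection`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ratio_output <- function(x, path) {
  df <- if (inherits(x, "ratio_curve")) x$points else x$intervals
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
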