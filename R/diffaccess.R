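#' Library profiles and low-count exclusion
#'
#' Tissue ATAC libraries vary widely in usable depth; libraries with far
#' fewer subnucleosomal reads than their peers lack counts over much of the
#' genome and are excluded before testing. The total here is the number of
#' read extremities (= 2 x fragments) of the chosen length class, i.e. the
#' column sums of the count matrix.
#'
#' @param counts bins x libraries matrix from [count_matrix()].
#' @param groups factor/character of `control`/`mutant` per column.
#' @param min_reads exclusion threshold on the per-library extremity total
#'   (default 1e7, appropriate for full-depth mammalian libraries; scale it
#'   with simulated depth).
#' @return list with `kept` (column indices), `excluded` (data.frame of
#'   library, total, reason) and `totals`.
#' @export
exclude_low_count_libraries <- function(counts, groups, min_reads = 1e7) {
  groups <- .check_groups(groups, ncol(counts))
  totals <- colSums(counts)
  kept <- which(totals >= min_reads)
  excluded <- which(totals < min_reads)
  for (g in levels(groups)) {
    if (sum(groups[kept] == g) < 2L)
      stop("group '", g, "' has fewer than 2 libraries after exclusion; ",
           "rank test undefined")
  }
  list(kept = kept,
       excluded = data.frame(
         library = colnames(counts)[excluded] %||% as.character(excluded),
         total = unname(totals[excluded]),
         reason = if (length(excluded)) sprintf("total %.3g < %.3g reads",
                                                totals[excluded], min_reads)
                  else character(0)),
       totals = totals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (!all(levels(groups) %in% c("control", "mutant")))
    groups <- factor(as.character(groups), levels = unique(as.character(groups)))
  else
    groups <- factor(as.character(groups), levels = c("control", "mutant"))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(groups) != n) stop("one group label per library required")
  groups
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each library j,
#' `s_j = median_i(count_ij / geomean_i)` where the geometric mean is taken
#' across libraries and the median across intervals with all-positive
#' counts. Size factors are rescaled to unit geometric mean so that
#' normalization is idempotent (re-estimating on a normalized matrix yields
#' factors of 1); this rescaling changes all libraries by a common constant
#' and therefore affects neither fold changes nor rank tests.
#'
#' @param counts intervals x libraries matrix (typically the retained rows
#'   of the raw count matrix).
#' @return numeric vector of positive size factors, one per column.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("size factors need >= 2 libraries")
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop("no interval has positive counts in every library; ",
         "reduce bin sparsity (e.g. stronger retention filter)")
  s <- exp(apply(logc[ok, , drop = FALSE] - loggeo[ok], 2L,
                 stats::median))
  s <- s / exp(mean(log(s)))
  s
}

#' Interval retention filter
#'
#' An interval (bin) enters the differential analysis only if it carries a
#' mean of at least `min_mean` read extremities across the kept libraries,
#' computed on raw counts.
#'
#' @param counts intervals x libraries raw count matrix (kept libraries).
#' @param min_mean retention threshold on the per-interval mean (default 5,
#'   inclusive).
#' @return integer vector of retained row indices.
#' @export
retention_filter <- function(counts, min_mean = 5) {
  which(rowMeans(as.matrix(counts)) >= min_mean)
}

#' Differential accessibility between two genotype groups
#'
#' The central fit. Starting from a bins x libraries read-extremity count
#' matrix, this (1) excludes low-count libraries, (2) retains intervals with
#' a raw mean of at least `min_mean` extremities, (3) estimates
#' median-of-ratios size factors on the retained intervals and normalizes,
#' and (4) for every retained interval computes the fold change
#' FC = mean(mutant) / mean(control) of normalized counts and a two-sided
#' Mann-Whitney p-value on the per-library normalized counts (exact null
#' when tie-free and total n <= 20, mid-rank normal approximation with tie
#' correction otherwise). Intervals with a zero control mean have undefined
#' FC; they are flagged and excluded from downstream ratio curves.
#'
#' @param counts bins x libraries integer matrix from [count_matrix()].
#' @param groups `control` / `mutant` label per column.
#' @param binning optional [genome_binning()]; when given, genomic
#'   coordinates are attached to the interval table.
#' @param min_mean retention threshold (mean raw extremities; default 5).
#' @param min_reads library exclusion threshold (default 1e7 extremities;
#'   pass a value scaled to the depth of your libraries).
#' @param per_base optional list `(positions, ...)` reserved for pooled
#'   per-position testing; see Details.
#' @details The per-library exact test has a p-value floor of
#'   `2 / choose(n1 + n2, n1)` (about 1.2e-3 at 6 vs 7). An alternative,
#'   speculative mode that pools per-position extremity counts within each
#'   interval can reach lower p-values but changes the unit of replication
#'   from animals to positions; it is deliberately not the default and is
#'   exposed via [mw_test()] on user-pooled data rather than here.
#' @return object of class `diff_access`: list with `intervals` (data.frame:
#'   `bin`, optional `chrom`/`start`/`end`, `mean_control`, `mean_mutant`,
#'   `fold_change`, `p_value`, `fc_defined`), `size_factors`, `groups`,
#'   `kept`, `excluded`, `params`.
#' @seealso [ratio_curve()], [plot.diff_access()]
#' @export
diff_accessibility <- function(counts, groups, binning = NULL,
                               min_mean = 5, min_reads = 1e7) {
  counts <- as.matrix(counts)
  groups <- .check_groups(groups, ncol(counts))
  excl <- exclude_low_count_libraries(counts, groups, min_reads = min_reads)
  kept <- excl$kept
  kc <- counts[, kept, drop = FALSE]
  kg <- droplevels(groups[kept])

  retained <- retention_filter(kc, min_mean = min_mean)
  if (length(retained) == 0L)
    stop("no interval passes the retention filter (min_mean = ", min_mean, ")")
  rc <- kc[retained, , drop = FALSE]

  s <- size_factors(rc)
  norm <- sweep(rc, 2L, s, "/")

  is_mut <- kg == levels(kg)[2]
  mean_con <- rowMeans(norm[, !is_mut, drop = FALSE])
  mean_mut <- rowMeans(norm[, is_mut, drop = FALSE])
  fc <- ifelse(mean_con > 0, mean_mut / mean_con, NA_real_)

  mw <- mw_test_rows(norm, kg)

  intervals <- data.frame(bin = retained,
                          mean_control = mean_con,
                          mean_mutant = mean_mut,
                          fold_change = fc,
                          p_value = mw$p_value,
                          fc_defined = mean_con > 0)
  if (!is.null(binning)) {
    co <- bin_coords(binning, retained)
    intervals <- cbind(co, intervals)
  }
  rownames(intervals) <- NULL

  structure(list(
    intervals = intervals,
    size_factors = stats::setNames(s, colnames(rc)),
    groups = kg,
    kept = kept,
    excluded = excl$excluded,
    library_totals = excl$totals,
    params = list(min_mean = min_mean, min_reads = min_reads,
                  n_bins = nrow(counts), n_retained = length(retained))),
    class = "diff_access")
}

#' @export
print.diff_access <- function(x, ...) {
  g <- table(x$groups)
  cat("Differential accessibility fit\n")
  cat(sprintf("  libraries: %s (%d excluded for low counts)\n",
              paste(sprintf("%d %s", g, names(g)), collapse = " vs "),
              nrow(x$excluded)))
  cat(sprintf("  intervals retained (mean >= %g): %d of %d (%.2f%%)\n",
              x$params$min_mean, x$params$n_retained, x$params$n_bins,
              100 * x$params$n_retained / x$params$n_bins))
  ok <- x$intervals$fc_defined
  cat(sprintf("  fold-change range: %.2f - %.2f; p-value range: %.2g - %.2g\n",
              min(x$intervals$fold_change[ok]), max(x$intervals$fold_change[ok]),
              min(x$intervals$p_value), max(x$intervals$p_value)))
  invisible(x)
}

#' @export
summary.diff_access <- function(object, p_tiers = c(5e-4, 1e-2, 5e-2), ...) {
  iv <- object$intervals
  tier_counts <- vapply(p_tiers, function(p) sum(iv$p_value < p), numeric(1))
  out <- list(
    n_retained = nrow(iv),
    n_fc_undefined = sum(!iv$fc_defined),
    n_enhanced = sum(iv$fc_defined & iv$fold_change > 1),
    n_repressed = sum(iv$fc_defined & iv$fold_change < 1),
    p_tiers = stats::setNames(tier_counts, format(p_tiers)),
    size_factors = object$size_factors,
    excluded = object$excluded)
  class(out) <- "summary.diff_access"
  out
}

#' @export
print.summary.diff_access <- function(x, ...) {
  cat("Differential accessibility summary\n")
  cat(sprintf("  retained intervals: %d (%d with undefined FC)\n",
              x$n_retained, x$n_fc_undefined))
  cat(sprintf("  enhanced (FC > 1): %d   repressed (FC < 1): %d\n",
              x$n_enhanced, x$n_repressed))
  cat("  intervals below p tiers:\n")
  for (i in seq_along(x$p_tiers))
    cat(sprintf("    p < %s: %d\n", names(x$p_tiers)[i], x$p_tiers[i]))
  if (nrow(x$excluded)) {
    cat("  excluded libraries:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("    %s (%s)\n", x$excluded$library[i], x$excluded$reason[i]))
  }
  invisible(x)
}

#' Volcano-style plot of fold changes against p-values
#'
#' Fold change on a log2 x-axis, p-value on a reversed log10 y-axis; values
#' right of 1 denote enhanced accessibility in the mutant, left of 1
#' repressed accessibility.
#'
#' @param x a `diff_access` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.diff_access <- function(x, ...) {
  iv <- x$intervals[x$intervals$fc_defined, ]
  graphics::plot(log2(iv$fold_change), -log10(iv$p_value),
                 pch = 16, cex = 0.3, col = grDevices::grey(0.3, 0.5),
                 xlab = "log2 fold change (mutant / control)",
                 ylab = "-log10 p-value", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Extract the per-interval statistics table
#'
#' @param x a `diff_access` object.
#' @return data.frame of retained intervals with means, fold change and
#'   p-value.
#' @export
interval_stats <- function(x) {
  stopifnot(inherits(x, "diff_access"))
  x$intervals
}

#' Write the interval statistics table as TSV
#'
#' @param x a `diff_access` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_interval_stats <- function(x, path) {
  data.table::fwrite(interval_stats(x), path, sep = "\t", quote = FALSE,
                     scipen = 50)
  invisible(path)
}
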