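#' Fixed-width genome binning
#'
#' Tiles a genome into contiguous, non-overlapping intervals of `bin_width`
#' base pairs per chromosome (0-based, half-open). The last bin of each
#' chromosome is truncated at the chromosome end. Bins are kept implicit:
#' the object stores only chromosome sizes, the bin width and cumulative
#' per-chromosome bin offsets, so tiling a full mammalian genome
#' (2.7e9 bp at 100 bp, i.e. 2.7e7 bins) costs nothing until counts are
#' materialised.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (name, length) as read by [read_chrom_sizes()].
#' @param bin_width bin width in bp (default 100).
#' @return An object of class `genome_binning` with fields `chrom_sizes`,
#'   `bin_width`, `bins_per_chrom`, `offsets` (0-based bin offset of each
#'   chromosome) and `n_bins`.
#' @examples
#' b <- genome_binning(c(chr1 = 1e6, chr2 = 5e5), bin_width = 100)
#' b$n_bins  # 15000
#' @export
genome_binning <- function(chrom_sizes, bin_width = 100L) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- as.numeric(chrom_sizes[[2]])
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names in chrom_sizes")
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes < 1))
    stop("chromosome lengths must be positive")
  bin_width <- as.numeric(bin_width)
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width < 1)
    stop("bin_width must be a single positive integer")
  bins_per_chrom <- ceiling(chrom_sizes / bin_width)
  offsets <- c(0, cumsum(bins_per_chrom))[seq_along(chrom_sizes)]
  names(offsets) <- names(chrom_sizes)
  structure(
    list(chrom_sizes = chrom_sizes, bin_width = bin_width,
         bins_per_chrom = bins_per_chrom, offsets = offsets,
         n_bins = sum(bins_per_chrom)),
    class = "genome_binning")
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("genome_binning: %d chromosome(s), %.4g bp total, %g-bp bins, %.4g bins\n",
              length(x$chrom_sizes), sum(x$chrom_sizes), x$bin_width, x$n_bins))
  invisible(x)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  sizes <- tab$size
  names(sizes) <- tab$chrom
  sizes
}

#' Write a chrom.sizes file
#' @param chrom_sizes named numeric vector.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(
    data.frame(names(chrom_sizes), format(chrom_sizes, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map genomic positions to global bin indices
#'
#' @param binning a [genome_binning()] object.
#' @param chrom character vector of chromosome names.
#' @param pos 0-based positions.
#' @return 1-based global bin indices (numeric; may exceed 2^31 - 1 on very
#'   large genomes).
#' @export
bin_index <- function(binning, chrom, pos) {
  stopifnot(inherits(binning, "genome_binning"))
  off <- binning$offsets[chrom]
  if (anyNA(off)) {
    bad <- unique(chrom[is.na(off)])
    stop("chromosome(s) not in binning: ", paste(bad, collapse = ", "))
  }
  if (any(pos < 0) || any(pos >= binning$chrom_sizes[chrom]))
    stop("position outside chromosome bounds")
  unname(off + pos %/% binning$bin_width + 1)
}

#' Genomic coordinates of global bin indices
#'
#' Inverse of [bin_index()]: returns the chromosome, 0-based start and
#' (truncated) end of each bin.
#'
#' @inheritParams bin_index
#' @param idx 1-based global bin indices.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
bin_coords <- function(binning, idx) {
  stopifnot(inherits(binning, "genome_binning"))
  if (any(idx < 1) || any(idx > binning$n_bins)) stop("bin index out of range")
  bounds <- c(0, cumsum(binning$bins_per_chrom))
  ci <- findInterval(idx - 1, bounds[-length(bounds)], rightmost.closed = FALSE)
  chrom <- names(binning$chrom_sizes)[ci]
  local_bin <- idx - 1 - binning$offsets[ci]
  start <- local_bin * binning$bin_width
  end <- pmin(start + binning$bin_width, binning$chrom_sizes[ci])
  data.frame(chrom = chrom, start = unname(start), end = unname(end),
             stringsAsFactors = FALSE)
}
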