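#' Read ATAC fragment records from a BED3+ file or a paired-end BAM
#'
#' Fragments are DNA molecules delimited by two Tn5 insertion events; their
#' two termini ("read extremities") mark accessible positions. Records are
#' validated against a [genome_binning()]: fragments on chromosomes absent
#' from the binning are dropped (and counted in the report), records with
#' `end <= start` are rejected, and malformed lines raise an error naming
#' the line.
#'
#' Coordinates are 0-based, half-open throughout (BED native). For BAM input
#' (requires the `Rsamtools` package), properly paired plus-strand mates
#' with positive template length are converted to the same convention, so a
#' pair whose template spans `[105, 245)` yields the same record as the BED
#' line `chr1  105  245`.
#'
#' @param path BED3+ file (plain text, optionally gzipped) or a `.bam` file.
#' @param binning a [genome_binning()] giving the chromosome namespace.
#' @return list with `fragments` (data.frame: `chrom`, `start`, `end`,
#'   `length`) and `report` (counts of records read, dropped by chromosome,
#'   rejected, and per length class).
#' @seealso [classify_length()], [count_extremities()]
#' @export
read_fragments <- function(path, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  if (!file.exists(path)) stop("fragment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    frag <- .read_fragments_bam(path)
  } else {
    frag <- .read_fragments_bed(path)
  }
  n_read <- nrow(frag)
  known <- frag$chrom %in% names(binning$chrom_sizes)
  n_dropped_chrom <- sum(!known)
  frag <- frag[known, , drop = FALSE]
  bad <- frag$end <= frag$start | frag$start < 0 |
    frag$end > binning$chrom_sizes[frag$chrom]
  n_rejected <- sum(bad)
  if (n_rejected > 0)
    message(n_rejected, " record(s) rejected (non-positive length or out of bounds)")
  frag <- frag[!bad, , drop = FALSE]
  frag$length <- frag$end - frag$start
  rownames(frag) <- NULL
  cls <- classify_length(frag$length)
  list(fragments = frag,
       report = list(n_read = n_read,
                     n_dropped_chrom = n_dropped_chrom,
                     n_rejected = n_rejected,
                     n_kept = nrow(frag),
                     class_counts = table(cls)))
}

.read_fragments_bed <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      select = 1:3, col.names = c("chrom", "start", "end"),
                      colClasses = list(character = 1),
                      data.table = FALSE, showProgress = FALSE),
    error = function(e) stop("failed to parse BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(dt[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1]
      stop("malformed BED record at line ", line, " of ", path,
           " (non-numeric ", col, ")", call. = FALSE)
    }
    dt[[col]] <- v
  }
  dt
}

.read_fragments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isMinusStrand = FALSE,
                                  isUnmappedQuery = FALSE),
    what = c("rname", "pos", "isize"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(rec$isize) & rec$isize > 0 & !is.na(rec$pos)
  data.frame(chrom = as.character(rec$rname)[keep],
             start = rec$pos[keep] - 1,       # SAM is 1-based
             end = rec$pos[keep] - 1 + rec$isize[keep],
             stringsAsFactors = FALSE)
}

#' Write fragments as a BED3 file
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  data.table::fwrite(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE,
                     scipen = 50)
  invisible(path)
}

#' Classify fragment lengths into nucleosome-occupancy classes
#'
#' Tn5 fragments shorter than one nucleosome footprint arise from open
#' chromatin; longer fragments span one or more nucleosomes. The classes
#' are: subnucleosomal (length <= 140 bp), nucleosomal (141-280 bp) and
#' poly-nucleosomal (>= 281 bp).
#'
#' @param len integer/numeric vector of fragment lengths (bp, >= 1).
#' @return factor with levels `subnucleosomal`, `nucleosomal`,
#'   `polynucleosomal`.
#' @examples
#' classify_length(c(140, 141, 280, 281))
#' @export
classify_length <- function(len) {
  if (any(!is.finite(len)) || any(len < 1))
    stop("fragment length must be >= 1")
  cut(len, breaks = c(0, 140, 280, Inf),
      labels = c("subnucleosomal", "nucleosomal", "polynucleosomal"),
      right = TRUE)
}

#' Count fragment extremities over a genome binning
#'
#' Every fragment contributes exactly two extremities, at 0-based positions
#' `start` and `end - 1`; each extremity increments the count of the bin
#' containing it. By default only subnucleosomal fragments are counted, the
#' subset carrying the cleanest accessibility signal; pass
#' `class_filter = NULL` to count all fragments.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (and optionally
#'   `length`), as produced by [read_fragments()] or [simulate_fragments()].
#' @param binning a [genome_binning()].
#' @param class_filter one of `"subnucleosomal"`, `"nucleosomal"`,
#'   `"polynucleosomal"`, or `NULL` for no filtering.
#' @return integer vector of length `binning$n_bins` (one count column).
#' @examples
#' b <- genome_binning(c(chr1 = 1000), 100)
#' fr <- data.frame(chrom = "chr1", start = 105, end = 245)
#' which(count_extremities(fr, b, class_filter = NULL) > 0)  # bins 2 and 3
#' @export
count_extremities <- function(fragments, binning,
                              class_filter = "subnucleosomal") {
  stopifnot(inherits(binning, "genome_binning"))
  if (binning$n_bins > .Machine$integer.max)
    stop("dense count vector unsupported for > 2^31 bins")
  if (!is.null(class_filter)) {
    class_filter <- match.arg(class_filter,
      c("subnucleosomal", "nucleosomal", "polynucleosomal"))
    len <- if ("length" %in% names(fragments)) fragments$length
           else fragments$end - fragments$start
    fragments <- fragments[classify_length(len) == class_filter, , drop = FALSE]
  }
  n <- as.integer(binning$n_bins)
  if (nrow(fragments) == 0L) return(integer(n))
  pos <- c(fragments$start, fragments$end - 1)
  chrom <- rep(fragments$chrom, 2L)
  idx <- bin_index(binning, chrom, pos)
  tabulate(idx, nbins = n)
}

#' Build a bins-by-libraries extremity count matrix
#'
#' @param libraries named list of fragment data.frames (one per library), or
#'   of file paths readable by [read_fragments()].
#' @param binning a [genome_binning()].
#' @param class_filter passed to [count_extremities()].
#' @return integer matrix (bins x libraries) with library names as columns;
#'   each column sums to twice the number of class-filtered fragments.
#' @export
count_matrix <- function(libraries, binning, class_filter = "subnucleosomal") {
  if (is.null(names(libraries)))
    names(libraries) <- sprintf("lib%02d", seq_along(libraries))
  cols <- lapply(libraries, function(x) {
    if (is.character(x)) x <- read_fragments(x, binning)$fragments
    count_extremities(x, binning, class_filter)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(libraries)
  mat
}

#' Write per-library bin counts as a tab-separated table
#'
#' Emits one row per non-zero bin: `chrom`, `bin_start`, `bin_end`, `count`.
#'
#' @param counts integer vector from [count_extremities()].
#' @param binning the matching [genome_binning()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_bin_counts <- function(counts, binning, path) {
  nz <- which(counts > 0)
  co <- bin_coords(binning, nz)
  data.table::fwrite(
    data.frame(chrom = co$chrom, bin_start = co$start, bin_end = co$end,
               count = counts[nz]),
    path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
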