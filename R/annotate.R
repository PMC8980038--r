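#' Convert an interval table to GRanges
#'
#' @param df data.frame with `chrom`, `start`, `end` in 0-based half-open
#'   coordinates (BED convention).
#' @param chrom_sizes optional named vector; when given, used as seqlengths
#'   and intervals are validated against it.
#' @return a `GRanges` (1-based closed internally, as usual for
#'   Bioconductor).
#' @export
intervals_to_granges <- function(df, chrom_sizes = NULL) {
  if (!all(c("chrom", "start", "end") %in% names(df)))
    stop("need columns chrom, start, end")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if (!is.null(chrom_sizes)) {
    bad <- !as.character(GenomeInfoDb::seqnames(gr)) %in% names(chrom_sizes)
    if (any(bad))
      stop("chromosome(s) not in chrom_sizes: ",
           paste(unique(as.character(GenomeInfoDb::seqnames(gr))[bad]),
                 collapse = ", "))
    sl <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
    suppressWarnings(GenomeInfoDb::seqinfo(gr) <-
      GenomeInfoDb::Seqinfo(seqnames = names(sl),
                            seqlengths = as.integer(sl)))
    if (any(GenomicRanges::end(gr) > sl[as.character(GenomeInfoDb::seqnames(gr))]))
      stop("interval beyond chromosome end")
  }
  gr
}

#' Read a feature set (genes or cCREs) from BED or GFF3
#'
#' Thin wrapper around `rtracklayer::import()`; GFF input is filtered to
#' `type == "gene"` when a type column is present. Requires the
#' `rtracklayer` package.
#'
#' @param path BED or GFF3 file.
#' @return a `GRanges`.
#' @export
read_features <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_features requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE) &&
      "type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene"))
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  gr
}

#' Build 20-kb gene flanks
#'
#' For each gene `[s, e)` the upstream flank `[s - flank, s)` and the
#' downstream flank `[e, e + flank)` are produced (strand-agnostic: both
#' sides of every gene), clipped at chromosome ends. With
#' `trim_genic = TRUE` any part of a flank overlapping a gene body (of any
#' gene) is removed, which makes flanks suitable for the mutually exclusive
#' gene / flank / intergenic summary.
#'
#' @param genes a `GRanges` of gene bodies.
#' @param flank flank width in bp (default 20000).
#' @param chrom_sizes named vector used for clipping (optional if `genes`
#'   carries seqlengths).
#' @param trim_genic remove gene-body overlap from the flanks
#'   (default TRUE).
#' @return a `GRanges` of flank intervals.
#' @export
make_flanks <- function(genes, flank = 20000, chrom_sizes = NULL,
                        trim_genic = TRUE) {
  up <- GenomicRanges::flank(genes, width = flank, start = TRUE,
                             ignore.strand = TRUE)
  down <- GenomicRanges::flank(genes, width = flank, start = FALSE,
                               ignore.strand = TRUE)
  fl <- c(up, down)
  if (!is.null(chrom_sizes)) {
    sl <- chrom_sizes[GenomeInfoDb::seqlevels(fl)]
    suppressWarnings(GenomeInfoDb::seqinfo(fl) <-
      GenomeInfoDb::Seqinfo(seqnames = names(sl),
                             seqlengths = as.integer(sl)))
  }
  fl <- GenomicRanges::trim(fl)
  fl <- fl[GenomicRanges::width(fl) > 0]
  if (trim_genic)
    fl <- GenomicRanges::setdiff(fl, genes, ignore.strand = TRUE)
  GenomicRanges::reduce(fl, ignore.strand = TRUE)
}

#' Overlap summary of query intervals against feature sets
#'
#' Any-overlap (>= 1 bp, half-open semantics on the 0-based inputs: touching
#' intervals do not overlap) of a query interval set against genes, gene
#' flanks and optionally cCREs. Reports, per feature set, the query-side
#' count/fraction of intervals hitting at least one feature and the
#' feature-side count of features hit; plus a mutually exclusive
#' gene / flank / intergenic partition in which the gene category takes
#' precedence (an interval overlapping both a gene and another gene's flank
#' counts as genic), and the fraction of the genome each feature set
#' covers.
#'
#' @param query `GRanges` or 0-based data.frame of query intervals.
#' @param genes `GRanges` of gene bodies.
#' @param flanks `GRanges` of gene flanks, e.g. from [make_flanks()];
#'   derived automatically (trimmed, 20 kb) when NULL and `genes` given.
#' @param ccres optional `GRanges` of candidate cis-regulatory elements.
#' @param chrom_sizes named vector (needed for genome-coverage fractions
#'   and coordinate validation of data.frame input).
#' @return object of class `overlap_summary`.
#' @export
overlap_summary <- function(query, genes, flanks = NULL, ccres = NULL,
                            chrom_sizes = NULL) {
  if (is.data.frame(query)) query <- intervals_to_granges(query, chrom_sizes)
  .check_chrom_namespace(query, genes, "genes")
  if (is.null(flanks))
    flanks <- make_flanks(genes, chrom_sizes = chrom_sizes)
  nq <- length(query)
  feats <- list(genes = genes, flanks = flanks)
  if (!is.null(ccres)) {
    .check_chrom_namespace(query, ccres, "ccres")
    feats$ccres <- ccres
  }

  per_feature <- lapply(feats, function(f) {
    hit_q <- GenomicRanges::countOverlaps(query, f, ignore.strand = TRUE) > 0
    hit_f <- GenomicRanges::countOverlaps(f, query, ignore.strand = TRUE) > 0
    list(n_query_overlapping = sum(hit_q),
         frac_query_overlapping = if (nq) sum(hit_q) / nq else NA_real_,
         n_features = length(f),
         n_features_hit = sum(hit_f))
  })

  in_gene <- GenomicRanges::countOverlaps(query, genes,
                                          ignore.strand = TRUE) > 0
  in_flank <- GenomicRanges::countOverlaps(query, flanks,
                                           ignore.strand = TRUE) > 0 & !in_gene
  exclusive <- c(gene = sum(in_gene), flank = sum(in_flank),
                 intergenic = nq - sum(in_gene) - sum(in_flank))

  genome_frac <- NULL
  if (!is.null(chrom_sizes)) {
    gsize <- sum(chrom_sizes)
    genome_frac <- vapply(feats, function(f)
      sum(GenomicRanges::width(GenomicRanges::reduce(f,
        ignore.strand = TRUE))) / gsize, numeric(1))
  }

  structure(list(n_query = nq,
                 per_feature = per_feature,
                 exclusive_counts = exclusive,
                 exclusive_fractions = if (nq) exclusive / nq else exclusive * NA,
                 genome_fraction = genome_frac,
                 category = ifelse(in_gene, "gene",
                                   ifelse(in_flank, "flank", "intergenic"))),
            class = "overlap_summary")
}

.check_chrom_namespace <- function(query, features, what) {
  qc <- GenomeInfoDb::seqlevelsInUse(query)
  fc <- GenomeInfoDb::seqlevelsInUse(features)
  if (length(intersect(qc, fc)) == 0L && length(qc) && length(fc))
    stop("no shared chromosome names between query and ", what,
         "; query has ", paste(utils::head(qc, 3), collapse = ","),
         " vs ", paste(utils::head(fc, 3), collapse = ","))
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary: %d query intervals\n", x$n_query))
  for (nm in names(x$per_feature)) {
    pf <- x$per_feature[[nm]]
    cat(sprintf("  %s: %d/%d query intervals overlap (%.1f%%); %d/%d features hit\n",
                nm, pf$n_query_overlapping, x$n_query,
                100 * pf$frac_query_overlapping,
                pf$n_features_hit, pf$n_features))
  }
  f <- x$exclusive_fractions
  cat(sprintf("  exclusive partition: gene %.1f%% | flank %.1f%% | intergenic %.1f%%\n",
              100 * f["gene"], 100 * f["flank"], 100 * f["intergenic"]))
  if (!is.null(x$genome_fraction)) {
    cat("  genome covered: ",
        paste(sprintf("%s %.1f%%", names(x$genome_fraction),
                      100 * x$genome_fraction), collapse = " | "), "\n")
  }
  invisible(x)
}
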