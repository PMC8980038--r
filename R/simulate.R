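#' Configuration for the synthetic ATAC experiment
#'
#' Defines a desk-scale two-genotype ATAC study: a small genome tiled with
#' accessible loci of varying width and strength, 6 control and 7 mutant
#' libraries of paired-end fragments whose lengths follow a
#' subnucleosomal / nucleosomal / poly-nucleosomal mixture, library-depth
#' variation (optionally including under-sequenced libraries that the
#' exclusion filter should catch), and a planted genotype effect: a
#' fraction `f_dep` of loci has mutant accessibility multiplied by
#' `m_dep < 1` and a fraction `f_enh` multiplied by `m_enh > 1`, biased
#' toward depletion to emulate a genome-wide accessibility decrease in the
#' mutant.
#'
#' @param seed master seed; one RNG stream per library is derived from it,
#'   so adding libraries does not perturb existing ones.
#' @param genome named vector of chromosome lengths (default two 5-Mb
#'   chromosomes, i.e. 1e5 bins at 100 bp).
#' @param n_control,n_mutant usable libraries per group (defaults 6 and 7).
#' @param n_low_control,n_low_mutant additional under-sequenced libraries
#'   per group (defaults 0) with depths from `low_depth_range`.
#' @param n_loci number of accessible loci (default 1200, about 10%
#'   of the simulated genome at the default widths).
#' @param locus_width_range loci widths are drawn uniformly from this range
#'   in bp (default 200-1500).
#' @param accessibility_sdlog per-locus baseline accessibility is
#'   log-normal, `rlnorm(meanlog = 0, sdlog = accessibility_sdlog)`
#'   (default 0.5).
#' @param frag_len_mix mixture weights of the subnucleosomal / nucleosomal /
#'   poly-nucleosomal classes (default 0.55 / 0.35 / 0.10).
#' @param depth_range per-library fragment counts are drawn uniformly from
#'   this range (default 2e5-3e5, giving per-bin means over accessible loci
#'   comparable to retained intervals in deep tissue ATAC libraries).
#' @param low_depth_range depths of under-sequenced libraries (default
#'   8e3-1.5e4, roughly a 20-fold drop, mirroring the depth contrast
#'   between discarded and kept tissue libraries).
#' @param f_dep,m_dep fraction of loci depleted in the mutant and their
#'   multiplier (defaults 0.10 and 0.6).
#' @param f_enh,m_enh fraction of loci enhanced in the mutant and their
#'   multiplier (defaults 0.05 and 1.4).
#' @param bg_frac fraction of fragments placed uniformly at random outside
#'   the locus model (default 0.2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       n_control = 6L, n_mutant = 7L,
                       n_low_control = 0L, n_low_mutant = 0L,
                       n_loci = 1200L,
                       locus_width_range = c(200, 1500),
                       accessibility_sdlog = 0.5,
                       frag_len_mix = c(subnucleosomal = 0.55,
                                        nucleosomal = 0.35,
                                        polynucleosomal = 0.10),
                       depth_range = c(2e5, 3e5),
                       low_depth_range = c(8e3, 1.5e4),
                       f_dep = 0.10, m_dep = 0.6,
                       f_enh = 0.05, m_enh = 1.4,
                       bg_frac = 0.2) {
  stopifnot(f_dep >= 0, f_enh >= 0, f_dep + f_enh <= 1,
            m_dep > 0, m_enh > 0, bg_frac >= 0, bg_frac <= 1,
            all(frag_len_mix >= 0), abs(sum(frag_len_mix) - 1) < 1e-8,
            n_control >= 2, n_mutant >= 2)
  if (max(locus_width_range) >= min(genome))
    stop("locus wider than the smallest chromosome")
  structure(as.list(environment()), class = "sim_config")
}

.lib_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + 7919 * i) %% 2147483647)
}

#' Simulate two-genotype ATAC fragment libraries with planted effects
#'
#' Places accessible loci on the simulated genome, then draws fragments per
#' library: with probability `bg_frac` a fragment is uniform background,
#' otherwise it is assigned to a locus with probability proportional to
#' locus accessibility x width x the group multiplier of that locus, its
#' midpoint is the locus centre plus Gaussian jitter (sd = width / 4,
#' clipped to the locus), and its length is drawn from the configured
#' class mixture (uniform within 30-140 / 141-280 / 281-600 bp). Output is
#' deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, per-library BED files, a
#'   chrom.sizes file and a `truth.json` are written there.
#' @return list with `libraries` (named list of fragment data.frames),
#'   `groups` (factor, control/mutant per library), `chrom_sizes`, and
#'   `truth` (list: `loci` data.frame with coordinates, accessibility and
#'   mutant multiplier; `depths`).
#' @export
simulate_fragments <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- names(cfg$genome)

  ## ground-truth loci
  n <- cfg$n_loci
  width <- round(stats::runif(n, cfg$locus_width_range[1],
                              cfg$locus_width_range[2]))
  chrom <- sample(chroms, n, replace = TRUE, prob = cfg$genome)
  start <- floor(stats::runif(n) * (cfg$genome[chrom] - width))
  acc <- stats::rlnorm(n, 0, cfg$accessibility_sdlog)
  mult <- rep(1, n)
  n_dep <- round(cfg$f_dep * n); n_enh <- round(cfg$f_enh * n)
  idx <- sample.int(n, n_dep + n_enh)
  mult[idx[seq_len(n_dep)]] <- cfg$m_dep
  if (n_enh > 0) mult[idx[n_dep + seq_len(n_enh)]] <- cfg$m_enh
  loci <- data.frame(chrom = chrom, start = unname(start),
                     end = unname(start + width), width = width,
                     accessibility = acc, mult_mutant = mult)

  ## library layout: controls first, then mutants; low-depth libraries last
  ## within each group
  groups <- c(rep("control", cfg$n_control + cfg$n_low_control),
              rep("mutant", cfg$n_mutant + cfg$n_low_mutant))
  low <- c(rep(c(FALSE, TRUE), c(cfg$n_control, cfg$n_low_control)),
           rep(c(FALSE, TRUE), c(cfg$n_mutant, cfg$n_low_mutant)))
  lib_names <- sprintf("%s%02d", ifelse(groups == "control", "con", "mut"),
                       unlist(lapply(table(groups)[unique(groups)], seq_len)))
  depths <- integer(length(groups))

  libraries <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    set.seed(.lib_seed(cfg$seed, i))
    rng <- if (low[i]) cfg$low_depth_range else cfg$depth_range
    depth <- round(stats::runif(1, rng[1], rng[2]))
    depths[i] <- depth
    m <- if (groups[i] == "mutant") loci$mult_mutant else rep(1, n)
    libraries[[i]] <- .draw_fragments(depth, loci, m, cfg)
  }
  names(libraries) <- lib_names

  out <- list(libraries = libraries,
              groups = factor(groups, levels = c("control", "mutant")),
              chrom_sizes = cfg$genome,
              truth = list(loci = loci,
                           depths = stats::setNames(depths, lib_names),
                           low_depth = stats::setNames(low, lib_names),
                           config = cfg[setdiff(names(cfg), "genome")]))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in lib_names)
      write_fragments(libraries[[nm]], file.path(dir, paste0(nm, ".bed")))
    write_chrom_sizes(cfg$genome, file.path(dir, "chrom.sizes"))
    jsonlite::write_json(
      list(loci = loci, depths = as.list(out$truth$depths),
           groups = as.character(out$groups)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

.draw_fragments <- function(depth, loci, mult, cfg) {
  n_bg <- stats::rbinom(1, depth, cfg$bg_frac)
  n_fg <- depth - n_bg
  chroms <- names(cfg$genome)

  ## foreground: sample locus, jitter midpoint around the locus centre
  w <- loci$accessibility * loci$width * mult
  li <- sample.int(nrow(loci), n_fg, replace = TRUE, prob = w)
  centre <- (loci$start[li] + loci$end[li]) / 2
  mid <- centre + stats::rnorm(n_fg, 0, loci$width[li] / 4)
  mid <- pmax(loci$start[li] + 1, pmin(loci$end[li] - 1, mid))
  fg_chrom <- loci$chrom[li]

  ## background: uniform over the genome
  bg_chrom <- sample(chroms, n_bg, replace = TRUE, prob = cfg$genome)
  bg_mid <- floor(stats::runif(n_bg) * cfg$genome[bg_chrom])

  chrom <- c(fg_chrom, bg_chrom)
  mid <- c(mid, bg_mid)

  cls <- sample.int(3L, depth, replace = TRUE, prob = cfg$frag_len_mix)
  len <- integer(depth)
  len[cls == 1L] <- sample(30:140, sum(cls == 1L), replace = TRUE)
  len[cls == 2L] <- sample(141:280, sum(cls == 2L), replace = TRUE)
  len[cls == 3L] <- sample(281:600, sum(cls == 3L), replace = TRUE)

  start <- round(mid - len / 2)
  start <- pmax(0, pmin(cfg$genome[chrom] - len, start))
  df <- data.frame(chrom = chrom, start = unname(start),
                   end = unname(start + len), stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, chroms), df$start), ]
  rownames(df) <- NULL
  df
}

#' Simulate spike trains of known burst composition
#'
#' Each train interleaves tonic pacemaker-like firing (a jittered regular
#' train at `tonic_rate`, ISI = (1/rate) x U(0.7, 1.3), so tonic ISIs stay
#' far above the burst-onset threshold at typical dopamine rates) with
#' planted bursts: burst onsets are spread over the epoch with at least
#' `min_gap` seconds between bursts, each burst has a uniform random size
#' in `burst_len` and intra-burst ISIs of `intra_isi` x U(0.8, 1.2). Tonic
#' spikes falling within `clearance` seconds of a burst spike are removed,
#' keeping planted bursts separable. The returned truth records, per
#' train, which spikes were planted as burst spikes and the resulting
#' burst-spike fraction.
#'
#' @param n_neurons number of trains (default 10).
#' @param duration epoch length in seconds (default 300).
#' @param tonic_rate tonic firing rate in Hz (default 2).
#' @param intra_isi nominal intra-burst ISI in seconds (default 0.030).
#' @param burst_len integer range of spikes per burst (default c(4, 8)).
#' @param burst_rate bursts per second (default 0.15).
#' @param min_gap minimum separation between burst onsets in seconds
#'   (default 1.0).
#' @param clearance tonic spikes closer than this to a burst spike are
#'   dropped (default 0.3 s).
#' @param seed master seed; per-neuron streams are derived from it.
#' @return list with `trains` (list of [spike_train()]) and `truth`
#'   (data.frame: `neuron`, `n_spikes`, `n_burst_spikes`,
#'   `burst_fraction`).
#' @export
simulate_spike_trains <- function(n_neurons = 10L, duration = 300,
                                  tonic_rate = 2, intra_isi = 0.030,
                                  burst_len = c(4L, 8L), burst_rate = 0.15,
                                  min_gap = 1.0, clearance = 0.3,
                                  seed = 1L) {
  stopifnot(intra_isi < 0.080, tonic_rate > 0, duration > 0)
  trains <- vector("list", n_neurons)
  truth <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    set.seed(.lib_seed(seed, i))
    ## tonic backbone
    n_max <- ceiling(duration * tonic_rate * 2) + 10
    isis <- stats::runif(n_max, 0.7, 1.3) / tonic_rate
    tonic <- cumsum(isis)
    tonic <- tonic[tonic < duration]

    ## planted bursts on a jittered grid with enforced minimum gap
    n_b <- round(burst_rate * duration)
    burst_spikes <- numeric(0)
    if (n_b > 0) {
      slot <- duration / n_b
      onset <- (seq_len(n_b) - 1) * slot +
        stats::runif(n_b, 0.1 * slot, max(0.1 * slot, slot - min_gap))
      sizes <- sample(burst_len[1]:burst_len[2], n_b, replace = TRUE)
      burst_spikes <- unlist(lapply(seq_len(n_b), function(k) {
        onset[k] + cumsum(c(0, intra_isi *
                              stats::runif(sizes[k] - 1, 0.8, 1.2)))
      }))
      burst_spikes <- burst_spikes[burst_spikes < duration]
    }

    if (length(burst_spikes)) {
      near <- vapply(tonic, function(x)
        min(abs(x - burst_spikes)) < clearance, logical(1))
      tonic <- tonic[!near]
    }
    times <- sort(c(tonic, burst_spikes))
    times <- times[!duplicated(times)]
    planted <- times %in% burst_spikes
    trains[[i]] <- spike_train(times, duration = duration,
                               id = sprintf("neuron%02d", i))
    truth[[i]] <- data.frame(neuron = sprintf("neuron%02d", i),
                             n_spikes = length(times),
                             n_burst_spikes = sum(planted),
                             burst_fraction = sum(planted) / length(times))
  }
  names(trains) <- sprintf("neuron%02d", seq_len(n_neurons))
  list(trains = trains, truth = do.call(rbind, truth))
}

#' Write spike trains as a (neuron_id, time_s) CSV
#'
#' @param trains list of [spike_train()] objects.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(names(trains), function(nm)
    data.frame(neuron_id = nm, time_s = trains[[nm]]$times)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
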