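# Independent oracles used across test files. These deliberately take the
# dumbest correct route (enumeration, all-pairs scans) so they share no code
# with the implementation they check.

# Two-sided Mann-Whitney p by full enumeration of all C(m+n, m) group-label
# assignments (tie-free data): doubled minimal tail of the exact U null.
enumerate_mw_p <- function(x, y) {
  m <- length(y)                       # U is reported for the second sample
  pooled <- c(x, y)
  n_tot <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  obs <- u_of(length(x) + seq_len(m))
  combos <- utils::combn(n_tot, m)
  u_all <- apply(combos, 2, u_of)
  p <- 2 * min(mean(u_all <= obs), mean(u_all >= obs))
  min(1, p)
}

# Burst segmentation by direct rule application: find every spike index i
# (scanning left to right, skipping past closed bursts) whose next ISI is
# below the onset threshold, then extend while ISIs stay within the offset
# threshold. Written as an index-set scan rather than a while-loop over a
# shared cursor to stay structurally different from detect_bursts().
oracle_bursts <- function(times, onset = 0.080, offset = 0.160) {
  n <- length(times)
  isi <- diff(times)
  bursts <- list()
  claimed <- 0L                         # last spike index already in a burst
  for (i in seq_len(max(0L, n - 1L))) {
    if (i <= claimed) next
    if (isi[i] < onset) {
      ext <- i + 1L
      while (ext < n && isi[ext] <= offset) ext <- ext + 1L
      bursts[[length(bursts) + 1L]] <- c(first = i, last = ext)
      claimed <- ext
    }
  }
  if (length(bursts) == 0L)
    return(data.frame(first = integer(0), last = integer(0)))
  as.data.frame(do.call(rbind, bursts))
}

# All-pairs interval overlap on 0-based half-open intervals.
oracle_overlaps <- function(q, f) {
  # q, f: data.frames with chrom, start, end; returns logical per row of q
  vapply(seq_len(nrow(q)), function(i) {
    any(f$chrom == q$chrom[i] & f$start < q$end[i] & q$start[i] < f$end)
  }, logical(1))
}

random_spike_train <- function(n, duration = 60, bursty = FALSE) {
  if (bursty) {
    # clustered times: mixture of tight clusters and sparse background
    centres <- sort(runif(max(1, n %/% 5), 0, duration))
    t <- c(runif(n %/% 2, 0, duration),
           rep(centres, each = 4) + abs(rnorm(4 * length(centres), 0, 0.05)))
  } else {
    t <- runif(n, 0, duration)
  }
  t <- sort(t)
  t <- t[c(TRUE, diff(t) > 1e-6)]
  t[t <= duration]
}
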