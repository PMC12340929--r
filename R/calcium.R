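#' Neuropil subtraction
#'
#' Elementwise subtraction of the surrounding-neuropil signal from a
#' cell's trace.
#'
#' @param trace cell fluorescence vector
#' @param neuropil neuropil fluorescence vector (same length)
#' @return corrected trace
#' @export
neuropil_subtract <- function(trace, neuropil) {
  if (length(trace) != length(neuropil)) stop("length mismatch")
  trace - neuropil
}

#' Zero-phase FIR lowpass filter
#'
#' Designs a linear-phase FIR lowpass with a Kaiser window sized to meet
#' the requested transition band and stopband attenuation, and applies
#' it forward-backward (zero phase). Frequencies are normalized to the
#' Nyquist frequency (so at 10 Hz sampling, a passband of 0.5 means
#' 2.5 Hz). DC gain is unity to within 1 dB.
#'
#' @param trace numeric vector
#' @param passband passband edge, normalized to Nyquist (default 0.5)
#' @param stopband stopband edge, normalized to Nyquist (default 0.65)
#' @param atten_db stopband attenuation in dB (default 25)
#' @return filtered trace (same length)
#' @export
lowpass <- function(trace, passband = 0.5, stopband = 0.65, atten_db = 25) {
  if (!(passband > 0 && passband < stopband && stopband < 1))
    stop("need 0 < passband < stopband < 1")
  dw <- (stopband - passband) * pi
  a <- atten_db
  beta <- if (a > 50) 0.1102 * (a - 8.7)
          else if (a >= 21) 0.5842 * (a - 21)^0.4 + 0.07886 * (a - 21)
          else 0
  n <- ceiling((a - 8) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1     # even order -> odd-length symmetric FIR
  if (length(trace) <= 3 * n) stop("trace shorter than filter order")
  h <- as.numeric(signal::fir1(n, (passband + stopband) / 2,
                               window = signal::kaiser(n + 1, beta)))
  h <- h / sum(h)                 # exact unit DC gain
  as.numeric(signal::filtfilt(h, 1, trace))
}

#' Baseline-normalized fluorescence
#'
#' Computes `(F - F0) / F0` and its standard deviation sigma. The
#' default baseline F0 is the 20th percentile of the full corrected
#' trace; a rolling-percentile baseline is available for drifting
#' recordings.
#'
#' @param trace corrected fluorescence vector
#' @param method "percentile" (default) or "rolling"
#' @param prob percentile used for the baseline (default 0.2)
#' @param window rolling window length in frames (method = "rolling")
#' @return list with `dff`, `sigma`, `f0`
#' @export
dff <- function(trace, method = c("percentile", "rolling"), prob = 0.2,
                window = 600) {
  method <- match.arg(method)
  if (method == "percentile") {
    f0 <- as.numeric(stats::quantile(trace, prob, type = 7))
    if (f0 <= 0) stop("baseline F0 <= 0; trace rejected")
    d <- (trace - f0) / f0
  } else {
    n <- length(trace)
    f0 <- vapply(seq_len(n), function(i) {
      lo <- max(1, i - window %/% 2)
      hi <- min(n, i + window %/% 2)
      as.numeric(stats::quantile(trace[lo:hi], prob, type = 7))
    }, 1)
    if (any(f0 <= 0)) stop("baseline F0 <= 0; trace rejected")
    d <- (trace - f0) / f0
  }
  list(dff = d, sigma = stats::sd(d), f0 = f0)
}

#' Threshold-based calcium event detection
#'
#' Candidate onsets are frames whose one-frame increase of dF/F exceeds
#' `2.5 * sigma`. Each candidate grows into an event spanning from its
#' onset until dF/F first falls below `end_mult * sigma` (default 0.5);
#' overlapping candidates merge. An event is kept only if its peak dF/F
#' reaches `peak_mult * sigma` (default 8) and the sum of dF/F over its
#' frames reaches `area_mult * sigma` frame units (default 200). Kept
#' events set their frames to 1 in the binary raster row. A flat trace
#' (sigma = 0) yields zero events without error.
#'
#' @param d dF/F vector
#' @param sigma SD of the dF/F trace (from [dff()])
#' @param onset_mult,peak_mult,area_mult,end_mult rule multipliers
#' @return list with `events` (data.frame onset/end/peak/area, frames
#'   1-based) and `raster` (binary integer vector)
#' @export
detect_events <- function(d, sigma, onset_mult = 2.5, peak_mult = 8,
                          area_mult = 200, end_mult = 0.5) {
  n <- length(d)
  raster <- integer(n)
  empty <- data.frame(onset = integer(0), end = integer(0),
                      peak = numeric(0), area = numeric(0))
  if (sigma <= 0) return(list(events = empty, raster = raster))
  onsets <- which(c(FALSE, diff(d) > onset_mult * sigma))
  if (length(onsets) == 0) return(list(events = empty, raster = raster))
  below <- d < end_mult * sigma
  ev <- list()
  last_end <- 0L
  for (o in onsets) {
    if (o <= last_end) next          # merged into the previous event
    nxt <- which(below[o:n])[1]
    e <- if (is.na(nxt)) n else o + nxt - 2L   # last frame >= end threshold
    if (e < o) e <- o
    last_end <- e
    ev[[length(ev) + 1]] <- c(o, e)
  }
  ev <- do.call(rbind, ev)
  peak <- vapply(seq_len(nrow(ev)), function(i) max(d[ev[i, 1]:ev[i, 2]]), 1)
  area <- vapply(seq_len(nrow(ev)), function(i) sum(d[ev[i, 1]:ev[i, 2]]), 1)
  keep <- peak >= peak_mult * sigma & area >= area_mult * sigma
  ev <- ev[keep, , drop = FALSE]
  for (i in seq_len(nrow(ev))) raster[ev[i, 1]:ev[i, 2]] <- 1L
  list(events = data.frame(onset = ev[, 1], end = ev[, 2],
                           peak = peak[keep], area = area[keep]),
       raster = raster)
}

#' Fraction of frames active
#' @param raster_row binary vector
#' @return active fraction in `[0, 1]`
#' @export
fraction_active <- function(raster_row) {
  if (length(raster_row) == 0) stop("need >= 1 frame")
  mean(raster_row != 0)
}

#' Depth-binned mean pairwise raster correlation
#'
#' Computes the Pearson correlation between the binary activity rows of
#' every unordered neuron pair in a slice, then averages the pair
#' correlations by the depth bins of the two neurons (default eight
#' 75-um bins from the pial surface). Each pair contributes to cells
#' (b_i, b_j) and (b_j, b_i), so the matrix is symmetric. Neurons deeper
#' than the last bin edge are excluded; pairs in which either row has
#' zero variance are skipped. Both exclusions are counted in the result.
#'
#' @param raster neurons x frames binary matrix
#' @param depth per-neuron depth (um from pial surface)
#' @param bin_width_um bin width (default 75)
#' @param n_bins number of bins (default 8)
#' @return list of class `bin_corr`: `matrix` (n_bins x n_bins mean
#'   correlations, `NaN` where no pair contributed), `pair_count`,
#'   `bin_edges`, `n_excluded_depth`, `n_skipped_zero_var`
#' @export
depth_bin_correlation <- function(raster, depth, bin_width_um = 75,
                                  n_bins = 8) {
  edges <- seq(0, n_bins * bin_width_um, by = bin_width_um)
  in_range <- depth >= 0 & depth < n_bins * bin_width_um
  n_excl <- sum(!in_range)
  if (sum(in_range) < 2) stop("fewer than 2 neurons within the bin range")
  r <- raster[in_range, , drop = FALSE]
  b <- findInterval(depth[in_range], edges, rightmost.closed = FALSE)
  v <- apply(r, 1, stats::sd) > 0
  n_zero_rows <- sum(!v)
  sums <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0L, n_bins, n_bins)
  if (sum(v) >= 2) {
    rc <- stats::cor(t(r[v, , drop = FALSE]))
    bv <- b[v]
    nv <- sum(v)
    for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
      bi <- bv[i]; bj <- bv[j]; cc <- rc[i, j]
      sums[bi, bj] <- sums[bi, bj] + cc
      cnt[bi, bj] <- cnt[bi, bj] + 1L
      if (bi != bj) {
        sums[bj, bi] <- sums[bj, bi] + cc
        cnt[bj, bi] <- cnt[bj, bi] + 1L
      }
    }
  }
  m <- sums / cnt    # 0/0 -> NaN flags empty bin pairs
  structure(list(matrix = m, pair_count = cnt, bin_edges = edges,
                 n_excluded_depth = n_excl,
                 n_skipped_zero_var = n_zero_rows),
            class = "bin_corr")
}

#' Compare slice-level mean correlations between genotypes
#'
#' For each slice's bin-correlation matrix computes (i) the overall mean
#' over all defined bin-pair entries and (ii) the superficial mean over
#' matrix rows whose bin upper edge is at most `superficial_cut_um`
#' (i.e. neuron 1 of the pair is superficial). Each metric is compared
#' between genotypes with a Student (pooled-variance) two-sample t-test
#' across slices; identical groups give t = 0, p = 1 by convention.
#'
#' @param mats list of `bin_corr` objects (one per slice)
#' @param genotypes per-slice genotype labels (two levels, >= 2 each)
#' @param superficial_cut_um depth cut for the superficial rows
#'   (default 300)
#' @return list: `per_slice` data.frame (slice mean, superficial mean,
#'   genotype) and `tests` data.frame (metric, group means, sem, t, df, p)
#' @export
slice_group_compare <- function(mats, genotypes, superficial_cut_um = 300) {
  gl <- unique(genotypes)
  if (length(gl) != 2 || any(table(genotypes) < 2))
    stop("need two genotypes with >= 2 slices each")
  overall <- vapply(mats, function(m)
    mean(m$matrix[is.finite(m$matrix)]), 1)
  superf <- vapply(mats, function(m) {
    rows <- which(m$bin_edges[-1] <= superficial_cut_um)
    v <- m$matrix[rows, , drop = FALSE]
    mean(v[is.finite(v)])
  }, 1)
  per_slice <- data.frame(slice = seq_along(mats), genotype = genotypes,
                          mean_corr = overall, superficial_corr = superf)
  one_test <- function(vals) {
    x <- vals[genotypes == gl[1]]; y <- vals[genotypes == gl[2]]
    if (isTRUE(all.equal(stats::var(c(x - mean(x), y - mean(y))), 0)) &&
        isTRUE(all.equal(mean(x), mean(y))))
      return(c(mean(x), mean(y), stats::sd(x) / sqrt(length(x)),
               stats::sd(y) / sqrt(length(y)), 0,
               length(x) + length(y) - 2, 1))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    c(mean(x), mean(y), stats::sd(x) / sqrt(length(x)),
      stats::sd(y) / sqrt(length(y)), unname(tt$statistic),
      unname(tt$parameter), tt$p.value)
  }
  res <- rbind(one_test(overall), one_test(superf))
  tests <- data.frame(metric = c("overall", "superficial"),
                      mean_1 = res[, 1], mean_2 = res[, 2],
                      sem_1 = res[, 3], sem_2 = res[, 4],
                      t = res[, 5], df = res[, 6], p = res[, 7])
  attr(tests, "groups") <- gl
  list(per_slice = per_slice, tests = tests)
}

#' Dendritic spine turnover metrics
#'
#' Set arithmetic on spine identities across two imaging sessions:
#' percentage eliminated = spines present in session 1 but not 2 over
#' the session-1 count; percentage formed = new spines in session 2 over
#' the session-1 count; density = spines per 10 um of dendrite on the
#' first imaging day.
#'
#' @param session1 character vector of spine ids at the first session
#' @param session2 character vector at the second session
#' @param segment_length_um total dendritic segment length (um, > 0)
#' @return list: `density_per_10um`, `pct_formed`, `pct_eliminated`
#' @export
spine_turnover <- function(session1, session2, segment_length_um) {
  if (length(session1) == 0) stop("empty first session")
  if (segment_length_um <= 0) stop("segment length must be > 0")
  n1 <- length(unique(session1))
  list(density_per_10um = 10 * n1 / segment_length_um,
       pct_formed = 100 * length(setdiff(session2, session1)) / n1,
       pct_eliminated = 100 * length(setdiff(session1, session2)) / n1)
}
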