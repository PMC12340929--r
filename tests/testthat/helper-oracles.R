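# Independent textbook oracles used across tests.

# Welch two-sample t statistic, df and two-sided p, straight from the
# formulas (kept independent of the package's vectorized implementation).
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pooled-variance (Student) two-sample t.
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Tiny nucleus-level fixture with explicit cell types, for aggregation.
toy_nuclei <- function() {
  counts <- matrix(c(2, 1,  3, 0,  5, 2,  1, 1,  0, 4,  2, 2),
                   nrow = 2,
                   dimnames = list(c("gA", "gB"), sprintf("n%d", 1:6)))
  meta <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    genotype = rep(c("WT", "HET"), each = 3),
    sex = "M", batch = "b1",
    cell_type_1 = c("T1", "T1", "T2", "T1", "T2", "T2"),
    cell_type_2 = c("T1", "T1", "T2", "T1", "T2", "T2"),
    cell_type_3 = "ClassA",
    stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# Synthetic dF/F pulse: a one-frame rise to `peak` (in sigma units),
# exponential decay with per-frame factor `phi`, on a zero baseline.
make_pulse <- function(n_frames, onset, peak_sigma, phi, sigma = 0.1) {
  d <- numeric(n_frames)
  k <- 0
  repeat {
    v <- peak_sigma * sigma * phi^k
    if (v < 1e-6 || onset + k > n_frames) break
    d[onset + k] <- v
    k <- k + 1
  }
  d
}

# per-second rasterization oracle for hourly hypnogram occupancy
raster_oracle <- function(h) {
  sec <- character(86400)
  for (i in seq_len(nrow(h))) {
    idx <- (h$start_s[i] + 1):(h$start_s[i] + h$duration_s[i])
    sec[idx] <- h$state[i]
  }
  out <- matrix(0, 24, 3, dimnames = list(NULL, c("Wake", "NREM", "REM")))
  for (hr in 0:23) {
    chunk <- sec[(hr * 3600 + 1):((hr + 1) * 3600)]
    for (st in colnames(out)) out[hr + 1, st] <- sum(chunk == st)
  }
  out
}
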