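test_that("neuropil subtraction is elementwise", {
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(neuropil_subtract(x, numeric(100)), x)
  expect_equal(neuropil_subtract(x, x), numeric(100))
  expect_equal(neuropil_subtract(x, y), x - y)
  expect_error(neuropil_subtract(x, y[1:50]), "length")
})

test_that("lowpass filter meets its band specification", {
  n <- 2000
  # DC preservation within 1% (away from the filtfilt edge transients)
  expect_equal(lowpass(rep(3, n))[100:1900], rep(3, 1801),
               tolerance = 0.01)
  # stopband: sinusoid at 0.9 x Nyquist attenuated by >= 25 dB
  s_stop <- sin(2 * pi * 0.45 * seq_len(n))      # 0.9 x Nyquist
  out <- lowpass(s_stop)
  expect_lt(max(abs(out[500:1500])), 10^(-25 / 20))
  # passband: sinusoid at 0.3 x Nyquist within 1 dB
  s_pass <- sin(2 * pi * 0.15 * seq_len(n))
  outp <- lowpass(s_pass)
  ratio <- max(abs(outp[500:1500])) / max(abs(s_pass))
  expect_gt(ratio, 10^(-1 / 20))
  expect_lt(ratio, 10^(1 / 20))
  expect_error(lowpass(rnorm(10)), "shorter")
  expect_error(lowpass(rnorm(100), passband = 0.7, stopband = 0.6),
               "passband")
})

test_that("dff uses the stated percentile baseline", {
  tr <- rep(10, 50)
  d <- dff(tr)
  expect_equal(d$dff, rep(0, 50))
  expect_equal(d$sigma, 0)
  d2 <- dff(rep(20, 50) + 0)   # trace = 2 * F0 would need a varying trace
  # explicit: F0 = 20th percentile; constant trace at 2*c has F0 = 2*c
  tr3 <- c(rep(5, 80), rep(10, 20))   # 20th pct = 5
  d3 <- dff(tr3)
  expect_equal(d3$f0, 5)
  expect_equal(max(d3$dff), 1)
  # percentile equals the sort-based order statistic oracle (type 7)
  set.seed(7)
  tr4 <- abs(rnorm(101, 10, 2))
  s <- sort(tr4)
  h <- (101 - 1) * 0.2 + 1
  oracle <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(dff(tr4)$f0, oracle)
  expect_error(dff(rep(-1, 50)), "F0")
})

test_that("event detector applies the onset, peak and area rules", {
  sigma <- 0.1
  # flat trace: no events
  flat <- detect_events(numeric(500), sigma)
  expect_equal(nrow(flat$events), 0)
  expect_equal(sum(flat$raster), 0)
  # sigma = 0: zero events, no error
  expect_equal(nrow(detect_events(numeric(500), 0)$events), 0)

  # pulse with 10 sigma one-frame rise, slow decay: peak 10 sigma >= 8,
  # area ~238 sigma-frames >= 200 -> exactly one event
  p1 <- make_pulse(800, 100, 10, 0.96, sigma)
  r1 <- detect_events(p1, sigma)
  expect_equal(nrow(r1$events), 1)
  expect_equal(r1$events$onset, 100)
  expect_gte(r1$events$peak, 8 * sigma)
  expect_gte(r1$events$area, 200 * sigma)

  # peak 5 sigma but large area: fails the 8 sigma criterion -> 0 events
  p2 <- make_pulse(3000, 100, 5, 0.995, sigma)
  expect_gte(sum(p2), 300 * sigma)
  r2 <- detect_events(p2, sigma)
  expect_equal(nrow(r2$events), 0)

  # peak 10 sigma but tiny area: fails the 200 sigma area criterion
  p3 <- make_pulse(500, 100, 10, 0.5, sigma)
  expect_lt(sum(p3), 200 * sigma)
  expect_equal(nrow(detect_events(p3, sigma)$events), 0)

  # raster frames span the kept event
  expect_equal(which(r1$raster == 1)[1], 100)
  expect_true(all(diff(which(r1$raster == 1)) == 1))
})

test_that("raster is invariant to positive affine rescaling of the trace", {
  set.seed(8)
  tr <- 100 + 50 * make_pulse(1000, 200, 12, 0.94, 0.1) + rnorm(1000, 0, 0.5)
  d1 <- dff(tr)
  r1 <- detect_events(d1$dff, d1$sigma)
  tr2 <- 3.7 * tr
  d2 <- dff(tr2)
  r2 <- detect_events(d2$dff, d2$sigma)
  expect_equal(r1$raster, r2$raster)
})

test_that("fraction active is the popcount fraction", {
  expect_equal(fraction_active(c(1, rep(0, 9))), 0.1)
  expect_equal(fraction_active(numeric(10)), 0)
  set.seed(9)
  r <- rbinom(1000, 1, 0.3)
  expect_equal(fraction_active(r), sum(r) / 1000)
  expect_error(fraction_active(integer(0)), "frame")
})

test_that("depth-binned correlation averages pairs by bin and stays symmetric", {
  # two identical nonconstant rows in one bin: diagonal entry 1
  r <- rbind(c(1, 0, 1, 0, 1, 0), c(1, 0, 1, 0, 1, 0))
  bc <- depth_bin_correlation(r, depth = c(10, 20))
  expect_equal(bc$matrix[1, 1], 1)
  expect_equal(bc$pair_count[1, 1], 1L)   # within-bin pair counted once

  # independent rows over many frames: entries near 0
  set.seed(10)
  n <- 20; fr <- 36000
  r2 <- matrix(rbinom(n * fr, 1, 0.05), n, fr)
  dep <- runif(n, 0, 600)
  bc2 <- depth_bin_correlation(r2, dep)
  vals <- bc2$matrix[is.finite(bc2$matrix)]
  expect_lt(max(abs(vals)), 0.01 + 3 / sqrt(fr))

  # symmetry and neuron-order invariance
  expect_equal(bc2$matrix, t(bc2$matrix))
  ord <- sample(n)
  bc3 <- depth_bin_correlation(r2[ord, ], dep[ord])
  expect_equal(bc2$matrix, bc3$matrix)
  expect_equal(bc2$pair_count, bc3$pair_count)

  # deep neurons excluded and counted; zero-variance rows skipped
  r4 <- rbind(r2[1:3, ], 0)
  d4 <- c(50, 60, 700, 80)
  bc4 <- depth_bin_correlation(r4, d4)
  expect_equal(bc4$n_excluded_depth, 1)
  expect_equal(bc4$n_skipped_zero_var, 1)
  expect_error(depth_bin_correlation(r2[1:2, ], c(700, 800)), "within")
})

test_that("latent structure appears only in the loaded depth block", {
  ts <- sim_calcium_traces(
    n_neurons = 32, n_frames = 36000, event_rate = 0.3,
    latents = list(list(rate = 2,
                        loading = function(d) ifelse(d < 150, 1, 0))),
    seed = 111)
  bc <- depth_bin_correlation(ts$truth$raster, ts$depth)
  rho <- expected_pair_correlation(0.03, 0.03, 0.2, 1, 1)
  # loaded 2x2 block near the closed form; unloaded far block near zero
  for (i in 1:2) for (j in 1:2) {
    if (bc$pair_count[i, j] > 0)
      expect_lt(abs(bc$matrix[i, j] - rho),
                3 * (1 - rho^2) / sqrt(36000) + 0.01)
  }
  off <- bc$matrix[5:8, 5:8]
  expect_lt(max(abs(off[is.finite(off)])), 0.01 + 3 / sqrt(36000))
})

test_that("slice group comparison matches the pooled-t oracle", {
  set.seed(12)
  mats <- lapply(1:6, function(i) {
    m <- matrix(rnorm(64, 0.005, 0.001), 8, 8)
    m <- (m + t(m)) / 2
    structure(list(matrix = m, pair_count = matrix(1L, 8, 8),
                   bin_edges = seq(0, 600, 75)), class = "bin_corr")
  })
  gts <- rep(c("WT", "HET"), each = 3)
  res <- slice_group_compare(mats, gts)
  per <- res$per_slice$mean_corr
  o <- pooled_t_oracle(per[1:3], per[4:6])
  row <- res$tests[res$tests$metric == "overall", ]
  expect_equal(row$t, o$t, tolerance = 1e-12)
  expect_equal(row$p, o$p, tolerance = 1e-12)

  # identical matrices in both groups: t = 0, p = 1 by convention
  same <- rep(mats[1], 4)
  res2 <- slice_group_compare(same, c("WT", "WT", "HET", "HET"))
  expect_equal(res2$tests$t, c(0, 0))
  expect_equal(res2$tests$p, c(1, 1))
  expect_error(slice_group_compare(mats[1:3], c("WT", "WT", "HET")),
               ">= 2 slices")
})

test_that("a planted slice-level group difference is detected with power", {
  hits <- 0
  for (i in 1:200) {
    set.seed(600 + i)
    wt <- rnorm(8, 0.005, 0.001)
    het <- rnorm(10, 0.002, 0.001)
    p <- t.test(wt, het, var.equal = TRUE)$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("spine turnover is exact set arithmetic", {
  s1 <- sprintf("sp%d", 1:100)
  expect_equal(spine_turnover(s1, s1, 100)$pct_formed, 0)
  expect_equal(spine_turnover(s1, s1, 100)$pct_eliminated, 0)
  out <- spine_turnover(s1, c(s1[1:90], sprintf("new%d", 1:15)), 50)
  expect_equal(out$pct_eliminated, 10)
  expect_equal(out$pct_formed, 15)
  expect_equal(spine_turnover(sprintf("s%d", 1:20), character(0), 25),
               list(density_per_10um = 8, pct_formed = 0,
                    pct_eliminated = 100))
  expect_error(spine_turnover(character(0), s1, 10), "empty")
})
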