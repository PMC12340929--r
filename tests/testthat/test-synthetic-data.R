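test_that("generators are bit-identical under a fixed seed", {
  a <- sim_pseudobulk_counts(n_genes = 50, seed = 7)
  b <- sim_pseudobulk_counts(n_genes = 50, seed = 7)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  t1 <- sim_tissue(n_somata = 100, seed = 3)
  t2 <- sim_tissue(n_somata = 100, seed = 3)
  expect_identical(t1$centers, t2$centers)

  h1 <- sim_hypnogram(seed = 9)
  h2 <- sim_hypnogram(seed = 9)
  expect_identical(h1, h2)

  c1 <- sim_calcium_traces(n_neurons = 5, n_frames = 200, seed = 4)
  c2 <- sim_calcium_traces(n_neurons = 5, n_frames = 200, seed = 4)
  expect_identical(c1$traces, c2$traces)
})

test_that("child seeds keep generator streams independent", {
  a <- sim_pseudobulk_counts(n_genes = 50, seed = 7)
  sim_tissue(n_somata = 10, seed = 7)      # interleave another generator
  b <- sim_pseudobulk_counts(n_genes = 50, seed = 7)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_true(child_seed(7, "counts") != child_seed(7, "tissue"))
})

test_that("pseudobulk count generator validates inputs and plants effects", {
  expect_error(sim_pseudobulk_counts(n_genes = 5), "n_genes")
  expect_error(sim_pseudobulk_counts(n_per_genotype = 1), "samples")
  expect_error(sim_pseudobulk_counts(dispersion = -1), "dispersion")

  null_sim <- sim_pseudobulk_counts(n_genes = 100, fraction_de = 0, seed = 1)
  expect_length(null_sim$truth$de_genes, 0)

  sim <- sim_pseudobulk_counts(n_genes = 200, fraction_de = 0.2, seed = 2)
  expect_length(sim$truth$de_genes, 40)
  v <- sim$counts$counts
  expect_true(all(v >= 0) && all(v == floor(v)))
})

test_that("planted logFC is recovered in the Poisson limit", {
  # dispersion -> 0, large libraries, logFC 1: the HET/WT ratio of group
  # mean CPM over all DE genes concentrates near 2 (up) and 0.5 (down)
  sim <- sim_pseudobulk_counts(n_genes = 500, n_per_genotype = 5,
                               dispersion = 0, libsize_range = c(2e6, 2e6),
                               batch_sd = 0, fraction_de = 0.2,
                               logfc_de = 1, seed = 42)
  cmat <- sim$counts$counts   # equal library-size targets: raw means suffice
  het <- sim$counts$meta$genotype == "HET"
  ratio <- rowMeans(cmat[, het]) / rowMeans(cmat[, !het])
  de <- match(sim$truth$de_genes, rownames(cmat))
  up <- de[sim$truth$de_logfc > 0]
  dn <- de[sim$truth$de_logfc < 0]
  expect_equal(median(ratio[up]), 2, tolerance = 0.1)
  expect_equal(median(ratio[dn]), 0.5, tolerance = 0.1)
  expect_equal(median(ratio[-de]), 1, tolerance = 0.1)
})

test_that("marker generator matches its Poisson design", {
  # dropout 0: every male nucleus has >= 1 count of a given Y gene with
  # probability 1 - exp(-5); with 4 independent Y genes a zero Y score is
  # essentially impossible
  nm <- sim_nuclei_markers(n_nuclei_per_pool = 400, y_mean = 5,
                           dropout = 0, seed = 5)
  males <- nm$truth$sex == "M"
  ysum <- colSums(nm$counts$counts[1:4, ])
  expect_true(all(ysum[males] >= 1))
  expect_true(all(ysum[!males] == 0))
  frac_pos <- mean(nm$counts$counts[1, males] >= 1)
  expect_equal(frac_pos, 1 - exp(-5), tolerance = 0.02)

  empty <- sim_nuclei_markers(n_nuclei_per_pool = 0, seed = 1)
  expect_equal(ncol(empty$counts$counts), 0)

  expect_error(sim_nuclei_markers(dropout = 1.5), "dropout")
  expect_error(sim_nuclei_markers(pools = list(p1 = c(M = "WT", F = "WT"))),
               "opposite")
})

test_that("calcium generator truth follows its closed-form design", {
  expect_error(sim_calcium_traces(n_frames = 50), "frames")
  expect_error(sim_calcium_traces(event_rate = -1), "negative")

  # no latent: raster rows are independent; mean |pairwise corr| is small
  ts <- sim_calcium_traces(n_neurons = 20, n_frames = 12000,
                           event_rate = 1, latents = list(), seed = 8)
  rc <- cor(t(ts$truth$raster))
  off <- rc[upper.tri(rc)]
  expect_lt(abs(mean(off)), 3 / sqrt(12000))

  # noise 0: the trace is exactly the truth raster convolved with the
  # exponential kernel (checked by direct convolution)
  ts1 <- sim_calcium_traces(n_neurons = 1, n_frames = 300, event_rate = 0.5,
                            noise_sd = 0, neuropil_sd = 0, baseline_f = 100,
                            amplitude = 1, tau = 0.6, seed = 2)
  r <- ts1$truth$raster[1, ]
  kern <- exp(-(0:299) / (0.6 * 10))
  conv <- vapply(seq_len(300), function(t)
    sum(r[seq_len(t)] * rev(kern[seq_len(t)])), 1)
  expect_equal(as.numeric(ts1$traces[1, ]), 100 * (1 + conv),
               tolerance = 1e-8)

  # shared latent, loading 1: empirical raster correlation matches the
  # closed form within 3 SE
  ts2 <- sim_calcium_traces(n_neurons = 2, n_frames = 36000,
                            event_rate = 0.3,
                            latents = list(list(rate = 2, loading = 1)),
                            seed = 77)
  rho <- expected_pair_correlation(0.03, 0.03, 0.2, 1, 1)
  emp <- cor(ts2$truth$raster[1, ], ts2$truth$raster[2, ])
  se <- (1 - rho^2) / sqrt(36000)
  expect_lt(abs(emp - rho), 3 * se)
})

test_that("hypnogram generator covers 24 h and honours its Markov design", {
  h <- sim_hypnogram(epoch_s = 10, seed = 1)
  expect_equal(nrow(h), 8640)
  expect_equal(sum(h$duration_s), 86400)

  absorb <- diag(3); dimnames(absorb) <- list(NULL, NULL)
  ha <- sim_hypnogram(P_light = absorb, P_dark = absorb, init = "Wake",
                      seed = 2)
  expect_true(all(ha$state == "Wake"))

  bad <- matrix(1, 3, 3)
  expect_error(sim_hypnogram(P_light = bad), "sum to 1")
  expect_error(sim_hypnogram(epoch_s = 7), "divide")

  # long-run NREM occupancy tracks the stationary distribution of the
  # light matrix within 3 SE over 50 replicates (light phase only)
  P <- default_sleep_matrix("light")
  pi_st <- stationary_distribution(P)
  occ <- vapply(1:50, function(i) {
    h <- sim_hypnogram(P_light = P, P_dark = P, seed = 100 + i)
    mean(h$state == "NREM")
  }, 1)
  se <- sd(occ) / sqrt(50)
  expect_lt(abs(mean(occ) - pi_st[2]), 3 * se)
})

test_that("tissue generator places somata uniformly with recorded truth", {
  expect_error(sim_tissue(n_somata = 0), "count")
  expect_error(sim_tissue(radius_mean = -2), "positive support")

  t1 <- sim_tissue(n_somata = 1, seed = 1)
  expect_true(all(t1$centers >= 0) &&
                all(t1$centers <= rep(c(1000, 1000, 300), each = 1)))

  # empirical density in a random sub-box is within Poisson error of N/V
  tis <- sim_tissue(n_somata = 20000, box = c(1000, 1000, 300), seed = 6)
  inside <- tis$centers[, 1] < 500 & tis$centers[, 2] < 500 &
    tis$centers[, 3] < 150
  expected <- 20000 / 8
  expect_lt(abs(sum(inside) - expected), 3 * sqrt(expected))

  sph <- sim_tissue(n_somata = 500, region = "sphere", sphere_radius = 400,
                    seed = 2)
  expect_true(all(rowSums(sph$centers^2) <= 400^2))
  expect_equal(sph$true_volume_um3, 4 / 3 * pi * 400^3)
})
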