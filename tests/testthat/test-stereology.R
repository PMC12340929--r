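test_that("section sampling tiles the region with a uniform random start", {
  tis <- sim_tissue(n_somata = 10, box = c(100, 100, 900), seed = 18)
  # box of height 9d: 9 sections for any start (plane count H/d)
  s <- sample_sections(tis, d = 100, t = 50, seed = 1)
  n_in <- sum(s$z >= 0 & s$z < 900)
  expect_equal(n_in, 9)
  expect_true(s$start >= 0 && s$start < 100)

  s2 <- sample_sections(tis, d = 100, t = 50, seed = 1)
  expect_identical(s$z, s2$z)   # same seed, same start

  expect_error(sample_sections(tis, d = 10, t = 50), "d >= t")
  thin <- sim_tissue(n_somata = 5, box = c(100, 100, 40), seed = 1)
  expect_warning(sample_sections(thin, d = 100, t = 40, seed = 1),
                 "thinner")

  # start offsets uniform over [0, d) across many seeds
  starts <- vapply(1:2000, function(i)
    sample_sections(tis, d = 100, t = 50, seed = i)$start, 1)
  ks <- suppressWarnings(ks.test(starts / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cavalieri estimate is exact for a box and unbiased for a sphere", {
  tis <- sim_tissue(n_somata = 10, box = c(200, 300, 900), seed = 19)
  for (seed in 1:20) {
    s <- sample_sections(tis, d = 100, t = 50, seed = seed)
    expect_equal(cavalieri_volume(s), 200 * 300 * 900)
  }

  # single section of area A -> d * A
  one <- list(z = 0, d = 480, area_um2 = 1234)
  expect_equal(cavalieri_volume(one), 480 * 1234)
  expect_error(cavalieri_volume(list(z = 1, d = 10)), "neither")

  # sphere r = 500, d = 100: mean over 500 random starts within 1%
  sph <- sim_tissue(n_somata = 10, region = "sphere", sphere_radius = 500,
                    seed = 20)
  est <- vapply(1:500, function(i)
    cavalieri_volume(sample_sections(sph, d = 100, t = 50, seed = i)), 1)
  truth <- 4 / 3 * pi * 500^3
  expect_lt(abs(mean(est) / truth - 1), 0.01)

  # point-counting mode approximates the area mode
  sp <- sample_sections(sph, d = 100, t = 50, mode = "points",
                        grid_um = 20, seed = 3)
  sa <- sample_sections(sph, d = 100, t = 50, mode = "area", seed = 3)
  expect_equal(cavalieri_volume(sp), cavalieri_volume(sa),
               tolerance = 0.02)
})

test_that("fractionator spec reproduces the standard sampling fractions", {
  # frame 18x18x10 um with 2 um guards, grid 480x480, 60 um sections
  # every 480 um: ssf 1/8, asf 324/230400, tsf 10/t_bar
  sp <- fractionator_spec(frame_um = c(18, 18), h = 10, guard = 2,
                          grid_um = c(480, 480), d = 480, t = 60)
  expect_equal(sp$ssf, 1 / 8)
  expect_equal(sp$asf, 324 / 230400)
  expect_equal(sp$tsf, 10 / 60)
  expect_error(fractionator_spec(h = 60, guard = 2, t = 60), "guard")
  expect_error(fractionator_spec(frame_um = c(500, 500)), "larger")
})

test_that("optical fractionator is a census at unit sampling fractions", {
  tis <- sim_tissue(n_somata = 500, box = c(200, 200, 100),
                    radius_mean = 3, seed = 21)
  spec <- fractionator_spec(frame_um = c(200, 200), h = 50, guard = 0,
                            grid_um = c(200, 200), d = 50, t = 50)
  of <- optical_fractionator_count(tis, spec, seed = 1)
  expect_equal(of$estimate, 500)
  expect_equal(of$Q, 500)
})

test_that("optical fractionator is unbiased with low CE on uniform tissue", {
  tis <- sim_tissue(n_somata = 10000, box = c(1000, 1000, 300), seed = 22)
  spec <- fractionator_spec(frame_um = c(50, 50), h = 10, guard = 2,
                            grid_um = c(100, 100), d = 40, t = 20)
  est <- vapply(1:100, function(i)
    optical_fractionator_count(tis, spec, seed = i)$estimate, 1)
  expect_lt(abs(mean(est) / 10000 - 1), 0.03)
  expect_lt(sd(est) / mean(est), 0.15)    # empirical CE
})

test_that("estimates scale correctly with tissue dimensions", {
  tis <- sim_tissue(n_somata = 3000, box = c(500, 500, 200), seed = 23)
  big <- tis
  big$centers <- tis$centers * 2
  big$box <- tis$box * 2
  big$true_volume_um3 <- tis$true_volume_um3 * 8

  est_v <- mean(vapply(1:50, function(i)
    cavalieri_volume(sample_sections(tis, d = 50, t = 25, seed = i)), 1))
  est_v2 <- mean(vapply(1:50, function(i)
    cavalieri_volume(sample_sections(big, d = 100, t = 50, seed = i)), 1))
  expect_equal(est_v2 / est_v, 8, tolerance = 0.02)

  spec <- fractionator_spec(frame_um = c(50, 50), h = 10, guard = 2,
                            grid_um = c(100, 100), d = 40, t = 20)
  est_n <- mean(vapply(1:80, function(i)
    optical_fractionator_count(tis, spec, seed = i)$estimate, 1))
  est_n2 <- mean(vapply(1:80, function(i)
    optical_fractionator_count(big, spec, seed = i)$estimate, 1))
  expect_equal(est_n / 3000, 1, tolerance = 0.05)
  expect_equal(est_n2 / 3000, 1, tolerance = 0.05)
})

test_that("grid translation by one period leaves the count unchanged", {
  tis <- sim_tissue(n_somata = 2000, box = c(400, 400, 100), seed = 24)
  spec <- fractionator_spec(frame_um = c(40, 40), h = 10, guard = 2,
                            grid_um = c(80, 80), d = 40, t = 20)
  of1 <- optical_fractionator_count(tis, spec, seed = 7)
  shifted <- tis
  shifted$centers[, 1] <- tis$centers[, 1] + spec$grid_um[1]
  of2 <- optical_fractionator_count(shifted, spec, seed = 7)
  expect_equal(of1$Q, of2$Q)
})

test_that("nucleator is exact on spheres and matches numeric integration", {
  expect_equal(nucleator_volume(5, n_rays = 1, seed = 1), 4 * pi / 3 * 125)
  expect_equal(nucleator_volume(5, n_rays = 50, seed = 2), 4 * pi / 3 * 125)
  expect_error(nucleator_volume(5, n_rays = 0), "n_rays")

  # prolate ellipsoid a = 2, b = c = 1 about its centre:
  # l(u) = (ux^2/a^2 + uy^2 + uz^2)^(-1/2); E[l^3] by numeric
  # integration over the sphere vs the Monte-Carlo estimator
  a <- 2
  ell <- function(u) 1 / sqrt(u[1, ]^2 / a^2 + u[2, ]^2 + u[3, ]^2)
  # numeric integral over polar angle (azimuthal symmetry about x):
  # direction x-component = cos(theta), measure sin(theta)/2 dtheta
  f <- function(th) (1 / (cos(th)^2 / a^2 + sin(th)^2))^(3 / 2) *
    sin(th) / 2
  e_l3 <- integrate(f, 0, pi, rel.tol = 1e-10)$value
  truth <- 4 * pi / 3 * e_l3
  est <- nucleator_volume(ell, n_rays = 10000, seed = 3)
  expect_lt(abs(est / truth - 1), 0.01)
  # sanity: the analytic ellipsoid volume equals (4 pi / 3) a b c = E-form
  expect_equal(truth, 4 * pi / 3 * a, tolerance = 1e-6)
})
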