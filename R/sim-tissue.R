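#' Simulate a 3D tissue block as a marked point process
#'
#' Soma centers are placed uniformly inside a bounded region (an
#' axis-aligned box or a sphere) with radii drawn from a stated
#' distribution; the true count, true region volume and all marks are
#' recorded so that stereological estimators can be validated against
#' known truth.
#'
#' @param n_somata true number of somata (>= 1)
#' @param region "box" or "sphere"
#' @param box box dimensions `c(lx, ly, lz)` in um (region = "box")
#' @param sphere_radius sphere radius in um (region = "sphere"; the
#'   sphere is centred at the origin)
#' @param radius_mean,radius_sd soma radius distribution (um); radii are
#'   drawn from a gamma with this mean and SD, so support is positive
#' @param seed integer seed
#' @return list of class `tissue`: `centers` (n x 3), `radii`,
#'   `region`, `box`/`sphere_radius`, `true_count`, `true_volume_um3`,
#'   `true_soma_volumes_um3`
#' @export
sim_tissue <- function(n_somata = 10000, region = c("box", "sphere"),
                       box = c(1000, 1000, 300), sphere_radius = 500,
                       radius_mean = 6, radius_sd = 1, seed = 1) {
  region <- match.arg(region)
  if (n_somata < 1) stop("true count must be >= 1")
  if (region == "box" && any(box <= 0)) stop("box dimensions must be > 0")
  if (radius_mean <= 0 || radius_sd < 0)
    stop("radius distribution must have positive support")
  with_seed(child_seed(seed, "tissue"), {
    if (region == "box") {
      centers <- cbind(runif(n_somata, 0, box[1]),
                       runif(n_somata, 0, box[2]),
                       runif(n_somata, 0, box[3]))
      vol <- prod(box)
    } else {
      centers <- matrix(NA_real_, n_somata, 3)
      filled <- 0
      while (filled < n_somata) {
        m <- 2 * (n_somata - filled)
        cand <- matrix(runif(3 * m, -sphere_radius, sphere_radius), ncol = 3)
        ok <- rowSums(cand^2) <= sphere_radius^2
        take <- min(sum(ok), n_somata - filled)
        if (take > 0)
          centers[filled + seq_len(take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
        filled <- filled + take
      }
      vol <- 4 / 3 * pi * sphere_radius^3
    }
    radii <- if (radius_sd == 0) rep(radius_mean, n_somata) else
      rgamma(n_somata, shape = (radius_mean / radius_sd)^2,
             rate = radius_mean / radius_sd^2)
    colnames(centers) <- c("x", "y", "z")
    structure(list(centers = centers, radii = radii, region = region,
                   box = if (region == "box") box else NULL,
                   sphere_radius = if (region == "sphere") sphere_radius else NULL,
                   true_count = n_somata, true_volume_um3 = vol,
                   true_soma_volumes_um3 = 4 / 3 * pi * radii^3),
              class = "tissue")
  })
}

# z-range of the region (somata can poke above it; sections for counting
# must extend past the top by the largest radius)
tissue_z_range <- function(tissue) {
  if (tissue$region == "box") c(0, tissue$box[3])
  else c(-tissue$sphere_radius, tissue$sphere_radius)
}

# analytic cross-section area of the region at height z
tissue_section_area <- function(tissue, z) {
  if (tissue$region == "box") {
    ifelse(z >= 0 & z < tissue$box[3], tissue$box[1] * tissue$box[2], 0)
  } else {
    r2 <- tissue$sphere_radius^2 - z^2
    ifelse(r2 > 0, pi * r2, 0)
  }
}
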