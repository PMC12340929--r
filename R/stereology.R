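#' Systematic uniform random sectioning of a tissue block
#'
#' Places section planes a fixed interval apart with a uniform random
#' start in `[0, d)` below the bottom of the region, records the nominal
#' slab `[z, z + t)` for each section, and measures the region's profile
#' area at each plane either analytically or by point counting on a
#' square grid of spacing `grid_um` (area per point = `grid_um^2`).
#'
#' @param tissue a [sim_tissue()] object
#' @param d section sampling interval (um); `d >= t`
#' @param t nominal section thickness (um, > 0)
#' @param mode "area" (analytic profile areas) or "points" (grid counts)
#' @param grid_um grid spacing for point counting
#' @param seed integer seed (drives the random start, and the grid
#'   offset in point mode)
#' @return list of class `section_series`: `z` (plane positions),
#'   `t`, `d`, `start`, `area_um2` (area mode) and/or `points`,
#'   `area_per_point_um2` (point mode)
#' @export
sample_sections <- function(tissue, d = 100, t = 60,
                            mode = c("area", "points"), grid_um = 50,
                            seed = 1) {
  mode <- match.arg(mode)
  if (!(d >= t && t > 0)) stop("need d >= t > 0")
  zr <- tissue_z_range(tissue)
  with_seed(child_seed(seed, "sections"), {
    start <- runif(1, 0, d)
    z <- seq(zr[1] - d + start, zr[2], by = d)
    z <- z[z + t > zr[1] & z < zr[2]]
    if (length(z) <= 1 && zr[2] - zr[1] < d)
      warning("region thinner than the sampling interval; single section")
    out <- list(z = z, t = t, d = d, start = start)
    if (mode == "area") {
      out$area_um2 <- tissue_section_area(tissue, z)
    } else {
      ox <- runif(1, 0, grid_um); oy <- runif(1, 0, grid_um)
      out$points <- vapply(z, function(zz) {
        if (tissue$region == "box") {
          if (zz < 0 || zz >= tissue$box[3]) return(0L)
          gx <- seq(ox, tissue$box[1], by = grid_um)
          gy <- seq(oy, tissue$box[2], by = grid_um)
          length(gx) * length(gy)
        } else {
          r2 <- tissue$sphere_radius^2 - zz^2
          if (r2 <= 0) return(0L)
          gx <- seq(ox - tissue$sphere_radius - grid_um, tissue$sphere_radius,
                    by = grid_um)
          gy <- seq(oy - tissue$sphere_radius - grid_um, tissue$sphere_radius,
                    by = grid_um)
          sum(outer(gx^2, gy^2, "+") <= r2)
        }
      }, 1)
      out$area_per_point_um2 <- grid_um^2
    }
    structure(out, class = "section_series")
  })
}

#' Cavalieri volume estimator
#'
#' `V = d * sum(A_i)` from systematically spaced profile areas with a
#' uniform random start (area mode), or
#' `V = d * (a/p) * sum(P_i)` from grid point counts (point mode).
#'
#' @param series a [sample_sections()] result
#' @return volume estimate in um^3
#' @export
cavalieri_volume <- function(series) {
  if (!is.null(series$area_um2)) {
    if (length(series$area_um2) == 0) stop("no section areas")
    series$d * sum(series$area_um2)
  } else if (!is.null(series$points)) {
    series$d * series$area_per_point_um2 * sum(series$points)
  } else stop("section series carries neither areas nor point counts")
}

#' Optical fractionator sampling specification
#'
#' @param frame_um counting-frame side lengths `c(x, y)` (um)
#' @param h dissector height (um)
#' @param guard guard zone (um); `h + 2 * guard <= t`
#' @param grid_um scan-grid spacing `c(X, Y)` (um); frame must fit the cell
#' @param d section sampling interval (um)
#' @param t section thickness (um); `t <= d`
#' @return list of class `fractionator_spec` with derived sampling
#'   fractions `ssf = t/d`, `asf = frame area / grid cell area`,
#'   `tsf = h / t` (nominal; the estimator uses measured thickness)
#' @export
fractionator_spec <- function(frame_um = c(18, 18), h = 10, guard = 2,
                              grid_um = c(480, 480), d = 480, t = 60) {
  if (h + 2 * guard > t) stop("dissector plus guard zones exceeds thickness")
  if (any(frame_um > grid_um)) stop("frame larger than grid cell")
  ssf <- t / d
  asf <- prod(frame_um) / prod(grid_um)
  tsf <- h / t
  if (any(c(ssf, asf, tsf) <= 0) || any(c(ssf, asf, tsf) > 1))
    stop("sampling fractions must be in (0, 1]")
  structure(list(frame_um = frame_um, h = h, guard = guard,
                 grid_um = grid_um, d = d, t = t,
                 ssf = ssf, asf = asf, tsf = tsf),
            class = "fractionator_spec")
}

#' Optical fractionator number estimator
#'
#' Samples sections of thickness `t` every `d` um with a uniform random
#' start, overlays a scan grid with a uniform random offset (optionally
#' rotated by a uniform random angle), and counts a soma when its unique
#' counting point -- the topmost z of the soma sphere, standing in for
#' the nucleolus -- falls inside the optical dissector
#' `[z + guard, z + guard + h)` of a sampled section and inside a
#' counting frame respecting the exclusion edges (left and lower edges
#' forbidden). The estimate is
#' `N = Q * (1/ssf) * (1/asf) * (1/tsf)` with `tsf = h / t_bar`,
#' `t_bar` the mean measured section thickness over counting sites
#' (site-weighted; the synthetic sections have no shrinkage so measured
#' equals nominal thickness).
#'
#' With `ssf = asf = tsf = 1` the procedure is a census and returns the
#' true count exactly.
#'
#' @param tissue a [sim_tissue()] object
#' @param spec a [fractionator_spec()]
#' @param rotate rotate the grid by a uniform random angle (default
#'   FALSE; unbiasedness for uniform tissue does not require it)
#' @param seed integer seed
#' @return list: `estimate`, `Q` (raw count), `t_bar`, fractions used
#' @export
optical_fractionator_count <- function(tissue, spec, rotate = FALSE,
                                       seed = 1) {
  zr <- tissue_z_range(tissue)
  cp_z <- tissue$centers[, 3] + tissue$radii   # unique counting point
  with_seed(child_seed(seed, "fractionator"), {
    u <- runif(1, 0, spec$d)
    ox <- runif(1, 0, spec$grid_um[1])
    oy <- runif(1, 0, spec$grid_um[2])
    xy <- tissue$centers[, 1:2, drop = FALSE]
    if (rotate) {
      th <- runif(1, 0, 2 * pi)
      R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      xy <- xy %*% R
    }
    # z criterion: counting point inside some dissector
    zrel <- (cp_z - (zr[1] - spec$d + u) - spec$guard) %% spec$d
    in_z <- zrel < spec$h
    # xy criterion: inside a frame anchored at grid nodes; left/lower
    # edges excluded (open at 0)
    rx <- (xy[, 1] - ox) %% spec$grid_um[1]
    ry <- (xy[, 2] - oy) %% spec$grid_um[2]
    in_xy <- rx > 0 & rx <= spec$frame_um[1] & ry > 0 & ry <= spec$frame_um[2]
    Q <- sum(in_z & in_xy)
    t_bar <- spec$t                    # measured thickness at sites
    tsf <- spec$h / t_bar
    list(estimate = Q / spec$ssf / spec$asf / tsf, Q = Q, t_bar = t_bar,
         ssf = spec$ssf, asf = spec$asf, tsf = tsf)
  })
}

#' Nucleator local volume estimator
#'
#' Estimates a cell's volume from the lengths of isotropic random rays
#' cast from a reference point (the nucleolus) to the cell boundary:
#' `v = (4 pi / 3) * mean(l^3)`. For a sphere of radius r about the
#' reference point every ray has length r, so the estimate is exactly
#' `(4 pi / 3) r^3`.
#'
#' @param boundary either a single radius (spherical soma) or a function
#'   `f(u)` mapping a 3-row matrix of unit direction vectors (columns)
#'   to ray lengths; must describe a star-shaped boundary about the
#'   reference point
#' @param n_rays number of isotropic rays (>= 1)
#' @param seed integer seed
#' @return volume estimate in um^3
#' @export
nucleator_volume <- function(boundary, n_rays = 4, seed = 1) {
  if (n_rays < 1) stop("n_rays must be >= 1")
  with_seed(child_seed(seed, "nucleator"), {
    v <- matrix(rnorm(3 * n_rays), 3)
    u <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    l <- if (is.function(boundary)) boundary(u)
         else rep(boundary, n_rays)
    if (any(l < 0)) stop("negative ray length")
    4 * pi / 3 * mean(l^3)
  })
}
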