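#' Simulate dF/F-like fluorescence traces with depth structure
#'
#' Each neuron sits at a known cortical depth and fires a per-frame
#' Bernoulli event train: private events at `event_rate` Hz plus shared
#' latent-factor events (each latent fires at `latent_rate` Hz and is
#' passed to a neuron with probability given by its depth-bin loading).
#' The binary onset raster (the union of private and accepted latent
#' events) is the recorded ground truth; the fluorescence trace is the
#' raster convolved with a single-exponential kernel (decay `tau` s,
#' amplitude `amplitude` dF/F units) plus white noise and a shared
#' neuropil component.
#'
#' Because the truth raster is an i.i.d. Bernoulli frame process, the
#' expected Pearson correlation between two neurons' raster rows has the
#' closed form implemented in [expected_pair_correlation()].
#'
#' @param n_neurons neurons in the slice
#' @param depth_range depth interval (um from pial surface); depths drawn
#'   uniformly so all bins are populated
#' @param frame_rate Hz
#' @param n_frames frames (>= 100)
#' @param event_rate private event rate (Hz, >= 0)
#' @param latents list of latent factors, each a list with `rate` (Hz)
#'   and `loading`, a function of depth (um) returning an acceptance
#'   probability in `[0,1]` (or a single number used for all depths)
#' @param amplitude transient peak amplitude (dF/F units)
#' @param tau kernel decay time constant (s)
#' @param noise_sd white-noise SD added to the trace
#' @param neuropil_sd SD of the shared slow neuropil component
#' @param baseline_f baseline fluorescence F0 (arbitrary units); the raw
#'   trace is `baseline_f * (1 + dff)` so percentile baselining recovers
#'   approximately `baseline_f`
#' @param slice,animal,genotype labels attached to the slice
#' @param seed integer seed
#' @return list of class `trace_set`: `traces` (neurons x frames raw
#'   fluorescence), `neuropil` (same shape), `depth`, `frame_rate`,
#'   `slice`, `animal`, `genotype`, and `truth` (binary `raster` of
#'   event onsets, per-neuron private rate, latent acceptance
#'   probabilities per neuron)
#' @export
sim_calcium_traces <- function(n_neurons = 40, depth_range = c(0, 600),
                               frame_rate = 10, n_frames = 6000,
                               event_rate = 0.3, latents = list(),
                               amplitude = 1, tau = 0.6,
                               noise_sd = 0.05, neuropil_sd = 0.02,
                               baseline_f = 100,
                               slice = "slice1", animal = "a1",
                               genotype = "WT", seed = 1) {
  if (n_frames < 100) stop("need >= 100 frames")
  if (event_rate < 0) stop("negative event rate")
  for (l in latents) if (l$rate < 0) stop("negative latent rate")
  with_seed(child_seed(seed, paste0("calcium_", slice)), {
    depth <- runif(n_neurons, depth_range[1], depth_range[2])
    p_own <- event_rate / frame_rate
    raster <- matrix(rbinom(n_neurons * n_frames, 1, p_own),
                     n_neurons, n_frames)
    accept <- matrix(0, n_neurons, max(1, length(latents)))
    if (length(latents)) {
      for (k in seq_along(latents)) {
        l <- latents[[k]]
        pl <- l$rate / frame_rate
        lv <- rbinom(n_frames, 1, pl)
        pa <- if (is.function(l$loading)) l$loading(depth)
              else rep(l$loading, n_neurons)
        accept[, k] <- pa
        take <- matrix(rbinom(n_neurons * n_frames, 1, pa),
                       n_neurons, n_frames)   # pa recycles down columns
        raster <- pmax(raster, take * matrix(lv, n_neurons, n_frames,
                                             byrow = TRUE))
      }
    }
    dff <- t(apply(raster, 1, function(r) {
      stats::filter(r, exp(-1 / (tau * frame_rate)), method = "recursive") *
        amplitude
    }))
    neuro <- matrix(rep(stats::filter(rnorm(n_frames, 0, neuropil_sd),
                                      rep(1 / 5, 5), sides = 1),
                        each = n_neurons), n_neurons, n_frames)
    neuro[is.na(neuro)] <- 0
    traces <- baseline_f * (1 + dff +
      matrix(rnorm(n_neurons * n_frames, 0, noise_sd),
             n_neurons, n_frames)) + baseline_f * neuro
    neuropil <- baseline_f * neuro
    structure(list(traces = traces, neuropil = neuropil, depth = depth,
                   frame_rate = frame_rate, slice = slice, animal = animal,
                   genotype = genotype,
                   truth = list(raster = raster, p_own = p_own,
                                accept = accept,
                                latent_rates = vapply(latents,
                                  function(l) l$rate, 1))),
              class = "trace_set")
  })
}

#' Expected raster correlation for a shared-latent pair
#'
#' Closed-form Pearson correlation between two neurons' per-frame binary
#' onset indicators under the generator model of
#' [sim_calcium_traces()]: each frame, neuron i fires privately with
#' probability `a_i`, and a shared latent fires with probability `p_l`
#' and is accepted with probability `l_i`. Writing
#' `q_i = 1 - (1 - a_i)(1 - p_l l_i)` for the marginal firing
#' probability, the covariance of the indicators is
#' `(1 - a1)(1 - a2) p_l (1 - p_l) l1 l2`, and the correlation is the
#' covariance over `sqrt(q1 (1-q1) q2 (1-q2))`.
#'
#' @param a1,a2 private per-frame firing probabilities
#' @param p_l latent per-frame firing probability
#' @param l1,l2 latent acceptance probabilities
#' @return expected Pearson correlation of the two binary rows
#' @export
expected_pair_correlation <- function(a1, a2, p_l, l1, l2) {
  q1 <- 1 - (1 - a1) * (1 - p_l * l1)
  q2 <- 1 - (1 - a2) * (1 - p_l * l2)
  cov <- (1 - a1) * (1 - a2) * p_l * (1 - p_l) * l1 * l2
  cov / sqrt(q1 * (1 - q1) * q2 * (1 - q2))
}
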