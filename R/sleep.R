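SLEEP_STATES <- c("Wake", "NREM", "REM")

#' Simulate a 24 h hypnogram
#'
#' First-order Markov chain over {Wake, NREM, REM} at fixed epoch
#' length, switching from the light-phase to the dark-phase transition
#' matrix at ZT12 (43200 s after lights-on). The hypnogram tiles
#' exactly [0, 86400) s with contiguous epochs.
#'
#' @param epoch_s epoch length in seconds; must divide 3600
#' @param P_light,P_dark 3x3 row-stochastic transition matrices with
#'   rows/columns ordered Wake, NREM, REM
#' @param init initial state
#' @param subject,genotype labels carried in the output
#' @param seed integer seed
#' @return data.frame of class `hypnogram`: subject, genotype, start_s,
#'   duration_s, state
#' @export
sim_hypnogram <- function(epoch_s = 10,
                          P_light = default_sleep_matrix("light"),
                          P_dark = default_sleep_matrix("dark"),
                          init = "Wake", subject = "m1", genotype = "WT",
                          seed = 1) {
  if (3600 %% epoch_s != 0) stop("epoch length must divide 3600 s")
  for (P in list(P_light, P_dark)) {
    if (!all(dim(P) == c(3, 3)) || any(P < 0) ||
        any(abs(rowSums(P) - 1) > 1e-9))
      stop("transition matrix rows must be non-negative and sum to 1")
  }
  n <- 86400L / epoch_s
  n_light <- 43200L / epoch_s
  with_seed(child_seed(seed, paste0("hypno_", subject)), {
    s <- integer(n)
    s[1] <- match(init, SLEEP_STATES)
    u <- runif(n)
    for (i in 2:n) {
      P <- if (i <= n_light) P_light else P_dark
      s[i] <- findInterval(u[i], cumsum(P[s[i - 1], ]),
                           rightmost.closed = TRUE) + 1L
      if (s[i] > 3L) s[i] <- 3L
    }
    out <- data.frame(subject = subject, genotype = genotype,
                      start_s = (seq_len(n) - 1) * epoch_s,
                      duration_s = epoch_s,
                      state = SLEEP_STATES[s],
                      stringsAsFactors = FALSE)
    class(out) <- c("hypnogram", "data.frame")
    out
  })
}

#' Default light/dark sleep transition matrices
#'
#' Epoch-to-epoch (10 s) transition probabilities chosen to mimic a
#' nocturnal rodent: sleep-dominated light phase, wake-dominated dark
#' phase, REM entered only from NREM.
#'
#' @param phase "light" or "dark"
#' @return 3x3 row-stochastic matrix (Wake, NREM, REM)
#' @export
default_sleep_matrix <- function(phase = c("light", "dark")) {
  phase <- match.arg(phase)
  m <- if (phase == "light") {
    rbind(c(0.88, 0.12, 0.00),
          c(0.05, 0.92, 0.03),
          c(0.08, 0.04, 0.88))
  } else {
    rbind(c(0.965, 0.035, 0.000),
          c(0.100, 0.880, 0.020),
          c(0.100, 0.040, 0.860))
  }
  dimnames(m) <- list(SLEEP_STATES, SLEEP_STATES)
  m
}

#' Stationary distribution of a transition matrix
#' @param P row-stochastic matrix
#' @return stationary probability vector
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

validate_hypnogram <- function(h) {
  h <- h[order(h$start_s), , drop = FALSE]
  if (nrow(h) == 0) stop("empty hypnogram")
  if (!all(h$state %in% SLEEP_STATES))
    stop("states must be in {Wake, NREM, REM}")
  ends <- h$start_s + h$duration_s
  if (h$start_s[1] != 0 || utils::tail(ends, 1) != 86400 ||
      (nrow(h) > 1 && any(abs(h$start_s[-1] - ends[-nrow(h)]) > 1e-9)))
    stop("epochs must tile [0, 86400) with no gaps or overlaps")
  h
}

#' Hourly state occupancy in seconds
#'
#' Apportions each epoch's duration to clock hours by exact overlap.
#' Row sums are exactly 3600 s.
#'
#' @param h a hypnogram data.frame (subject-level): columns `start_s`,
#'   `duration_s`, `state`; epochs must tile [0, 86400)
#' @return 24 x 3 matrix of seconds (columns Wake, NREM, REM)
#' @export
hourly_state_seconds <- function(h) {
  h <- validate_hypnogram(h)
  out <- matrix(0, 24, 3, dimnames = list(NULL, SLEEP_STATES))
  s <- match(h$state, SLEEP_STATES)
  for (i in seq_len(nrow(h))) {
    a <- h$start_s[i]; b <- a + h$duration_s[i]
    h0 <- floor(a / 3600); h1 <- ceiling(b / 3600) - 1
    for (hr in h0:h1) {
      ov <- min(b, (hr + 1) * 3600) - max(a, hr * 3600)
      if (ov > 0) out[hr + 1, s[i]] <- out[hr + 1, s[i]] + ov
    }
  }
  out
}

#' Light/dark phase totals and hourly variability
#'
#' Per state and phase (light = ZT0-12 = hours 0-11, dark = ZT12-24),
#' the total seconds and the sample standard deviation (n-1) of the 12
#' hourly values.
#'
#' @param hourly 24 x 3 matrix from [hourly_state_seconds()]
#' @return data.frame: state, phase, total_s, sd_s
#' @export
phase_summary <- function(hourly) {
  if (!all(dim(hourly) == c(24, 3))) stop("need a 24 x 3 hourly table")
  rows <- list()
  for (st in SLEEP_STATES) {
    for (ph in c("light", "dark")) {
      idx <- if (ph == "light") 1:12 else 13:24
      v <- hourly[idx, st]
      rows[[length(rows) + 1]] <- data.frame(
        state = st, phase = ph, total_s = sum(v), sd_s = stats::sd(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Welch comparisons of sleep metrics between genotypes
#'
#' For each (state, phase) cell and each metric (phase total seconds or
#' SD of hourly seconds), an unpaired Welch-corrected two-sample t-test
#' between genotypes, with group means and SEM. If both groups have zero
#' variance with n = 2, the Welch df is undefined and the pooled df
#' n1 + n2 - 2 is used with a warning.
#'
#' @param summaries data.frame stacking [phase_summary()] rows per
#'   subject, with added `subject` and `genotype` columns
#' @param metrics metrics to compare (subset of `c("total_s", "sd_s")`)
#' @return data.frame: state, phase, metric, per-group mean and sem,
#'   t, df, p
#' @export
sleep_genotype_compare <- function(summaries,
                                   metrics = c("total_s", "sd_s")) {
  gl <- unique(summaries$genotype)
  if (length(gl) != 2) stop("need exactly two genotypes")
  rows <- list()
  for (st in unique(summaries$state)) for (ph in c("light", "dark")) {
    sub <- summaries[summaries$state == st & summaries$phase == ph, ]
    for (m in metrics) {
      x <- sub[[m]][sub$genotype == gl[1]]
      y <- sub[[m]][sub$genotype == gl[2]]
      if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 subjects per genotype")
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        warning("zero variance in both groups; pooled df fallback")
        t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
        df <- length(x) + length(y) - 2
        p <- if (t == 0) 1 else 0
      } else {
        tt <- stats::t.test(x, y)            # Welch correction
        t <- unname(tt$statistic); df <- unname(tt$parameter)
        p <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        state = st, phase = ph, metric = m,
        mean_1 = mean(x), sem_1 = stats::sd(x) / sqrt(length(x)),
        mean_2 = mean(y), sem_2 = stats::sd(y) / sqrt(length(y)),
        t = t, df = df, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- gl
  out
}
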