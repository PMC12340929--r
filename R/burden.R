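#' Minimum-expression threshold from nominally significant genes
#'
#' The expression floor used by the burden statistic: the minimum
#' `baseMean` among genes with raw p < `p_cut`. If no gene is nominally
#' significant the floor is 0 and every tested gene counts as expressed.
#'
#' @param de a DE table with columns `pval` and `baseMean`
#' @param p_cut raw p cutoff defining the threshold-setting gene set
#' @return numeric baseMean cutoff (0 if no gene has p < `p_cut`)
#' @export
min_expression_threshold <- function(de, p_cut = 0.05) {
  if (!all(c("pval", "baseMean") %in% names(de)))
    stop("DE table must have 'pval' and 'baseMean' columns")
  if (nrow(de) == 0) stop("empty DE table")
  hit <- de$pval < p_cut
  if (!any(hit)) return(0)
  min(de$baseMean[hit])
}

#' Differential-expression burden of a cell population
#'
#' Burden = 100 * (significant genes above the expression floor) /
#' (genes above the expression floor). The default significance rule is
#' adjusted p < 0.05; the rule used to set the floor itself is raw
#' p < 0.05 (see [min_expression_threshold()]).
#'
#' @param de a DE table (columns `pval`, `padj`, `baseMean`)
#' @param threshold baseMean expression floor (>= 0)
#' @param sig a function of the DE table returning a logical significance
#'   vector; default `padj < 0.05`
#' @return burden percentage in `[0, 100]`
#' @export
de_burden <- function(de, threshold = min_expression_threshold(de),
                      sig = function(d) d$padj < 0.05) {
  if (threshold < 0) stop("threshold must be >= 0")
  expressed <- de$baseMean >= threshold
  n_exp <- sum(expressed)
  if (n_exp == 0) stop("no expressed genes above the threshold")
  100 * sum(sig(de) & expressed) / n_exp
}

# All distinct re-assignments of genotype labels, optionally within batch.
# Returns a list of integer vectors (indices that become HET), or NULL if
# the number of assignments exceeds `cap`.
enumerate_assignments <- function(genotype, batch = NULL, cap = Inf) {
  n <- length(genotype)
  if (is.null(batch) || length(unique(batch)) < 2) {
    k <- sum(genotype == "HET")
    n_assign <- choose(n, k)
    if (n_assign > cap) return(NULL)
    asplit(utils::combn(n, k), 2)
  } else {
    per <- lapply(split(seq_len(n), batch), function(idx) {
      k <- sum(genotype[idx] == "HET")
      asplit(utils::combn(idx, k), 2)
    })
    n_assign <- prod(vapply(per, length, 1))
    if (n_assign > cap) return(NULL)
    grids <- do.call(expand.grid, lapply(per, seq_along))
    lapply(seq_len(nrow(grids)), function(i)
      unlist(lapply(seq_along(per), function(b) per[[b]][[grids[i, b]]]),
             use.names = FALSE))
  }
}

#' Permutation test for the DE burden statistic
#'
#' Computes the observed burden of a pseudobulk contrast and its
#' significance by permuting sample-level genotype labels (within batch
#' when a batch factor is present and `within_batch` is TRUE). Each
#' permutation reruns the full DE engine and, by default, recomputes the
#' expression floor (set `freeze_threshold = TRUE` to reuse the observed
#' floor). When the number of distinct label assignments is at most
#' `n_iter` they are enumerated exhaustively and the p-value is exact
#' (share of assignments, observed included, with burden >= observed);
#' otherwise `n_iter` Monte-Carlo permutations are drawn and the add-one
#' estimator `(1 + #{perm >= obs}) / (1 + n_iter)` is used.
#'
#' The statistic is direction-free, so the test is two-sided by
#' construction and invariant to swapping the WT/HET labels.
#'
#' @param pb a sample-level [count_matrix()] with `genotype` metadata
#' @param n_iter Monte-Carlo iterations (>= 100); also the enumeration cap
#' @param seed integer seed for the Monte-Carlo branch
#' @param sig significance rule for the numerator (default padj < 0.05)
#' @param use_batch include batch as DE covariate if present
#' @param within_batch permute genotype labels within batch levels
#' @param freeze_threshold reuse the observed expression floor in
#'   permutations instead of recomputing it
#' @param min_cpm,min_frac expression filter passed to the DE engine
#' @return list of class `burden_result`: `burden`, `threshold`,
#'   `n_expressed`, `n_de`, `perm_p`, `n_perm`, `exact`, `seed`,
#'   `warnings`
#' @export
burden_permutation_test <- function(pb, n_iter = 1000, seed = 1,
                                    sig = function(d) d$padj < 0.05,
                                    use_batch = TRUE, within_batch = TRUE,
                                    freeze_threshold = FALSE,
                                    min_cpm = 1, min_frac = 0.5) {
  if (n_iter < 100) stop("n_iter must be >= 100")
  gt <- pb$meta$genotype
  if (length(unique(gt)) != 2) stop("need exactly two genotype levels")
  cm <- cpm(pb$counts)
  logexpr <- log2(cm + 1)
  bm <- rowMeans(cm)
  batch <- if (use_batch && "batch" %in% names(pb$meta)) pb$meta$batch else NULL
  pbatch <- if (within_batch) batch else NULL

  burden_for <- function(labels) {
    res <- de_engine(logexpr, bm, labels, batch, min_cpm, min_frac)
    d <- data.frame(pval = res$pval, padj = res$padj, baseMean = res$base_mean)
    thr <- if (freeze_threshold) obs_thr else min_expression_threshold(d)
    c(de_burden(d, thr, sig), thr,
      sum(d$baseMean >= thr), sum(sig(d) & d$baseMean >= thr))
  }
  obs_res <- de_engine(logexpr, bm, gt, batch, min_cpm, min_frac)
  obs_d <- data.frame(pval = obs_res$pval, padj = obs_res$padj,
                      baseMean = obs_res$base_mean)
  obs_thr <- min_expression_threshold(obs_d)
  obs <- de_burden(obs_d, obs_thr, sig)

  warns <- character(0)
  assigns <- enumerate_assignments(gt, pbatch, cap = n_iter)
  n <- length(gt)
  if (!is.null(assigns)) {
    if (length(assigns) < 20)
      warns <- c(warns, sprintf(
        "only %d distinct label assignments; p-value resolution is coarse",
        length(assigns)))
    perm <- vapply(assigns, function(idx) {
      lab <- rep("WT", n); lab[idx] <- "HET"
      burden_for(lab)[1]
    }, 1)
    perm_p <- mean(perm >= obs)   # observed assignment is in the set
    n_perm <- length(assigns)
    exact <- TRUE
  } else {
    perm <- with_seed(child_seed(seed, "burden_perm"), {
      vapply(seq_len(n_iter), function(i) {
        lab <- if (is.null(pbatch)) sample(gt) else {
          l <- gt
          for (idx in split(seq_len(n), pbatch)) l[idx] <- sample(gt[idx])
          l
        }
        burden_for(lab)[1]
      }, 1)
    })
    perm_p <- (1 + sum(perm >= obs)) / (1 + n_iter)
    n_perm <- n_iter
    exact <- FALSE
  }
  structure(list(burden = obs, threshold = obs_thr,
                 n_expressed = sum(obs_d$baseMean >= obs_thr),
                 n_de = sum(sig(obs_d) & obs_d$baseMean >= obs_thr),
                 perm_p = perm_p, n_perm = n_perm, exact = exact,
                 seed = seed, warnings = warns),
            class = "burden_result")
}

#' @exportS3Method base::print
print.burden_result <- function(x, ...) {
  cat(sprintf("DE burden: %.3f%% (%d of %d expressed genes)\n",
              x$burden, x$n_de, x$n_expressed))
  cat(sprintf("baseMean threshold: %.4g\n", x$threshold))
  cat(sprintf("permutation p = %.4g (%d %s permutations)\n", x$perm_p,
              x$n_perm, if (x$exact) "exhaustive" else "Monte-Carlo"))
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}
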