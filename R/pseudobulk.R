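#' Aggregate nucleus-level counts to sample-level pseudobulk
#'
#' Restricts a nucleus-level count matrix to one cell population at a
#' chosen level of the cell-type hierarchy and sums counts over each
#' sample's nuclei. Samples with zero nuclei of the population are
#' omitted. Sample-level metadata (genotype, sex, batch) is carried over
#' from the first nucleus of each sample.
#'
#' @param x a [count_matrix()] of nuclei with `cell_type_1..3` metadata
#' @param level hierarchy level (1, 2 or 3)
#' @param population cell-type label at that level
#' @return a [count_matrix()] whose units are samples
#' @export
aggregate_pseudobulk <- function(x, level = 2, population) {
  col <- paste0("cell_type_", level)
  if (!col %in% names(x$meta)) stop("metadata lacks column ", col)
  if (!population %in% x$meta[[col]])
    stop("unknown population '", population, "' at level ", level)
  keep <- x$meta[[col]] == population
  sub <- x$counts[, keep, drop = FALSE]
  samp <- x$meta$sample[keep]
  f <- factor(samp, levels = unique(samp))
  agg <- sub %*% stats::model.matrix(~ 0 + f)
  agg <- as.matrix(agg)
  colnames(agg) <- levels(f)
  meta_cols <- intersect(c("sample", "genotype", "sex", "batch", "pool"),
                         names(x$meta))
  meta <- x$meta[keep, meta_cols, drop = FALSE]
  meta <- meta[!duplicated(meta$sample), , drop = FALSE]
  meta <- meta[match(levels(f), meta$sample), , drop = FALSE]
  count_matrix(round(agg), meta)
}

#' Counts per million
#' @param counts genes x units matrix
#' @return CPM matrix (columns scaled to 1e6)
#' @export
cpm <- function(counts) {
  ls <- colSums(counts)
  if (any(ls == 0)) stop("zero library size")
  sweep(as.matrix(counts), 2, ls, "/") * 1e6
}

# Vectorized Welch two-sample t over matrix rows.
# Returns t, df and two-sided p; rows with zero variance in both groups
# get p = 1 (t = 0 when the means agree, Inf-protected otherwise).
welch_rows <- function(mat, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    t[degen] <- 0
    p[degen] <- 1
    df[degen] <- n1 + n2 - 2
  }
  list(t = t, df = df, p = p, m1 = m1, m2 = m2)
}

# Core DE engine on precomputed log-expression; used by de_test and by
# the burden permutation loop (which re-labels genotype many times).
de_engine <- function(logexpr, base_mean, genotype, batch = NULL,
                      min_cpm = 1, min_frac = 0.5) {
  het <- which(genotype == "HET")
  wt <- which(genotype == "WT")
  if (length(het) < 2 || length(wt) < 2)
    stop("need >= 2 samples per genotype")
  # expression filter: CPM >= min_cpm in >= min_frac of either group
  # (logexpr = log2(CPM + 1), so the cutoff is log2(min_cpm + 1))
  thr <- log2(min_cpm + 1)
  ok1 <- rowSums(logexpr[, het, drop = FALSE] >= thr) >=
    ceiling(min_frac * length(het))
  ok2 <- rowSums(logexpr[, wt, drop = FALSE] >= thr) >=
    ceiling(min_frac * length(wt))
  keep <- which((ok1 | ok2) & rowSums(logexpr) > 0)
  y <- logexpr[keep, , drop = FALSE]
  if (!is.null(batch) && length(unique(batch)) > 1) {
    # batch present: per-gene least squares on genotype + batch; the
    # genotype-coefficient t with n - p df is the exact test under this
    # model (a Welch t on batch-subtracted values loses the batch df and
    # is anticonservative), and logFC is the adjusted HET - WT effect
    gt <- factor(genotype, levels = c("WT", "HET"))
    X <- stats::model.matrix(~ gt + factor(batch))
    XtXinv <- solve(crossprod(X))
    beta <- t(XtXinv %*% crossprod(X, t(y)))
    rss <- rowSums((y - beta %*% t(X))^2)
    dfree <- ncol(y) - ncol(X)
    se <- sqrt(rss / dfree * XtXinv[2, 2])
    tstat <- beta[, 2] / se
    p <- 2 * stats::pt(-abs(tstat), dfree)
    degen <- se == 0
    if (any(degen)) { tstat[degen] <- 0; p[degen] <- 1 }
    w <- list(t = tstat, df = rep(dfree, nrow(y)), p = p)
    lfc <- beta[, 2]
  } else {
    w <- welch_rows(y, het, wt)
    lfc <- w$m1 - w$m2   # HET minus WT group means of log2 values
  }
  list(keep = keep, logfc = lfc, t = w$t, df = w$df, pval = w$p,
       padj = stats::p.adjust(w$p, "BH"), base_mean = base_mean[keep])
}

#' Per-gene differential expression on pseudobulk counts
#'
#' The internal DE engine: counts are normalized to counts-per-million
#' and log-transformed as `log2(CPM + 1)`; genes failing the expression
#' filter (CPM >= `min_cpm` in at least half the samples of either
#' genotype group) are dropped; if a batch factor is supplied its
#' per-gene least-squares fit is removed before testing (group means are
#' preserved); each remaining gene gets a Welch two-sample t between
#' genotypes, `logFC` = difference of HET and WT group means of the log2
#' values, Benjamini-Hochberg adjustment over the tested genes, and
#' `baseMean` = mean CPM over all samples. A gene with zero variance in
#' both groups gets p = 1 with its logFC as computed.
#'
#' Any externally produced table with columns `gene`, `logFC`, `pval`,
#' `padj`, `baseMean` can be substituted downstream ([de_burden()],
#' [dem_test()]), so a shrinkage-based engine can be plugged in.
#'
#' @param pb a [count_matrix()] whose units are samples with `genotype`
#'   metadata (levels WT and HET) and optionally `batch`
#' @param use_batch include the batch covariate if present (default TRUE)
#' @param min_cpm,min_frac expression filter parameters
#' @return a `data.frame` (class `de_table`) with columns gene, logFC,
#'   t, df, pval, padj, baseMean
#' @export
de_test <- function(pb, use_batch = TRUE, min_cpm = 1, min_frac = 0.5) {
  gt <- pb$meta$genotype
  if (is.null(gt) || !all(c("WT", "HET") %in% gt))
    stop("both WT and HET samples are required")
  cm <- cpm(pb$counts)
  logexpr <- log2(cm + 1)
  bm <- rowMeans(cm)
  batch <- if (use_batch && "batch" %in% names(pb$meta)) pb$meta$batch else NULL
  res <- de_engine(logexpr, bm, gt, batch, min_cpm, min_frac)
  out <- data.frame(gene = rownames(pb$counts)[res$keep],
                    logFC = res$logfc, t = res$t, df = res$df,
                    pval = res$pval, padj = res$padj,
                    baseMean = res$base_mean,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_table", "data.frame")
  out
}
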