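#' Expression-matched module score
#'
#' Scores a gene module per unit (cell, nucleus or cluster) as the mean
#' expression of the module genes minus the mean expression of an
#' expression-matched control pool: genes are placed in `n_bins`
#' quantile bins of mean expression, and each module gene contributes
#' `n_controls` control genes drawn without replacement from its own bin
#' (excluding module genes; draws are independent across module genes,
#' so a control can serve several module genes). The score is therefore
#' centred at 0 for a module with no expression signal and is invariant
#' to adding a constant to all genes of a unit.
#'
#' @param expr normalized expression matrix, genes x units, rownames set
#' @param module_genes character vector of module gene names; genes
#'   absent from `expr` are dropped with a warning
#' @param n_bins number of quantile bins (>= 2)
#' @param n_controls controls drawn per module gene
#' @param seed integer seed making the control draw deterministic
#' @return numeric per-unit score vector (names = colnames of `expr`)
#' @export
module_score <- function(expr, module_genes, n_bins = 24, n_controls = 100,
                         seed = 1) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  present <- intersect(module_genes, rownames(expr))
  if (length(present) == 0) stop("no module gene present in the matrix")
  if (length(present) < length(module_genes))
    warning(sprintf("%d module gene(s) absent from the matrix; dropped",
                    length(module_genes) - length(present)))
  avg <- rowMeans(expr)
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- rownames(expr)
  ctrl <- with_seed(child_seed(seed, "module_score"), {
    unlist(lapply(present, function(g) {
      cand <- setdiff(names(bin)[bin == bin[g]], module_genes)
      if (length(cand) == 0) return(character(0))
      sample(cand, min(n_controls, length(cand)))
    }), use.names = FALSE)
  })
  if (length(ctrl) == 0) stop("no control genes available")
  mod_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  mod_mean - ctrl_mean
}

#' Annotate clusters by best-scoring marker module
#'
#' Scores each marker module in each cluster with [module_score()] on the
#' cluster-mean expression matrix and assigns every cluster the label of
#' its highest-scoring module. Exact ties are broken lexicographically by
#' module name and flagged.
#'
#' @param cluster_expr cluster-mean expression matrix, genes x clusters
#' @param marker_modules named list of marker gene vectors, one per label
#' @param ... passed to [module_score()]
#' @return data.frame with `cluster`, `label`, `tie` (logical) and the
#'   full score matrix as attribute `"scores"`
#' @export
annotate_clusters <- function(cluster_expr, marker_modules, ...) {
  if (is.null(dim(cluster_expr)) || ncol(cluster_expr) == 0)
    stop("empty cluster matrix")
  if (length(marker_modules) == 0) stop("need >= 1 marker module")
  labels <- sort(names(marker_modules))
  scores <- sapply(labels, function(lb)
    module_score(cluster_expr, marker_modules[[lb]], ...))
  scores <- matrix(scores, ncol = length(labels),
                   dimnames = list(colnames(cluster_expr), labels))
  best <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    which(s == max(s))
  })
  tie <- vapply(best, length, 1L) > 1
  lab <- labels[vapply(best, `[`, 1L, 1)]   # lexicographic: labels sorted
  out <- data.frame(cluster = colnames(cluster_expr), label = lab,
                    tie = tie, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scores") <- scores
  out
}

#' Differential module expression against the grey module
#'
#' Tests, per co-expression module, whether the module genes' log2 fold
#' changes differ from those of the reserved "grey" (unassigned) module
#' using a Welch two-sample t-test, reporting both medians for display.
#' Bonferroni correction is applied over all module x population
#' comparisons performed in the call. The direction is the sign of
#' (median module logFC - median grey logFC).
#'
#' @param de a DE table, or a named list of DE tables (one per cell
#'   population); each needs columns `gene` and `logFC`
#' @param modules named character vector or two-column data.frame
#'   (gene, module) mapping genes to module labels; label "grey" is the
#'   reference and is never tested against itself
#' @param min_genes minimum module genes present in a DE table for the
#'   module to be tested there (modules below this are skipped with a
#'   warning)
#' @param one_sample if TRUE, a one-sample t of module logFC against the
#'   grey median (constant) instead of the two-sample Welch test
#' @return data.frame (class `dem_table`): module, population,
#'   median_logfc, median_grey, t, df, pval, p_bonf, n_genes, direction
#' @export
dem_test <- function(de, modules, min_genes = 5, one_sample = FALSE) {
  if (is.data.frame(modules)) {
    mm <- stats::setNames(as.character(modules[[2]]), modules[[1]])
  } else mm <- modules
  if (!"grey" %in% mm) stop("module map must contain a 'grey' module")
  if (is.data.frame(de)) de <- list(all = de)
  rows <- list()
  for (popn in names(de)) {
    d <- de[[popn]]
    grey_lfc <- d$logFC[d$gene %in% names(mm)[mm == "grey"]]
    if (length(grey_lfc) < 2) stop("grey module has < 2 genes with logFC")
    for (mod in setdiff(unique(mm), "grey")) {
      lfc <- d$logFC[d$gene %in% names(mm)[mm == mod]]
      if (length(lfc) == 0) {
        warning("module '", mod, "' absent from DE table '", popn,
                "'; skipped")
        next
      }
      if (length(lfc) < min_genes) {
        warning("module '", mod, "' has < ", min_genes,
                " genes in DE table '", popn, "'; skipped")
        next
      }
      if (one_sample) {
        tt <- stats::t.test(lfc, mu = stats::median(grey_lfc))
      } else {
        tt <- stats::t.test(lfc, grey_lfc)   # Welch by default
      }
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, population = popn,
        median_logfc = stats::median(lfc),
        median_grey = stats::median(grey_lfc),
        t = unname(tt$statistic), df = unname(tt$parameter),
        pval = tt$p.value, n_genes = length(lfc),
        direction = if (stats::median(lfc) >= stats::median(grey_lfc))
          "up" else "down",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no module could be tested")
  out$p_bonf <- pmin(1, out$pval * nrow(out))
  out <- out[, c("module", "population", "median_logfc", "median_grey",
                 "t", "df", "pval", "p_bonf", "n_genes", "direction")]
  class(out) <- c("dem_table", "data.frame")
  out
}
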