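#' Classify nucleus sex from X/Y marker expression
#'
#' A nucleus is called male when its summed Y-marker count reaches
#' `tau_y` and its Xist (X-inactivation) count is at most `tau_x`;
#' female when Xist reaches `tau_x_f` with zero Y signal; otherwise
#' unknown. Thresholds are explicit package defaults (the underlying
#' rule is marker-presence based; tune for ambient contamination).
#'
#' @param nuclei a [count_matrix()] of nucleus-level counts
#' @param y_genes Y-linked marker genes (default Ddx3y, Uty, Eif2s3y,
#'   Kdm5d); at least one must be present
#' @param x_inactive_gene female marker (default "Xist")
#' @param tau_y minimum Y score for a male call
#' @param tau_x maximum Xist count tolerated in a male call
#' @param tau_x_f minimum Xist count for a female call
#' @return character vector per nucleus in `{"M","F","unknown"}`
#' @export
classify_sex <- function(nuclei,
                         y_genes = c("Ddx3y", "Uty", "Eif2s3y", "Kdm5d"),
                         x_inactive_gene = "Xist",
                         tau_y = 1, tau_x = 0, tau_x_f = 1) {
  yp <- intersect(y_genes, rownames(nuclei$counts))
  if (length(yp) == 0 || !x_inactive_gene %in% rownames(nuclei$counts))
    stop("marker genes absent from the matrix")
  score_y <- colSums(nuclei$counts[yp, , drop = FALSE])
  score_x <- as.numeric(nuclei$counts[x_inactive_gene, ])
  out <- rep("unknown", ncol(nuclei$counts))
  out[score_y >= tau_y & score_x <= tau_x] <- "M"
  out[score_x >= tau_x_f & score_y == 0] <- "F"
  stats::setNames(out, colnames(nuclei$counts))
}

#' Assign genotype from pool design and sex
#'
#' In the pooled design every pool contains one male and one female of
#' opposite genotype, so genotype is a pure lookup from (pool, sex).
#' Unknown-sex nuclei are left unassigned (`NA`).
#'
#' @param sex per-nucleus labels in `{"M","F","unknown"}`
#' @param pool_of per-nucleus pool id (same length)
#' @param design named list: pool id -> `c(M = genotype, F = genotype)`
#'   with opposite genotypes in each pool
#' @return character vector of genotypes (`NA` for unknown sex)
#' @export
assign_genotype <- function(sex, pool_of, design) {
  stopifnot(length(sex) == length(pool_of))
  if (!all(pool_of %in% names(design)))
    stop("pool id absent from design: ",
         paste(setdiff(unique(pool_of), names(design)), collapse = ", "))
  for (p in design)
    if (!all(c("M", "F") %in% names(p)) || p[["M"]] == p[["F"]])
      stop("each pool must map both sexes to opposite genotypes")
  out <- rep(NA_character_, length(sex))
  known <- sex %in% c("M", "F")
  out[known] <- mapply(function(p, s) design[[p]][[s]],
                       pool_of[known], sex[known], USE.NAMES = FALSE)
  stats::setNames(out, names(sex))
}

#' Cell-type proportions per sample
#'
#' @param meta nucleus metadata with `sample` and a cell-type column
#' @param type_col cell-type column name
#' @return sample x cell-type matrix of proportions (rows sum to 1)
#' @export
proportion_table <- function(meta, type_col = "cell_type_2") {
  tab <- table(meta$sample, meta[[type_col]])
  sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' Linear model for one cell type's proportion
#'
#' Ordinary least squares of a cell type's per-sample proportion on
#' genotype, sex and batch indicators, with two-sided t p-values on the
#' coefficients (residual df = n - p). Optionally the proportions are
#' logit-transformed first (with a small clamp away from 0/1) for
#' boundary-heavy data.
#'
#' @param props sample x cell-type proportion matrix
#' @param cell_type column of `props` to model
#' @param covars data.frame of per-sample covariates (rows matched to
#'   `props` rows by order) with columns among genotype, sex, batch
#' @param logit model logit(proportion) instead of the raw proportion
#' @return coefficient table: estimate, se, t, p per term
#' @export
proportion_model <- function(props, cell_type, covars, logit = FALSE) {
  if (!cell_type %in% colnames(props)) stop("unknown cell type")
  if (nrow(covars) != nrow(props)) stop("covariate rows must match samples")
  y <- props[, cell_type]
  if (logit) {
    eps <- 0.5 / 1000
    y <- stats::qlogis(pmin(pmax(y, eps), 1 - eps))
  }
  use <- intersect(c("genotype", "sex", "batch"), names(covars))
  dat <- cbind(data.frame(y = y), covars[use])
  for (v in use) if (length(unique(dat[[v]])) < 2) dat[[v]] <- NULL
  fit <- stats::lm(y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased: ", paste(bad, collapse = ", "))
  }
  co <- summary(fit)$coefficients
  data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
             t = co[, 3], p = co[, 4], stringsAsFactors = FALSE,
             row.names = NULL)
}
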