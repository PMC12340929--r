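#' Simulate sample-level pseudobulk counts with planted effects
#'
#' Draws a genes x samples negative-binomial count matrix emulating a
#' balanced two-genotype snRNA-seq pseudobulk design (default 5 WT vs
#' 5 HET samples, alternating sex, two library batches). A chosen
#' fraction of genes carries a genotype log2 fold change; optional
#' planted co-expression modules share a per-sample latent factor and
#' may carry their own genotype shift. All planted effects are returned
#' as ground truth.
#'
#' The negative binomial is parameterized by mean and dispersion with
#' `variance = mu + mu^2 * dispersion`, so `dispersion = 0` is the
#' Poisson limit (drawn with `rpois`).
#'
#' @param n_genes number of genes (>= 10)
#' @param n_per_genotype samples per genotype (>= 2)
#' @param dispersion NB dispersion (>= 0)
#' @param libsize_range range of per-sample library sizes (uniform draw)
#' @param batch_sd SD (log2 scale) of per-gene-per-batch offsets
#' @param fraction_de fraction of genes given the genotype logFC
#' @param logfc_de signed log2 fold change (HET vs WT) for DE genes;
#'   sign is randomized per gene
#' @param modules optional list of planted modules, each a list with
#'   `n_genes`, `logfc` (genotype shift, log2) and `loading` (log2-scale
#'   latent-factor loading); module genes are taken from the non-DE pool
#' @param mean_log2_cpm,sd_log2_cpm location/spread of baseline gene
#'   abundance (log2 CPM scale)
#' @param seed integer seed; fixed seed gives bit-identical output
#' @return list with `counts` (a [count_matrix()], units = samples) and
#'   `truth` (list: `de_genes`, `de_logfc`, `modules` with member genes,
#'   shifts and loadings, `latent` per-sample factor values)
#' @export
sim_pseudobulk_counts <- function(n_genes = 2000, n_per_genotype = 5,
                                  dispersion = 0.1,
                                  libsize_range = c(4e5, 6e5),
                                  batch_sd = 0.1,
                                  fraction_de = 0, logfc_de = 1,
                                  modules = NULL,
                                  mean_log2_cpm = 5, sd_log2_cpm = 2,
                                  seed = 1) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (n_per_genotype < 2) stop("need >= 2 samples per genotype")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (any(libsize_range <= 0)) stop("library sizes must be positive")
  if (fraction_de < 0 || fraction_de > 1) stop("fraction_de must be in [0,1]")
  with_seed(child_seed(seed, "counts"), {
    n_samp <- 2L * n_per_genotype
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- sprintf("s%02d", seq_len(n_samp))
    genotype <- rep(c("WT", "HET"), each = n_per_genotype)
    sex <- rep_len(c("M", "F"), n_samp)
    batch <- rep_len(c("b1", "b2"), n_samp)

    base <- rnorm(n_genes, mean_log2_cpm, sd_log2_cpm)   # log2 relative abundance
    lfc <- numeric(n_genes)
    n_de <- round(fraction_de * n_genes)
    de_idx <- integer(0)
    if (n_de > 0) {
      de_idx <- sample.int(n_genes, n_de)
      lfc[de_idx] <- logfc_de * sample(c(-1, 1), n_de, replace = TRUE)
    }

    latent <- rnorm(n_samp)
    loading <- numeric(n_genes)
    mod_truth <- list()
    if (!is.null(modules)) {
      pool <- setdiff(seq_len(n_genes), de_idx)
      for (k in seq_along(modules)) {
        m <- modules[[k]]
        ng <- m$n_genes
        if (length(pool) < ng) stop("not enough non-DE genes for modules")
        idx <- pool[seq_len(ng)]
        pool <- pool[-seq_len(ng)]
        lfc[idx] <- lfc[idx] + m$logfc
        loading[idx] <- if (is.null(m$loading)) 0.2 else m$loading
        mod_truth[[k]] <- list(genes = genes[idx], logfc = m$logfc,
                               loading = loading[idx][1])
      }
    }

    libsize <- runif(n_samp, libsize_range[1], libsize_range[2])
    het <- as.numeric(genotype == "HET")
    boff <- matrix(rnorm(n_genes * 2, 0, batch_sd), n_genes, 2)
    bcol <- as.integer(factor(batch))

    log2mu <- outer(base, rep(0, n_samp), "+") +
      outer(lfc, het) + outer(loading, latent) + boff[, bcol]
    # constant denominator (baseline total) so planted logFCs appear
    # exactly in the count means; realized library sizes then vary
    # mildly around the drawn targets
    mu <- sweep(2^log2mu / sum(2^base), 2, libsize, "*")
    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), mu), n_genes, n_samp)
    } else {
      matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
             n_genes, n_samp)
    }
    dimnames(counts) <- list(genes, samples)
    meta <- data.frame(sample = samples, genotype = genotype, sex = sex,
                       batch = batch, stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, meta),
         truth = list(de_genes = genes[de_idx], de_logfc = lfc[de_idx],
                      modules = mod_truth, latent = latent))
  })
}

#' Simulate per-nucleus sex-marker counts
#'
#' Nucleus-level counts for Y-linked marker genes and Xist under a
#' pooled design in which each pool contains one male and one female of
#' opposite genotype. Male nuclei draw Poisson counts for every Y marker
#' with the stated mean and ~0 Xist; females the converse. Dropout zeroes
#' each count independently with the stated probability. True sex,
#' genotype and pool per nucleus are recorded.
#'
#' @param n_nuclei_per_pool nuclei per pool (half male, half female in
#'   expectation); may be 0 (empty matrix, no error)
#' @param pools named list mapping pool id to `c(M = genotype, F = genotype)`;
#'   genotypes must be opposite within a pool
#' @param y_mean Poisson mean for each Y marker in males
#' @param xist_mean Poisson mean for Xist in females
#' @param leak_mean Poisson mean of the off-sex marker signal (ambient)
#' @param dropout probability in `[0,1]` a count is zeroed
#' @param y_genes Y-marker gene names
#' @param seed integer seed
#' @return list with `counts` (a [count_matrix()], units = nuclei; marker
#'   genes only) and `truth` (data.frame nucleus/sex/genotype/pool)
#' @export
sim_nuclei_markers <- function(n_nuclei_per_pool = 200,
                               pools = list(p1 = c(M = "WT", F = "HET"),
                                            p2 = c(M = "HET", F = "WT")),
                               y_mean = 5, xist_mean = 8, leak_mean = 0,
                               dropout = 0,
                               y_genes = c("Ddx3y", "Uty", "Eif2s3y", "Kdm5d"),
                               seed = 1) {
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0,1]")
  for (p in pools)
    if (!all(c("M", "F") %in% names(p)) || p[["M"]] == p[["F"]])
      stop("each pool must map both sexes to opposite genotypes")
  with_seed(child_seed(seed, "markers"), {
    gene_names <- c(y_genes, "Xist")
    npool <- length(pools)
    n <- npool * n_nuclei_per_pool
    if (n == 0) {
      cm <- count_matrix(
        matrix(integer(0), length(gene_names), 0,
               dimnames = list(gene_names, character(0))),
        data.frame(sample = character(0)))
      return(list(counts = cm,
                  truth = data.frame(nucleus = character(0), sex = character(0),
                                     genotype = character(0), pool = character(0))))
    }
    pool <- rep(names(pools), each = n_nuclei_per_pool)
    sex <- unlist(lapply(seq_len(npool), function(i)
      rep_len(c("M", "F"), n_nuclei_per_pool)), use.names = FALSE)
    genotype <- mapply(function(p, s) pools[[p]][[s]], pool, sex,
                       USE.NAMES = FALSE)
    male <- sex == "M"
    ymat <- matrix(0L, length(y_genes), n)
    ymat[, male] <- matrix(rpois(length(y_genes) * sum(male), y_mean),
                           length(y_genes))
    if (leak_mean > 0)
      ymat[, !male] <- matrix(rpois(length(y_genes) * sum(!male), leak_mean),
                              length(y_genes))
    xist <- integer(n)
    xist[!male] <- rpois(sum(!male), xist_mean)
    if (leak_mean > 0) xist[male] <- rpois(sum(male), leak_mean)
    counts <- rbind(ymat, xist)
    if (dropout > 0) {
      keep <- matrix(runif(length(counts)) >= dropout, nrow(counts))
      counts <- counts * keep
    }
    storage.mode(counts) <- "integer"
    nuclei <- sprintf("n%05d", seq_len(n))
    dimnames(counts) <- list(gene_names, nuclei)
    meta <- data.frame(sample = pool, pool = pool, stringsAsFactors = FALSE)
    truth <- data.frame(nucleus = nuclei, sex = sex, genotype = genotype,
                        pool = pool, stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, meta), truth = truth)
  })
}

#' Simulate nucleus-level counts with cell types
#'
#' Small nucleus-resolution companion to [sim_pseudobulk_counts()] used
#' to exercise pseudobulk aggregation and cell-type proportion analysis:
#' each nucleus belongs to a sample and to a cell type (three-level
#' hierarchy, with level 3 collapsing types into two classes), and draws
#' Poisson counts around cell-type-specific gene means.
#'
#' @param n_genes genes
#' @param n_samples samples (alternating genotype/sex, two batches)
#' @param n_cell_types distinct cell types at hierarchy level 2
#' @param nuclei_per_sample nuclei drawn per sample
#' @param type_probs optional per-sample cell-type probabilities
#'   (matrix n_samples x n_cell_types); default uniform
#' @param mean_count Poisson mean scale
#' @param seed integer seed
#' @return list with `counts` ([count_matrix()], units = nuclei) and
#'   `truth` (per-type gene means, per-nucleus type)
#' @export
sim_nucleus_counts <- function(n_genes = 100, n_samples = 6,
                               n_cell_types = 3, nuclei_per_sample = 50,
                               type_probs = NULL, mean_count = 2,
                               seed = 1) {
  with_seed(child_seed(seed, "nuclei"), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    types <- sprintf("T%d", seq_len(n_cell_types))
    gmean <- matrix(rexp(n_genes * n_cell_types, 1 / mean_count),
                    n_genes, n_cell_types, dimnames = list(genes, types))
    if (is.null(type_probs))
      type_probs <- matrix(1 / n_cell_types, n_samples, n_cell_types)
    n <- n_samples * nuclei_per_sample
    sample_id <- rep(sprintf("s%02d", seq_len(n_samples)),
                     each = nuclei_per_sample)
    genotype <- rep(rep_len(c("WT", "HET"), n_samples),
                    each = nuclei_per_sample)
    sex <- rep(rep_len(c("M", "F"), n_samples), each = nuclei_per_sample)
    batch <- rep(rep_len(c("b1", "b2"), n_samples), each = nuclei_per_sample)
    type <- unlist(lapply(seq_len(n_samples), function(s)
      sample(types, nuclei_per_sample, replace = TRUE,
             prob = type_probs[s, ])), use.names = FALSE)
    counts <- matrix(rpois(n_genes * n,
                           gmean[, match(type, types), drop = FALSE]),
                     n_genes, n)
    nuclei <- sprintf("n%05d", seq_len(n))
    dimnames(counts) <- list(genes, nuclei)
    lvl3 <- ifelse(as.integer(factor(type, types)) <= ceiling(n_cell_types / 2),
                   "ClassA", "ClassB")
    meta <- data.frame(sample = sample_id, genotype = genotype, sex = sex,
                       batch = batch, cell_type_1 = type, cell_type_2 = type,
                       cell_type_3 = lvl3, stringsAsFactors = FALSE)
    list(counts = count_matrix(counts, meta),
         truth = list(gene_means = gmean, type = type))
  })
}
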