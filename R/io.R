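#' Write a count matrix to disk
#'
#' Sparse MTX plus two sidecar TSVs (`genes.tsv`, `meta.tsv`) when
#' `format = "mtx"`, or a single dense TSV plus `meta.tsv` when
#' `format = "dense"`. Identifiers are never quoted; decimal point is
#' always '.'.
#'
#' @param x a [count_matrix()]
#' @param dir output directory (created if needed)
#' @param format "mtx" or "dense"
#' @return invisibly, the files written
#' @export
write_count_matrix <- function(x, dir, format = c("mtx", "dense")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_f <- file.path(dir, "meta.tsv")
  meta <- cbind(unit = colnames(x$counts), x$meta)
  utils::write.table(meta, meta_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (format == "mtx") {
    mf <- file.path(dir, "counts.mtx")
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(x$counts,
      sparse = TRUE), "generalMatrix"), "CsparseMatrix"), mf)
    gf <- file.path(dir, "genes.tsv")
    writeLines(rownames(x$counts), gf)
    invisible(c(mf, gf, meta_f))
  } else {
    cf <- file.path(dir, "counts.tsv")
    utils::write.table(cbind(gene = rownames(x$counts),
                             as.data.frame(as.matrix(x$counts))),
                       cf, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(cf, meta_f))
  }
}

#' Read a count matrix written by [write_count_matrix()]
#' @param dir directory containing the files
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(dir) {
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = "character")
  units <- meta$unit
  meta$unit <- NULL
  if (file.exists(file.path(dir, "counts.mtx"))) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    rownames(m) <- readLines(file.path(dir, "genes.tsv"))
    colnames(m) <- units
  } else {
    d <- utils::read.table(file.path(dir, "counts.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
  }
  count_matrix(m, meta)
}

#' Write a DE table as TSV
#' @param de a DE table from [de_test()]
#' @param path output file
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, c("gene", "logFC", "pval", "padj", "baseMean")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE table TSV
#' @param path file with header gene, logFC, pval, padj, baseMean
#' @return data.frame of class `de_table`
#' @export
read_de_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene", "logFC", "pval", "padj", "baseMean")
  if (!all(need %in% names(d)))
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  class(d) <- c("de_table", "data.frame")
  d
}

#' Write / read a hypnogram CSV
#'
#' Columns: subject, genotype, start_s, duration_s, state.
#' @param h hypnogram data.frame
#' @param path CSV file
#' @export
write_hypnogram <- function(h, path) {
  utils::write.csv(h, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(h) <- c("hypnogram", "data.frame")
  h
}

#' Write / read a tissue block
#'
#' Soma table as CSV (x, y, z, radius) plus a JSON truth sidecar with
#' the region, true count and true volume.
#'
#' @param tissue a [sim_tissue()] object
#' @param dir output directory
#' @export
write_tissue <- function(tissue, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(tissue$centers, radius = tissue$radii),
                   file.path(dir, "somata.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- list(region = tissue$region, box = tissue$box,
                sphere_radius = tissue$sphere_radius,
                true_count = tissue$true_count,
                true_volume_um3 = tissue$true_volume_um3)
  jsonlite::write_json(truth[!vapply(truth, is.null, TRUE)],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_tissue
#' @export
read_tissue <- function(dir) {
  s <- utils::read.csv(file.path(dir, "somata.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(centers = as.matrix(s[, c("x", "y", "z")]),
                 radii = s$radius, region = truth$region,
                 box = truth$box, sphere_radius = truth$sphere_radius,
                 true_count = truth$true_count,
                 true_volume_um3 = truth$true_volume_um3,
                 true_soma_volumes_um3 = 4 / 3 * pi * s$radius^3),
            class = "tissue")
}

#' Write / read a module map as two-column TSV
#'
#' Columns: gene, module; the reserved label "grey" marks unassigned
#' genes.
#' @param modules named character vector (names = genes) or two-column
#'   data.frame
#' @param path TSV file
#' @export
write_module_map <- function(modules, path) {
  d <- if (is.data.frame(modules)) {
    stats::setNames(modules[, 1:2], c("gene", "module"))
  } else data.frame(gene = names(modules), module = unname(modules))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_module_map
#' @export
read_module_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.character(d$module), d$gene)
}

#' Write / read a trace set as a columnar archive
#'
#' One directory per slice holding the trace and neuropil matrices in
#' Parquet (frames in rows, neurons in columns) plus a metadata table
#' (depth, labels, frame rate). The truth raster, when present, is
#' stored alongside.
#'
#' @param ts a [sim_calcium_traces()] trace set
#' @param dir output directory
#' @export
write_trace_set <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- sprintf("neuron%03d", seq_len(nrow(ts$traces)))
  asdf <- function(m) stats::setNames(as.data.frame(t(m)), nm)
  arrow::write_parquet(asdf(ts$traces), file.path(dir, "traces.parquet"))
  arrow::write_parquet(asdf(ts$neuropil),
                       file.path(dir, "neuropil.parquet"))
  if (!is.null(ts$truth$raster))
    arrow::write_parquet(asdf(ts$truth$raster),
                         file.path(dir, "raster.parquet"))
  meta <- data.frame(neuron = nm, depth_um = ts$depth, slice = ts$slice,
                     animal = ts$animal, genotype = ts$genotype,
                     frame_rate_hz = ts$frame_rate)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  getm <- function(f) t(as.matrix(arrow::read_parquet(file.path(dir, f))))
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  out <- list(traces = unname(getm("traces.parquet")),
              neuropil = unname(getm("neuropil.parquet")),
              depth = meta$depth_um, frame_rate = meta$frame_rate_hz[1],
              slice = meta$slice[1], animal = meta$animal[1],
              genotype = meta$genotype[1], truth = NULL)
  rf <- file.path(dir, "raster.parquet")
  if (file.exists(rf))
    out$truth <- list(raster = unname(getm("raster.parquet")))
  class(out) <- "trace_set"
  out
}
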