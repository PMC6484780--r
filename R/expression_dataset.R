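#' Expression dataset container
#'
#' Bundles a gene x sample count matrix with its sample sheet and gene
#' metadata. Samples are described by `sample_id`, `species`, `cell_type`
#' and `replicate` (extra columns such as `condition` are kept); genes carry
#' at least `gene_id` and `biotype`.
#'
#' @param counts Non-negative integer matrix with rownames = gene ids and
#'   colnames = sample ids.
#' @param samples data.frame with one row per column of `counts`.
#' @param genes data.frame with one row per row of `counts`; default derives
#'   ids from rownames with unknown biotype.
#' @return Object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(counts, samples, genes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts needs unique gene ids as rownames")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts needs unique sample ids as colnames")
  }
  req <- c("sample_id", "species", "cell_type", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id)) {
    stop("sample sheet ids must match count matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(genes)) {
    genes <- data.frame(gene_id = rownames(counts), biotype = NA_character_)
  }
  if (!all(c("gene_id") %in% names(genes)) ||
      !setequal(genes$gene_id, rownames(counts))) {
    stop("gene metadata must carry a gene_id column matching the matrix")
  }
  genes <- genes[match(rownames(counts), genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(counts = counts, samples = samples, genes = genes),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  cat("cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Subset an expression dataset to selected samples
#'
#' @param ds ExpressionDataset.
#' @param sample_ids Character vector of sample ids to keep.
#' @return ExpressionDataset restricted to those samples, in the given order.
#' @export
subset_samples <- function(ds, sample_ids) {
  stopifnot(all(sample_ids %in% colnames(ds$counts)))
  expression_dataset(ds$counts[, sample_ids, drop = FALSE],
                     ds$samples[match(sample_ids, ds$samples$sample_id), ,
                                drop = FALSE],
                     ds$genes)
}

#' Read counts + sample sheet from disk
#'
#' Counts are tab-delimited with a header row of sample ids and gene ids in
#' the first column; the sample sheet is a CSV with columns `sample_id`,
#' `species`, `cell_type`, `replicate` (extra columns kept). Gene metadata,
#' when given, is a tab-delimited table with a `gene_id` column.
#'
#' @param counts_path,samples_path,genes_path File paths (`genes_path`
#'   optional).
#' @return ExpressionDataset.
#' @export
read_expression_dataset <- function(counts_path, samples_path,
                                    genes_path = NULL) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  samples <- utils::read.csv(samples_path)
  genes <- if (!is.null(genes_path)) utils::read.delim(genes_path) else NULL
  expression_dataset(counts, samples, genes)
}

#' Write counts + sample sheet (+ gene metadata) to disk
#'
#' @param ds ExpressionDataset.
#' @param counts_path,samples_path,genes_path Output paths (`genes_path`
#'   optional).
#' @export
write_expression_dataset <- function(ds, counts_path, samples_path,
                                     genes_path = NULL) {
  tab <- data.frame(gene_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(ds$samples, samples_path, row.names = FALSE)
  if (!is.null(genes_path)) {
    utils::write.table(ds$genes, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
}
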