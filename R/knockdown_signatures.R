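#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

# internal: DE between two condition groups within one cell type
.condition_contrast <- function(ds, cell_type, condA, condB, sf, label) {
  s <- ds$samples
  ia <- which(s$cell_type == cell_type & s$condition %in% condA)
  ib <- which(s$cell_type == cell_type & s$condition %in% condB)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need at least 2 replicates per condition in ", cell_type)
  }
  res <- nb_two_group_test(ds$counts[, ia, drop = FALSE],
                           ds$counts[, ib, drop = FALSE],
                           size_factors_a = sf[ia], size_factors_b = sf[ib])
  data.frame(gene_id = rownames(ds$counts), log2fc = res$log2fc,
             pvalue = res$pvalue, fdr = bh_fdr(res$pvalue),
             contrast = label, row.names = NULL)
}

#' Knockdown differential expression within one cell type
#'
#' Runs the pooled contrast (all knockdown shRNAs together versus the
#' control shRNA), which defines significance, plus one contrast per shRNA,
#' which define direction consistency. Positive `log2fc` = higher in
#' knockdown. Size factors are computed once on the cell type's samples.
#'
#' @param ds ExpressionDataset whose sample sheet has a `condition` column
#'   with shRNA labels.
#' @param cell_type Cell type to analyze (e.g. `"CMP"`, `"LSK"`).
#' @param sh_labels Knockdown shRNA condition labels.
#' @param control_label Control shRNA condition label (e.g. `"Renilla"`).
#' @return List with `pooled` (DETable) and `per_sh` (named list of
#'   DETables).
#' @export
knockdown_de <- function(ds, cell_type, sh_labels, control_label) {
  if (!"condition" %in% names(ds$samples)) {
    stop("sample sheet needs a 'condition' column")
  }
  .check_cell_types(ds, cell_type)
  present <- unique(ds$samples$condition[ds$samples$cell_type == cell_type])
  missing <- setdiff(c(sh_labels, control_label), present)
  if (length(missing)) {
    stop("condition(s) absent in ", cell_type, ": ",
         paste(missing, collapse = ", "))
  }
  idx <- which(ds$samples$cell_type == cell_type)
  sf <- rep(NA_real_, ncol(ds$counts))
  sf[idx] <- size_factors(ds$counts[, idx, drop = FALSE])
  pooled <- .condition_contrast(ds, cell_type, sh_labels, control_label, sf,
                                paste(paste(sh_labels, collapse = "+"), "vs",
                                      control_label))
  per_sh <- lapply(sh_labels, function(sh) {
    .condition_contrast(ds, cell_type, sh, control_label, sf,
                        paste(sh, "vs", control_label))
  })
  names(per_sh) <- sh_labels
  list(pooled = pooled, per_sh = per_sh)
}

#' Genes consistently downregulated across shRNAs
#'
#' Default (`mode = "pooled"`): genes significant and down in the pooled
#' contrast (FDR below threshold, negative fold change) whose fold change
#' is negative in *every* per-shRNA contrast. `mode = "per_sh"` instead
#' intersects per-shRNA significance (FDR and direction in each table).
#'
#' @param pooled Pooled DETable.
#' @param per_sh List of per-shRNA DETables over the same genes.
#' @param fdr FDR threshold (default 0.05).
#' @param mode `"pooled"` or `"per_sh"`.
#' @return Character vector of gene ids (sorted).
#' @export
consistent_downregulated <- function(pooled, per_sh, fdr = 0.05,
                                     mode = c("pooled", "per_sh")) {
  mode <- match.arg(mode)
  if (length(per_sh) == 0) stop("need at least one per-shRNA table")
  for (tab in per_sh) {
    if (!identical(tab$gene_id, pooled$gene_id)) {
      stop("per-shRNA tables must cover the same gene universe as the pooled table")
    }
  }
  if (mode == "pooled") {
    keep <- !is.na(pooled$fdr) & pooled$fdr < fdr & pooled$log2fc < 0
    for (tab in per_sh) keep <- keep & tab$log2fc < 0
  } else {
    keep <- rep(TRUE, nrow(pooled))
    for (tab in per_sh) {
      keep <- keep & !is.na(tab$fdr) & tab$fdr < fdr & tab$log2fc < 0
    }
  }
  sort(pooled$gene_id[keep])
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' One-sided hypergeometric tail per set, against the universe of genes
#' tested in the differential-expression contrast, Bonferroni-corrected for
#' the number of sets tested.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param sets Named list of gene sets.
#' @param universe Character vector: genes tested.
#' @return data.frame sorted by p: `set`, `k` (overlap), `n_set` (in-universe
#'   set size), `percent` (100 k / n_set), `pvalue`, `p_bonferroni`.
#' @export
enrich_gene_sets <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(query, s))
    p <- if (length(s) == 0) 1 else
      hypergeom_enrichment(k, length(query), length(s), length(universe))
    data.frame(set = nm, k = k, n_set = length(s),
               percent = if (length(s)) round(100 * k / length(s), 1) else NA_real_,
               pvalue = p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$pvalue * length(sets))
  out <- out[order(out$pvalue, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a pathway captured by a query gene set
#'
#' `k = |query %in% set|`, `N = |set %in% universe|`, percent = 100 k / N
#' rounded to one decimal (e.g. an overlap of 43 in a 130-gene pathway is
#' 33.1%).
#'
#' @param query Query gene ids (e.g. consistently downregulated genes).
#' @param set Pathway gene ids.
#' @param universe Genes tested.
#' @return List with `k`, `N`, `percent`.
#' @export
signature_fraction <- function(query, set, universe) {
  set_u <- intersect(unique(set), unique(universe))
  if (length(set_u) == 0) stop("pathway has no genes in the universe")
  k <- length(intersect(unique(query), set_u))
  list(k = k, N = length(set_u), percent = round(100 * k / length(set_u), 1))
}

#' Induction of signature genes along a differentiation step
#'
#' Differential expression between two cell types in the control condition,
#' restricted to the signature genes: counts how many are significantly
#' upregulated in the destination cell type (FDR below threshold, positive
#' fold change; BH adjustment over all genes tested). Signature genes
#' absent from the dataset are counted in `n_total` as untested and logged.
#'
#' @param ds ExpressionDataset with a `condition` column in its sample sheet.
#' @param signature Character vector of signature gene ids.
#' @param from_cell_type,to_cell_type The differentiation step (e.g. LSK to
#'   CMP).
#' @param control_label Control condition label.
#' @param fdr FDR threshold (default 0.05).
#' @return List: `n_up_significant`, `n_total`, `mean_log2fc` (over tested
#'   signature genes, destination vs origin), `untested` (absent ids).
#' @export
induction_counts <- function(ds, signature, from_cell_type, to_cell_type,
                             control_label, fdr = 0.05) {
  if (length(signature) == 0) {
    return(list(n_up_significant = 0L, n_total = 0L, mean_log2fc = NA_real_,
                untested = character()))
  }
  keep <- ds$samples$sample_id[ds$samples$condition == control_label]
  sub <- subset_samples(ds, keep)
  de <- run_contrast(sub, to_cell_type, from_cell_type)
  hit <- match(signature, de$gene_id)
  untested <- signature[is.na(hit)]
  des <- de[hit[!is.na(hit)], , drop = FALSE]
  list(n_up_significant = sum(des$log2fc > 0 & des$fdr < fdr, na.rm = TRUE),
       n_total = length(signature),
       mean_log2fc = if (nrow(des)) mean(des$log2fc) else NA_real_,
       untested = untested)
}

#' Mean percent expression change of a gene across shRNAs
#'
#' Converts each per-shRNA log2 fold change to a percent reduction,
#' `100 * (1 - 2^log2fc)`, and averages across shRNAs. Negative values
#' indicate an increase. Used to quantify knockdown effects on neighboring
#' genes.
#'
#' @param per_sh List of per-shRNA DETables.
#' @param gene_id Gene to report.
#' @return Mean percent reduction.
#' @export
neighbor_effect <- function(per_sh, gene_id) {
  vals <- vapply(per_sh, function(tab) {
    i <- match(gene_id, tab$gene_id)
    if (is.na(i)) stop("gene absent from a per-shRNA table: ", gene_id)
    tab$log2fc[i]
  }, numeric(1))
  mean(100 * (1 - 2^vals))
}
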