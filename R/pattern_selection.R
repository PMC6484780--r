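#' Configuration for expression-pattern classification
#'
#' Defines the thresholds and cell-type groupings used to call the three
#' candidate expression-pattern classes on mouse progenitor RNA-seq data:
#'
#' * `progenitor_enriched` — up in one progenitor group against the others
#'   (HSC | CMP/GMP pooled | CLP by default);
#' * `lineage_enriched` — differential between differentiated myeloid and
#'   lymphoid cell types with concordant ("primed") differential expression
#'   already present between the myeloid and lymphoid progenitors;
#' * `downregulated_in_differentiation` — down in a differentiated type
#'   relative to its progenitor while differentially expressed between
#'   progenitor/stem populations.
#'
#' @param fc_threshold Fold-change threshold (default 2, on the natural
#'   scale).
#' @param fdr_threshold BH FDR threshold (default 0.05).
#' @param progenitor_groups Named list mapping group label to cell types.
#' @param lineage_pairs Named list with `myeloid` and `lymphoid`
#'   differentiated cell types.
#' @param lineage_progenitors Named list with the progenitor cell types of
#'   the two lineages (for the "primed" contrast).
#' @param differentiation_edges List of `c(progenitor, descendant)` pairs.
#' @param progenitor_mode `"each"` (default; enrichment required against
#'   every other progenitor group) or `"pooled"` (against the pooled rest).
#' @return List of class `pattern_config`.
#' @export
pattern_config <- function(fc_threshold = 2,
                           fdr_threshold = 0.05,
                           progenitor_groups = list(
                             HSC = "HSC",
                             CMP_GMP = c("CMP", "GMP"),
                             CLP = "CLP"
                           ),
                           lineage_pairs = list(
                             myeloid = c("Mono", "Gran"),
                             lymphoid = c("B", "T")
                           ),
                           lineage_progenitors = list(
                             myeloid = c("CMP", "GMP"),
                             lymphoid = "CLP"
                           ),
                           differentiation_edges = list(
                             c("GMP", "Gran"), c("GMP", "Mono"),
                             c("CLP", "B"), c("CLP", "T")
                           ),
                           progenitor_mode = c("each", "pooled")) {
  if (fc_threshold <= 0) stop("fc_threshold must be positive")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  structure(list(fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold,
                 progenitor_groups = progenitor_groups,
                 lineage_pairs = lineage_pairs,
                 lineage_progenitors = lineage_progenitors,
                 differentiation_edges = differentiation_edges,
                 progenitor_mode = match.arg(progenitor_mode)),
            class = "pattern_config")
}

.samples_for <- function(ds, cell_types, species = NULL) {
  keep <- ds$samples$cell_type %in% cell_types
  if (!is.null(species)) keep <- keep & ds$samples$species == species
  ds$samples$sample_id[keep]
}

.check_cell_types <- function(ds, cell_types) {
  missing <- setdiff(cell_types, unique(ds$samples$cell_type))
  if (length(missing)) {
    stop("cell type(s) absent from dataset: ", paste(missing, collapse = ", "))
  }
}

#' Differential-expression contrast between two cell-type groups
#'
#' Runs the NB Wald test on all genes for group A vs group B (positive
#' `log2fc` = higher in A) with BH adjustment across the genes of this one
#' contrast. Size factors are computed once on the full dataset so that all
#' contrasts share a normalization.
#'
#' @param ds ExpressionDataset.
#' @param groupA,groupB Character vectors of cell types (non-overlapping).
#' @param species Optional species restriction.
#' @param sf Optional precomputed size factors for all samples of `ds`.
#' @return `DETable` data.frame: `gene_id`, `log2fc`, `pvalue`, `fdr`,
#'   `contrast`.
#' @export
run_contrast <- function(ds, groupA, groupB, species = NULL, sf = NULL) {
  .check_cell_types(ds, c(groupA, groupB))
  if (length(intersect(groupA, groupB))) stop("contrast groups overlap")
  if (is.null(sf)) sf <- size_factors(ds$counts)
  ia <- match(.samples_for(ds, groupA, species), colnames(ds$counts))
  ib <- match(.samples_for(ds, groupB, species), colnames(ds$counts))
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need at least 2 samples per group")
  }
  res <- nb_two_group_test(ds$counts[, ia, drop = FALSE],
                           ds$counts[, ib, drop = FALSE],
                           size_factors_a = sf[ia], size_factors_b = sf[ib])
  data.frame(gene_id = rownames(ds$counts),
             log2fc = res$log2fc,
             pvalue = res$pvalue,
             fdr = bh_fdr(res$pvalue),
             contrast = paste(paste(groupA, collapse = "+"), "vs",
                              paste(groupB, collapse = "+")),
             row.names = NULL)
}

# significance helpers on a DETable; NA (untested) is treated as not DE
.up <- function(de, cfg) {
  !is.na(de$fdr) & de$log2fc > log2(cfg$fc_threshold) & de$fdr < cfg$fdr_threshold
}
.down <- function(de, cfg) {
  !is.na(de$fdr) & de$log2fc < -log2(cfg$fc_threshold) & de$fdr < cfg$fdr_threshold
}

#' Classify genes into candidate expression-pattern classes
#'
#' Runs all pairwise progenitor-group contrasts, the differentiated
#' myeloid-vs-lymphoid contrast, the myeloid-vs-lymphoid progenitor
#' ("primed") contrast, and each configured differentiation edge, then
#' assigns the three pattern labels described in [pattern_config()]. A gene
#' may carry several labels.
#'
#' @param ds ExpressionDataset (one species).
#' @param cfg A [pattern_config()].
#' @return List with `calls` (data.frame: `gene_id`, one logical column per
#'   label, `n_labels`) and `support` (long data.frame of the label-supporting
#'   contrasts: `gene_id`, `label`, `contrast`, `log2fc`, `fdr`).
#' @export
classify_patterns <- function(ds, cfg = pattern_config()) {
  .check_cell_types(ds, unique(c(unlist(cfg$progenitor_groups),
                                 unlist(cfg$lineage_pairs),
                                 unlist(cfg$lineage_progenitors),
                                 unlist(cfg$differentiation_edges))))
  sf <- size_factors(ds$counts)
  gids <- rownames(ds$counts)
  ng <- length(gids)
  groups <- cfg$progenitor_groups
  glabs <- names(groups)

  # pairwise progenitor contrasts (computed once per unordered pair)
  pairde <- list()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) {
        pairde[[paste(glabs[i], glabs[j])]] <-
          run_contrast(ds, groups[[i]], groups[[j]], sf = sf)
      }
    }
  }
  up_in <- function(i, j) {  # gene up in group i vs group j
    if (i < j) .up(pairde[[paste(glabs[i], glabs[j])]], cfg)
    else .down(pairde[[paste(glabs[j], glabs[i])]], cfg)
  }

  support <- list()
  add_support <- function(label, de, sel) {
    if (!any(sel)) return(invisible(NULL))
    support[[length(support) + 1]] <<-
      data.frame(gene_id = gids[sel], label = label,
                 contrast = de$contrast[sel], log2fc = de$log2fc[sel],
                 fdr = de$fdr[sel])
  }

  # class 1: up vs every other progenitor group (or vs the pooled rest)
  lab1 <- rep(FALSE, ng)
  for (i in seq_along(groups)) {
    if (cfg$progenitor_mode == "each") {
      hit <- rep(TRUE, ng)
      for (j in seq_along(groups)[-i]) hit <- hit & up_in(i, j)
      for (j in seq_along(groups)[-i]) {
        de <- if (i < j) pairde[[paste(glabs[i], glabs[j])]]
              else pairde[[paste(glabs[j], glabs[i])]]
        add_support("progenitor_enriched", de, hit)
      }
    } else {
      de <- run_contrast(ds, groups[[i]], unlist(groups[-i]), sf = sf)
      hit <- .up(de, cfg)
      add_support("progenitor_enriched", de, hit)
    }
    lab1 <- lab1 | hit
  }

  # class 2: differentiated myeloid vs lymphoid DE, concordant with the
  # progenitor-level ("primed") myeloid vs lymphoid DE
  de_diff <- run_contrast(ds, cfg$lineage_pairs$myeloid,
                          cfg$lineage_pairs$lymphoid, sf = sf)
  de_prog <- run_contrast(ds, cfg$lineage_progenitors$myeloid,
                          cfg$lineage_progenitors$lymphoid, sf = sf)
  lab2 <- (.up(de_diff, cfg) & .up(de_prog, cfg)) |
          (.down(de_diff, cfg) & .down(de_prog, cfg))
  add_support("lineage_enriched", de_diff, lab2)
  add_support("lineage_enriched", de_prog, lab2)

  # class 3: down along a differentiation edge AND DE in some pairwise
  # progenitor contrast
  prog_de_any <- rep(FALSE, ng)
  for (de in pairde) prog_de_any <- prog_de_any | .up(de, cfg) | .down(de, cfg)
  lab3 <- rep(FALSE, ng)
  for (edge in cfg$differentiation_edges) {
    de <- run_contrast(ds, edge[2], edge[1], sf = sf)  # descendant vs progenitor
    hit <- .down(de, cfg) & prog_de_any
    add_support("downregulated_in_differentiation", de, hit)
    lab3 <- lab3 | hit
  }

  calls <- data.frame(gene_id = gids,
                      progenitor_enriched = lab1,
                      lineage_enriched = lab2,
                      downregulated_in_differentiation = lab3)
  calls$n_labels <- rowSums(calls[, 2:4])
  support <- if (length(support)) do.call(rbind, support) else
    data.frame(gene_id = character(), label = character(),
               contrast = character(), log2fc = numeric(), fdr = numeric())
  list(calls = calls, support = support[order(support$gene_id), , drop = FALSE])
}

#' Select labelled lncRNA candidates
#'
#' Union of all genes carrying at least one pattern label, restricted to the
#' requested biotype, in deterministic (gene id) order.
#'
#' @param calls Result of [classify_patterns()] (or its `calls` element).
#' @param genes Gene metadata data.frame with `gene_id` and `biotype`.
#' @param biotype Biotype to keep (default `"lncRNA"`).
#' @return Character vector of candidate gene ids.
#' @export
select_candidates <- function(calls, genes, biotype = "lncRNA") {
  if (is.list(calls) && !is.data.frame(calls)) calls <- calls$calls
  labelled <- calls$gene_id[calls$n_labels > 0]
  keep <- genes$gene_id[!is.na(genes$biotype) & genes$biotype == biotype]
  sort(intersect(labelled, keep))
}
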