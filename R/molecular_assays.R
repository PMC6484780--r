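.check_ct_table <- function(ct) {
  req <- c("sample_id", "condition", "target", "replicate", "ct")
  if (!all(req %in% names(ct))) {
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  }
  bad <- !is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 45)
  if (any(bad)) stop("Ct values must lie in (0, 45] (or NA for no amplification)")
  ct
}

#' Relative expression by the delta-delta-Ct method
#'
#' Quantifies a target's expression in each condition relative to a control
#' condition, normalized to a housekeeping gene:
#' `2^-[(Ct_target - Ct_hk)_test - (Ct_target - Ct_hk)_control]`.
#' Technical replicates are averaged to a mean Ct per sample (clonal line)
#' and target; delta-Ct is formed per sample, then averaged per condition.
#' The control condition is 1 by construction. A (condition, sample) whose
#' target never amplified (all Ct missing) is reported as below detection.
#'
#' @param ct Ct table: `sample_id`, `condition`, `target`, `replicate`, `ct`
#'   (NA = no amplification).
#' @param target Target transcript name.
#' @param housekeeping Housekeeping control target (e.g. `"Gapdh"`).
#' @param control_condition Reference condition label.
#' @return List with `per_condition` (data.frame `condition`,
#'   `rel_expression`, `below_detection`) and `per_sample` (data.frame
#'   `condition`, `sample_id`, `delta_ct`, `rel_expression`).
#' @export
ddct_expression <- function(ct, target, housekeeping = "Gapdh",
                            control_condition) {
  ct <- .check_ct_table(ct)
  if (!housekeeping %in% ct$target) stop("housekeeping target not measured")
  if (!target %in% ct$target) stop("target not measured")
  if (!control_condition %in% ct$condition) stop("control condition absent")
  mean_ct <- function(cond, samp, tgt) {
    v <- ct$ct[ct$condition == cond & ct$sample_id == samp & ct$target == tgt]
    if (length(v) == 0) return(NULL)
    if (all(is.na(v))) return(NA_real_)
    mean(v, na.rm = TRUE)
  }
  per_sample <- list()
  for (cond in unique(ct$condition)) {
    for (samp in unique(ct$sample_id[ct$condition == cond])) {
      tg <- mean_ct(cond, samp, target)
      hk <- mean_ct(cond, samp, housekeeping)
      if (is.null(tg)) next
      if (is.null(hk) || is.na(hk)) stop("housekeeping missing for sample ", samp)
      per_sample[[length(per_sample) + 1]] <-
        data.frame(condition = cond, sample_id = samp,
                   delta_ct = tg - hk)  # NA = target below detection
    }
  }
  per_sample <- do.call(rbind, per_sample)
  ctrl_dct <- per_sample$delta_ct[per_sample$condition == control_condition]
  if (all(is.na(ctrl_dct))) stop("control condition target below detection")
  ctrl_mean <- mean(ctrl_dct, na.rm = TRUE)
  per_sample$rel_expression <- 2^-(per_sample$delta_ct - ctrl_mean)
  agg <- stats::aggregate(delta_ct ~ condition, per_sample,
                          function(v) mean(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  bd <- tapply(is.na(per_sample$delta_ct), per_sample$condition, all)
  per_condition <- data.frame(
    condition = agg$condition,
    rel_expression = 2^-(agg$delta_ct - ctrl_mean),
    below_detection = as.vector(bd[agg$condition]))
  list(per_condition = per_condition, per_sample = per_sample)
}

#' qPCR primer efficiency from a serial-dilution standard curve
#'
#' Least-squares slope of Ct against log10 input amount; efficiency is
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle, slope -3.3219).
#' Used as primer QC only; the delta-delta-Ct analysis is not
#' efficiency-corrected.
#'
#' @param log10_dilution Numeric vector of log10 input amounts (>= 3 points).
#' @param ctv Corresponding Ct values.
#' @return List with `efficiency`, `slope`, `r_squared`.
#' @export
primer_efficiency <- function(log10_dilution, ctv) {
  if (length(log10_dilution) < 3) stop("need at least 3 dilution points")
  if (length(log10_dilution) != length(ctv)) stop("length mismatch")
  fit <- stats::lm(ctv ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  if (is.na(slope) || slope >= 0) {
    stop("non-negative slope: invalid dilution series")
  }
  list(efficiency = 10^(-1 / slope) - 1, slope = slope,
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Subcellular fractionation enrichment
#'
#' Enrichment of a transcript in a fraction (cytoplasmic or nuclear)
#' relative to total RNA: `2^-(Ct_fraction - Ct_total)`. This compares
#' enrichment against known control transcripts rather than measuring
#' absolute compartment proportions. Missing Cts propagate as missing.
#'
#' @param ct_fraction,ct_total Ct values (vectors recycle).
#' @return Enrichment values (NA where either Ct is missing).
#' @export
fraction_enrichment <- function(ct_fraction, ct_total) {
  2^-(ct_fraction - ct_total)
}

#' Single-molecule FISH localization fractions
#'
#' Per-cell cytoplasmic fraction of RNA spots, `cyto / (cyto + nuclear)`;
#' cells without any spot are excluded from the cohort mean and logged.
#'
#' @param spots data.frame: `cell_id`, `nuclear_spots`, `cytoplasmic_spots`.
#' @return List with `per_cell` (data.frame `cell_id`, `cyto_fraction`),
#'   `cohort_mean`, and `excluded_cells` (zero-spot cell ids).
#' @export
smfish_localization <- function(spots) {
  req <- c("cell_id", "nuclear_spots", "cytoplasmic_spots")
  if (!all(req %in% names(spots))) {
    stop("spot table needs columns: ", paste(req, collapse = ", "))
  }
  tot <- spots$nuclear_spots + spots$cytoplasmic_spots
  zero <- tot == 0
  per_cell <- data.frame(cell_id = spots$cell_id[!zero],
                         cyto_fraction = spots$cytoplasmic_spots[!zero] /
                           tot[!zero])
  list(per_cell = per_cell,
       cohort_mean = mean(per_cell$cyto_fraction),
       excluded_cells = spots$cell_id[zero])
}
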