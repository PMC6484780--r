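.check_animal_records <- function(records) {
  req <- c("animal_id", "sh_label", "timepoint", "compartment",
           "total", "donor", "donor_zsgreen")
  if (!all(req %in% names(records))) {
    stop("animal records need columns: ", paste(req, collapse = ", "))
  }
  if (any(records$donor > records$total) ||
      any(records$donor_zsgreen > records$donor) ||
      any(records[, c("total", "donor", "donor_zsgreen")] < 0)) {
    stop("invalid event counts: need 0 <= donor_zsgreen <= donor <= total")
  }
  records
}

#' Donor chimerism per animal and timepoint
#'
#' Fraction of events in a compartment that are donor-derived
#' (CD45.2 within CD45.1 recipients). Zero totals yield a missing value.
#'
#' @param records Long per-animal data.frame with columns `animal_id`,
#'   `sh_label`, `timepoint`, `compartment`, `total`, `donor`,
#'   `donor_zsgreen`.
#' @param compartment Compartment to evaluate (default `"overall"`).
#' @return data.frame: `animal_id`, `sh_label`, `timepoint`, `chimerism`.
#' @export
donor_chimerism <- function(records, compartment = "overall") {
  r <- .check_animal_records(records)
  r <- r[r$compartment == compartment, , drop = FALSE]
  data.frame(animal_id = r$animal_id, sh_label = r$sh_label,
             timepoint = r$timepoint,
             chimerism = ifelse(r$total > 0, r$donor / r$total, NA_real_))
}

#' Reporter-positive fraction within the donor compartment
#'
#' Fraction of donor events that carry the zsGreen reporter (i.e. the
#' shRNA cassette); the clone-fitness readout tracked over time. Zero donor
#' counts yield a missing value (excluded downstream).
#'
#' @inheritParams donor_chimerism
#' @return data.frame: `animal_id`, `sh_label`, `timepoint`, `zsgreen_frac`.
#' @export
zsgreen_within_donor <- function(records, compartment = "overall") {
  r <- .check_animal_records(records)
  r <- r[r$compartment == compartment, , drop = FALSE]
  data.frame(animal_id = r$animal_id, sh_label = r$sh_label,
             timepoint = r$timepoint,
             zsgreen_frac = ifelse(r$donor > 0, r$donor_zsgreen / r$donor,
                                   NA_real_))
}

#' Per-animal reporter depletion relative to a baseline timepoint
#'
#' For each animal, the zsGreen-within-donor fraction at every timepoint
#' divided by the animal's own fraction at the baseline timepoint (the first
#' blood measurement; initial transduction rates are not observable, so each
#' animal is its own reference). Animals missing a usable baseline (absent,
#' zero donor, or zero reporter fraction) are excluded and logged.
#'
#' @inheritParams donor_chimerism
#' @param baseline Baseline timepoint (default 4, i.e. week 4).
#' @return data.frame `animal_id`, `sh_label`, `timepoint`, `ratio`, with an
#'   `exclusions` attribute (data.frame `animal_id`, `reason`).
#' @export
relative_depletion <- function(records, baseline = 4, compartment = "overall") {
  z <- zsgreen_within_donor(records, compartment)
  out <- list(); excl <- list()
  for (id in unique(z$animal_id)) {
    zi <- z[z$animal_id == id, , drop = FALSE]
    b <- zi[zi$timepoint == baseline, , drop = FALSE]
    if (nrow(b) == 0) {
      excl[[id]] <- "no baseline record"
    } else if (is.na(b$zsgreen_frac[1]) || b$zsgreen_frac[1] == 0) {
      excl[[id]] <- "baseline zsGreen fraction missing or zero"
    } else {
      zi$ratio <- zi$zsgreen_frac / b$zsgreen_frac[1]
      out[[id]] <- zi[, c("animal_id", "sh_label", "timepoint", "ratio")]
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(animal_id = character(), sh_label = character(),
               timepoint = numeric(), ratio = numeric())
  rownames(res) <- NULL
  attr(res, "exclusions") <- data.frame(animal_id = names(excl),
                                        reason = unlist(excl, use.names = FALSE))
  res
}

#' Per-timepoint significance of depletion versus the control arm
#'
#' Compares the per-animal depletion ratios of each shRNA arm against the
#' control arm at every timepoint, with the Mann-Whitney rank-sum test
#' (constitutive transplant design) or Welch's t test (inducible design).
#'
#' @param depletion Result of [relative_depletion()].
#' @param control_label Control shRNA label (e.g. `"Renilla"`).
#' @param design `"constitutive"` (rank-sum) or `"inducible"` (Welch).
#' @return data.frame: `sh_label`, `timepoint`, `mean_ratio`,
#'   `mean_ratio_control`, `pvalue`.
#' @export
depletion_significance <- function(depletion, control_label,
                                   design = c("constitutive", "inducible")) {
  design <- match.arg(design)
  out <- list()
  for (tp in sort(unique(depletion$timepoint))) {
    d <- depletion[depletion$timepoint == tp & !is.na(depletion$ratio), ]
    ctrl <- d$ratio[d$sh_label == control_label]
    for (sh in setdiff(unique(d$sh_label), control_label)) {
      x <- d$ratio[d$sh_label == sh]
      p <- if (length(x) >= 2 && length(ctrl) >= 2) {
        if (design == "constitutive") rank_sum_test(x, ctrl)$pvalue
        else welch_t_test(x, ctrl)$pvalue
      } else NA_real_
      out[[length(out) + 1]] <- data.frame(
        sh_label = sh, timepoint = tp, mean_ratio = mean(x),
        mean_ratio_control = mean(ctrl), pvalue = p)
    }
  }
  do.call(rbind, out)
}

#' Lineage bias of the reporter-positive clone
#'
#' Ratio of the zsGreen-within-donor fraction in one lineage compartment to
#' the same fraction in the overall donor compartment. A value of 1 means
#' the transduced clone contributes to the lineage in proportion to its
#' overall output; values below 1 indicate bias against the lineage.
#'
#' @inheritParams donor_chimerism
#' @param lineage Lineage compartment label (e.g. `"B220"`, `"myeloid"`).
#' @param overall Label of the overall compartment.
#' @return data.frame: `animal_id`, `sh_label`, `timepoint`, `bias`.
#' @export
lineage_bias <- function(records, lineage, overall = "overall") {
  zl <- zsgreen_within_donor(records, lineage)
  zo <- zsgreen_within_donor(records, overall)
  key <- function(d) paste(d$animal_id, d$timepoint)
  m <- match(key(zl), key(zo))
  denom <- zo$zsgreen_frac[m]
  data.frame(animal_id = zl$animal_id, sh_label = zl$sh_label,
             timepoint = zl$timepoint,
             bias = ifelse(!is.na(denom) & denom > 0,
                           zl$zsgreen_frac / denom, NA_real_))
}

#' Filter animals on donor chimerism at a QC timepoint
#'
#' An animal is retained only when its overall donor chimerism exceeds
#' `min_donor` strictly at the QC timepoint (exactly `min_donor` is
#' excluded).
#'
#' @inheritParams donor_chimerism
#' @param min_donor Chimerism threshold (default 0.20).
#' @param at_week QC timepoint (default 16, weeks post-transplant).
#' @return List with `records` (retained rows, all timepoints) and
#'   `excluded` (data.frame `animal_id`, `chimerism`, `reason`).
#' @export
qc_filter_animals <- function(records, min_donor = 0.20, at_week = 16) {
  ch <- donor_chimerism(records, "overall")
  ch <- ch[ch$timepoint == at_week, , drop = FALSE]
  status <- data.frame(animal_id = ch$animal_id, chimerism = ch$chimerism)
  keep <- status$animal_id[!is.na(status$chimerism) &
                             status$chimerism > min_donor]
  dropped <- status[!status$animal_id %in% keep, , drop = FALSE]
  dropped$reason <- ifelse(is.na(dropped$chimerism),
                           "no events at QC timepoint",
                           sprintf("chimerism %.3f <= %.2f at week %d",
                                   dropped$chimerism, min_donor, at_week))
  no_qc <- setdiff(unique(records$animal_id), status$animal_id)
  if (length(no_qc)) {
    dropped <- rbind(dropped, data.frame(animal_id = no_qc,
                                         chimerism = NA_real_,
                                         reason = "no record at QC timepoint"))
  }
  list(records = records[records$animal_id %in% keep, , drop = FALSE],
       excluded = dropped)
}

#' Relative TMRM intensity of a progenitor population
#'
#' Geometric-mean TMRM intensity of the population of interest divided by
#' the geometric mean over all stem and progenitor cells pooled (the LSK and
#' Lin- Sca1- cKit+ compartments together), normalizing out inter-animal
#' staining differences. With raw event intensities the pool is formed by
#' concatenating events; with per-population summaries (`geomean` + `n`
#' columns) the pooled value is the event-count-weighted geometric mean.
#'
#' @param tmrm Long data.frame: either `animal_id`, `sh_label`,
#'   `population`, `intensity` (one row per event) or `animal_id`,
#'   `sh_label`, `population`, `geomean`, `n`.
#' @param population Population of interest (e.g. `"CMP"`).
#' @param pool_populations Populations forming the stem/progenitor pool.
#' @param floor Optional positive floor for non-positive intensities
#'   (see [geometric_mean()]).
#' @return data.frame: `animal_id`, `sh_label`, `relative_tmrm`.
#' @export
relative_tmrm <- function(tmrm, population,
                          pool_populations = c("LT_HSC", "ST_HSC",
                                               "CMP", "GMP", "MEP"),
                          floor = NULL) {
  summarized <- "geomean" %in% names(tmrm)
  out <- list()
  for (id in unique(tmrm$animal_id)) {
    ti <- tmrm[tmrm$animal_id == id, , drop = FALSE]
    pop <- ti[ti$population == population, , drop = FALSE]
    pool <- ti[ti$population %in% pool_populations, , drop = FALSE]
    val <- if (nrow(pop) == 0 || nrow(pool) == 0) {
      NA_real_
    } else if (summarized) {
      # count-weighted geometric mean of the pooled populations
      gp <- exp(stats::weighted.mean(log(pop$geomean), pop$n))
      gall <- exp(stats::weighted.mean(log(pool$geomean), pool$n))
      gp / gall
    } else {
      geometric_mean(pop$intensity, floor = floor) /
        geometric_mean(pool$intensity, floor = floor)
    }
    out[[id]] <- data.frame(animal_id = id, sh_label = ti$sh_label[1],
                            relative_tmrm = val)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
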