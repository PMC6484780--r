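#' Simulation configuration with planted ground truth
#'
#' One configuration object drives every generator in the package. Defaults
#' describe the study conditions the analyses assume: bulk RNA-seq counts
#' are negative binomial with variance `mu + dispersion * mu^2`
#' (dispersion 0.1, typical for bulk data), six replicates per mouse cell
#' type and four per human cell type, four-fold planted pattern effects,
#' conserved syntelogs sharing a latent log2 profile (sd 1.5) observed in
#' human with sd-0.2 noise, per-interval reporter decay 0.7 and B-lineage
#' bias 0.25 in the planted transplant arms, a 0.8 TMRM multiplier on CMP,
#' 20% residual expression after knockdown with Ct noise sd 0.2, and an
#' 80% cytoplasmic localization fraction.
#'
#' @param seed Integer master seed; generator-specific sub-streams are
#'   derived from it by fixed offsets.
#' @param ... Overrides for any default listed in the function definition.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # expression dataset
    n_genes = 2000, n_per_class = 10,
    n_conserved = 25, n_nonconserved = 25,
    frac_lnc_background = 0.3,
    fold_change = 4, dispersion = 0.1,
    reps_mouse = 6, reps_human = 4,
    mouse_cell_types = c("HSC", "MPP", "CMP", "GMP", "CLP", "MEP",
                         "B", "T", "Mono", "Gran"),
    human_cell_types = c("HSC", "CMP", "GMP", "CLP"),
    base_log2_min = 5, base_log2_max = 9,
    profile_sd = 1.5, conserved_noise_sd = 0.2,
    frac_syntenic_pattern = 0.6, frac_human_expressed = 0.8,
    low_expression_mean = 5,
    # synteny / toy genomes
    chrom_mouse = "chrM1", chrom_human = "chrH1",
    chrom_length_mouse = 8e6, chrom_length_human = 8e6,
    locus_width = 2000, locus_spacing = 5000,
    chain_gap = 10, neg_strand_every = 4,
    # transplant cohorts
    n_animals_per_arm = 6,
    timepoints = c(4, 8, 12, 16, 20),
    events_overall = 10000,
    lineage_props = c(B220 = 0.35, myeloid = 0.45),
    chimerism_mean = 0.6, chimerism_sd = 0.08,
    zsgreen_start = 0.4, zsgreen_animal_sd = 0.15,
    depletion_decay = c(Renilla = 1, shSpehd = 0.7),
    bias_multiplier = c(Renilla = 1, shEbf1 = 0.25),
    bias_lineage = "B220",
    # TMRM
    tmrm_arms = c("Renilla", "shSpehd"),
    tmrm_populations = c(LT_HSC = 0.8, ST_HSC = 0.9, CMP = 1.1,
                         GMP = 1.0, MEP = 1.2),
    tmrm_multiplier = list(shSpehd = c(CMP = 0.8)),
    tmrm_events = 500, tmrm_log_sd = 0.4, tmrm_base = 1000,
    tmrm_animal_sd = 0.2,
    # qPCR / fractionation / smFISH
    kd_fraction = c(shSpehd = 0.2),
    qpcr_control = "Renilla",
    n_clonal_lines = 3, n_qpcr_reps = 3, ct_noise_sd = 0.2,
    ct_base_target = 25, ct_base_hk = 18,
    cyto_enrichment = c(lncX = 1.5, Gapdh = 4, Malat1 = 0.1),
    nuc_enrichment = c(lncX = 0.6, Gapdh = 0.2, Malat1 = 8),
    primer_efficiency_true = 1.0, dilution_points = 0:-4,
    smfish_cells = 100, smfish_spots = 50, smfish_cyto_fraction = 0.8,
    # knockdown RNA-seq signature dataset
    kd_n_genes = 1000, kd_reps = 4,
    kd_sh_labels = c("sh1", "sh2"), kd_control = "Renilla",
    kd_cell_types = c("LSK", "CMP"),
    oxphos_size = 40, oxphos_down_fold = 1.5,
    kd_down_n = 50, kd_down_fold = 2,
    induction_fold = 3, induction_frac = 0.67,
    n_decoy_sets = 5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  .validate_sim_config(cfg)
}

.validate_sim_config <- function(cfg) {
  bad <- character()
  pos <- c("n_genes", "reps_mouse", "reps_human", "fold_change",
           "locus_width", "locus_spacing", "n_animals_per_arm",
           "events_overall", "tmrm_events", "n_clonal_lines", "n_qpcr_reps",
           "smfish_cells", "smfish_spots", "kd_n_genes", "kd_reps")
  for (f in pos) if (cfg[[f]] <= 0) bad <- c(bad, paste(f, "must be positive"))
  if (cfg$dispersion <= 0) bad <- c(bad, "dispersion must be positive")
  frc <- c("frac_lnc_background", "frac_syntenic_pattern",
           "frac_human_expressed", "smfish_cyto_fraction", "induction_frac")
  for (f in frc) if (cfg[[f]] < 0 || cfg[[f]] > 1) {
    bad <- c(bad, paste(f, "must lie in [0, 1]"))
  }
  if (any(cfg$kd_fraction < 0 | cfg$kd_fraction > 1)) {
    bad <- c(bad, "kd_fraction entries must lie in [0, 1]")
  }
  if (any(cfg$depletion_decay <= 0) || any(cfg$bias_multiplier <= 0)) {
    bad <- c(bad, "decay and bias multipliers must be positive")
  }
  if (length(bad)) stop("invalid sim_config: ", paste(bad, collapse = "; "))
  structure(cfg, class = "sim_config")
}

# counts ~ NB(mu, dispersion) for a matrix of per-sample means
.rnb <- function(mu, dispersion) {
  matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

.make_samples <- function(species, cell_types, reps, prefix) {
  df <- expand.grid(replicate = seq_len(reps), cell_type = cell_types,
                    stringsAsFactors = FALSE)
  df$species <- species
  df$sample_id <- sprintf("%s_%s_r%d", prefix, df$cell_type, df$replicate)
  df[, c("sample_id", "species", "cell_type", "replicate")]
}

#' Generate mouse + human expression datasets with planted truth
#'
#' Plants three pattern classes of mouse lncRNAs (progenitor-group
#' enrichment, concordant lineage enrichment, downregulation along a
#' differentiation edge on top of progenitor-level differences), a pool of
#' profiled syntenic lncRNAs split into conserved (human profile = mouse
#' latent profile + noise) and non-conserved (independent human profile)
#' pairs, and flat background genes. All counts are negative binomial;
#' output is deterministic given the config seed.
#'
#' @param cfg [sim_config()].
#' @return List: `mouse` and `human` ExpressionDatasets and `truth`, a
#'   data.frame with one row per mouse gene (`gene_id`, `biotype`,
#'   `pattern_class`, `syntenic`, `human_id`, `conserved`,
#'   `human_expressed`).
#' @export
generate_expression_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 11)
  n_pat <- 3 * cfg$n_per_class
  n_prof <- cfg$n_conserved + cfg$n_nonconserved
  n_bg <- cfg$n_genes - n_pat - n_prof
  if (n_bg < 0) stop("n_genes too small for the planted gene pools")
  gid <- sprintf("mg%04d", seq_len(cfg$n_genes))
  pattern_class <- rep(NA_character_, cfg$n_genes)
  pattern_class[seq_len(cfg$n_per_class)] <- "progenitor_enriched"
  pattern_class[cfg$n_per_class + seq_len(cfg$n_per_class)] <- "lineage_enriched"
  pattern_class[2 * cfg$n_per_class + seq_len(cfg$n_per_class)] <-
    "downregulated_in_differentiation"
  profiled <- n_pat + seq_len(n_prof)
  biotype <- rep("protein_coding", cfg$n_genes)
  biotype[seq_len(n_pat + n_prof)] <- "lncRNA"
  if (n_bg > 0) {
    bg <- n_pat + n_prof + seq_len(n_bg)
    biotype[sample(bg, round(cfg$frac_lnc_background * n_bg))] <- "lncRNA"
  }

  cts <- cfg$mouse_cell_types
  lfc <- log2(cfg$fold_change)
  base <- stats::runif(cfg$n_genes, cfg$base_log2_min, cfg$base_log2_max)
  logmu <- matrix(base, cfg$n_genes, length(cts),
                  dimnames = list(gid, cts))
  # class 1: enriched in one progenitor group (rotating)
  groups <- list(HSC = "HSC", CMP_GMP = c("CMP", "GMP"), CLP = "CLP")
  for (i in seq_len(cfg$n_per_class)) {
    g <- groups[[(i - 1) %% 3 + 1]]
    logmu[i, g] <- logmu[i, g] + lfc
  }
  # class 2: concordant lineage enrichment (alternating direction)
  for (i in cfg$n_per_class + seq_len(cfg$n_per_class)) {
    up <- if (i %% 2 == 0) c("Mono", "Gran", "CMP", "GMP") else
      c("B", "T", "CLP")
    logmu[i, up] <- logmu[i, up] + lfc
  }
  # class 3: high in CMP/GMP (progenitor-level DE) and dropping in the
  # differentiated myeloid descendants
  for (i in 2 * cfg$n_per_class + seq_len(cfg$n_per_class)) {
    logmu[i, c("CMP", "GMP")] <- logmu[i, c("CMP", "GMP")] + lfc
  }
  # profiled syntenic lncRNAs: latent profile over the shared progenitor panel
  shared <- cfg$human_cell_types
  latent <- matrix(stats::rnorm(n_prof * length(shared), 0, cfg$profile_sd),
                   n_prof, length(shared), dimnames = list(NULL, shared))
  logmu[profiled, shared] <- logmu[profiled, shared] + latent

  msamp <- .make_samples("mouse", cts, cfg$reps_mouse, "m")
  mu <- 2^logmu[, msamp$cell_type, drop = FALSE]
  colnames(mu) <- msamp$sample_id
  mcounts <- .rnb(mu, cfg$dispersion)

  # human syntelogs: all profiled genes, plus a fraction of pattern genes
  syntenic <- rep(FALSE, cfg$n_genes)
  syntenic[profiled] <- TRUE
  pat_syn <- which(!is.na(pattern_class))
  pat_syn <- pat_syn[stats::runif(length(pat_syn)) < cfg$frac_syntenic_pattern]
  syntenic[pat_syn] <- TRUE
  human_id <- ifelse(syntenic, sub("^mg", "hg", gid), NA_character_)
  conserved <- rep(NA, cfg$n_genes)
  conserved[syntenic] <- FALSE
  conserved[n_pat + seq_len(cfg$n_conserved)] <- TRUE   # conserved profiled pool
  conserved[pat_syn] <- TRUE                            # pattern syntelogs share profiles
  human_expressed <- rep(NA, cfg$n_genes)
  human_expressed[syntenic] <- stats::runif(sum(syntenic)) < cfg$frac_human_expressed

  hsamp <- .make_samples("human", shared, cfg$reps_human, "h")
  hidx <- which(syntenic)
  hbase <- ifelse(human_expressed[hidx],
                  stats::runif(length(hidx), cfg$base_log2_min, cfg$base_log2_max),
                  log2(cfg$low_expression_mean))
  hlogmu <- matrix(hbase, length(hidx), length(shared),
                   dimnames = list(human_id[hidx], shared))
  mprof <- logmu[, shared, drop = FALSE]
  mprof <- mprof - rowMeans(mprof)
  for (r in seq_along(hidx)) {
    i <- hidx[r]
    hlogmu[r, ] <- hlogmu[r, ] + (if (conserved[i]) {
      mprof[i, ] + stats::rnorm(length(shared), 0, cfg$conserved_noise_sd)
    } else {
      stats::rnorm(length(shared), 0, cfg$profile_sd)
    })
  }
  hmu <- 2^hlogmu[, hsamp$cell_type, drop = FALSE]
  colnames(hmu) <- hsamp$sample_id
  hcounts <- .rnb(hmu, cfg$dispersion)

  mouse <- expression_dataset(mcounts, msamp,
                              data.frame(gene_id = gid, biotype = biotype))
  human <- expression_dataset(hcounts, hsamp,
                              data.frame(gene_id = rownames(hlogmu),
                                         biotype = "lncRNA"))
  truth <- data.frame(gene_id = gid, biotype = biotype,
                      pattern_class = pattern_class,
                      syntenic = syntenic, human_id = human_id,
                      conserved = conserved,
                      human_expressed = human_expressed)
  list(mouse = mouse, human = human, truth = truth)
}

#' Generate toy two-species genomes: annotations + a liftover chain
#'
#' Lays mouse lncRNA loci along a toy chromosome; syntenic loci are covered
#' (above the default liftOver match fraction) by a dedicated chain mapping
#' onto the human syntelog's interval, with small alignment gaps, and every
#' fourth syntenic chain on the negative strand; non-syntenic loci fall
#' outside all chains. Human syntelog intervals are annotated at the mapped
#' positions (shuffled order along the human chromosome).
#'
#' @param cfg [sim_config()].
#' @param truth Optional truth table from [generate_expression_dataset()];
#'   its lncRNA genes and syntenic/syntelog assignments are reused. Without
#'   it, a standalone set of loci is created.
#' @return List: `mouse_genes`, `human_genes` (annotation data.frames),
#'   `chain` (`chain_map`), `truth` (data.frame `gene_id`, `syntenic`,
#'   `human_id`).
#' @export
generate_synteny_dataset <- function(cfg = sim_config(), truth = NULL) {
  set.seed(cfg$seed + 22)
  if (is.null(truth)) {
    n <- cfg$n_conserved + cfg$n_nonconserved
    gene_id <- sprintf("mg%04d", seq_len(n))
    syntenic <- stats::runif(n) < 0.5
    human_id <- ifelse(syntenic, sub("^mg", "hg", gene_id), NA_character_)
  } else {
    keep <- truth$biotype == "lncRNA"
    gene_id <- truth$gene_id[keep]
    syntenic <- truth$syntenic[keep]
    human_id <- truth$human_id[keep]
  }
  n <- length(gene_id)
  w <- cfg$locus_width; sp <- cfg$locus_spacing
  margin <- 100
  starts <- 1000 + (seq_len(n) - 1) * (w + sp)
  if (max(starts) + w + margin > cfg$chrom_length_mouse) {
    stop("infeasible packing: mouse chromosome too short for ", n, " loci")
  }
  mouse_genes <- data.frame(gene_id = gene_id, chrom = cfg$chrom_mouse,
                            start = starts, end = starts + w,
                            strand = "+", biotype = "lncRNA")
  syn_idx <- which(syntenic)
  hstarts_pool <- 1000 + (seq_along(syn_idx) - 1) * (w + sp)
  if (length(syn_idx) &&
      max(hstarts_pool) + w + margin > cfg$chrom_length_human) {
    stop("infeasible packing: human chromosome too short")
  }
  hstarts <- sample(hstarts_pool)   # decouple order across species
  chains <- list()
  human_rows <- list()
  for (j in seq_along(syn_idx)) {
    i <- syn_idx[j]
    s <- starts[i]; hs <- hstarts[j]
    neg <- j %% cfg$neg_strand_every == 0
    t_start <- s - margin; t_end <- s + w + margin
    span <- t_end - t_start
    gap <- cfg$chain_gap
    b <- floor((span - 2 * gap) / 3)
    sizes <- c(b, b, span - 2 * gap - 2 * b)
    q_plus_start <- hs - margin
    q_plus_end <- q_plus_start + span
    ch <- list(score = 1000, t_name = cfg$chrom_mouse,
               t_size = cfg$chrom_length_mouse, t_strand = "+",
               t_start = t_start, t_end = t_end,
               q_name = cfg$chrom_human, q_size = cfg$chrom_length_human,
               q_strand = if (neg) "-" else "+",
               q_start = if (neg) cfg$chrom_length_human - q_plus_end
                         else q_plus_start,
               q_end = if (neg) cfg$chrom_length_human - q_plus_start
                       else q_plus_end,
               id = as.character(j),
               blocks = data.frame(size = sizes, dt = c(gap, gap, 0),
                                   dq = c(gap, gap, 0)))
    chains[[j]] <- .validate_chain(ch)
    human_rows[[j]] <- data.frame(gene_id = human_id[i],
                                  chrom = cfg$chrom_human,
                                  start = hs, end = hs + w,
                                  strand = if (neg) "-" else "+",
                                  biotype = "lncRNA")
  }
  human_genes <- if (length(human_rows)) do.call(rbind, human_rows) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer(), strand = character(), biotype = character())
  list(mouse_genes = mouse_genes, human_genes = human_genes,
       chain = structure(chains, class = "chain_map"),
       truth = data.frame(gene_id = gene_id, syntenic = syntenic,
                          human_id = human_id))
}

#' Generate per-animal transplant summaries and TMRM intensities
#'
#' Samples gated flow-cytometry event summaries for competitive-transplant
#' cohorts: per animal, timepoint and compartment, donor events are binomial
#' in the animal's chimerism and reporter-positive donor events binomial in
#' a zsGreen rate that decays by the arm's planted per-interval multiplier
#' (and is multiplied by the arm's planted bias in the target lineage).
#' Compartments are sampled independently around their planted rates. TMRM
#' event intensities are log-normal with planted per-population multipliers
#' and a per-animal staining factor.
#'
#' @param cfg [sim_config()].
#' @return List: `records` (animal summary data.frame), `tmrm` (long event
#'   intensity data.frame), `truth` (per-arm planted parameters).
#' @export
generate_transplant_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 33)
  if (cfg$n_animals_per_arm < 2) stop("need at least 2 animals per arm")
  arms <- union(names(cfg$depletion_decay), names(cfg$bias_multiplier))
  baseline <- cfg$timepoints[1]
  interval <- if (length(cfg$timepoints) > 1) diff(cfg$timepoints)[1] else 1
  rows <- list()
  for (arm in arms) {
    decay <- ifelse(arm %in% names(cfg$depletion_decay),
                    cfg$depletion_decay[[arm]], 1)
    bias <- ifelse(arm %in% names(cfg$bias_multiplier),
                   cfg$bias_multiplier[[arm]], 1)
    for (a in seq_len(cfg$n_animals_per_arm)) {
      id <- sprintf("%s_a%02d", arm, a)
      chim <- min(max(stats::rnorm(1, cfg$chimerism_mean, cfg$chimerism_sd),
                      0.05), 0.95)
      zs0 <- min(cfg$zsgreen_start *
                   exp(stats::rnorm(1, 0, cfg$zsgreen_animal_sd)), 0.9)
      for (tp in cfg$timepoints) {
        zs <- min(zs0 * decay^((tp - baseline) / interval), 0.95)
        comps <- c(overall = 1, cfg$lineage_props)
        for (cn in names(comps)) {
          total <- round(cfg$events_overall * comps[[cn]])
          rate <- if (cn == cfg$bias_lineage) min(zs * bias, 0.95) else zs
          donor <- stats::rbinom(1, total, chim)
          dz <- stats::rbinom(1, donor, rate)
          rows[[length(rows) + 1]] <- data.frame(
            animal_id = id, sh_label = arm, timepoint = tp,
            compartment = cn, total = total, donor = donor,
            donor_zsgreen = dz)
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  tm <- list()
  for (arm in cfg$tmrm_arms) {
    mult <- cfg$tmrm_multiplier[[arm]]
    for (a in seq_len(cfg$n_animals_per_arm)) {
      id <- sprintf("%s_t%02d", arm, a)
      afac <- exp(stats::rnorm(1, 0, cfg$tmrm_animal_sd))
      for (p in names(cfg$tmrm_populations)) {
        m <- if (!is.null(mult) && p %in% names(mult)) mult[[p]] else 1
        ints <- stats::rlnorm(cfg$tmrm_events,
                              meanlog = log(cfg$tmrm_base *
                                            cfg$tmrm_populations[[p]] *
                                            m * afac),
                              sdlog = cfg$tmrm_log_sd)
        tm[[length(tm) + 1]] <- data.frame(animal_id = id, sh_label = arm,
                                           population = p, intensity = ints)
      }
    }
  }
  tmrm <- do.call(rbind, tm)
  rownames(tmrm) <- NULL
  truth <- data.frame(
    arm = arms,
    decay = vapply(arms, function(a)
      ifelse(a %in% names(cfg$depletion_decay), cfg$depletion_decay[[a]], 1),
      numeric(1)),
    bias = vapply(arms, function(a)
      ifelse(a %in% names(cfg$bias_multiplier), cfg$bias_multiplier[[a]], 1),
      numeric(1)))
  list(records = records, tmrm = tmrm, truth = truth)
}

#' Generate qPCR, fractionation, dilution-series and smFISH tables
#'
#' Ct values encode expression as `Ct = baseline - log2(expression) +
#' noise`; knockdown conditions multiply expression by the planted residual
#' fraction. Fractionation Cts encode the planted compartment enrichments;
#' the dilution series encodes the planted primer efficiency; smFISH spot
#' counts are binomial in the planted cytoplasmic fraction.
#'
#' @param cfg [sim_config()].
#' @return List: `ct` (knockdown Ct table), `fractionation` (data.frame
#'   `target`, `fraction`, `ct`), `dilution` (data.frame `log10_dilution`,
#'   `ct`), `smfish` (spot table), `truth`.
#' @export
generate_assay_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 44)
  conds <- c(cfg$qpcr_control, names(cfg$kd_fraction))
  rows <- list()
  for (cond in conds) {
    expr <- if (cond == cfg$qpcr_control) 1 else cfg$kd_fraction[[cond]]
    for (line in seq_len(cfg$n_clonal_lines)) {
      sid <- sprintf("%s_line%d", cond, line)
      for (rep in seq_len(cfg$n_qpcr_reps)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, condition = cond, target = "lncX",
          replicate = rep,
          ct = cfg$ct_base_target - log2(expr) +
            stats::rnorm(1, 0, cfg$ct_noise_sd))
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, condition = cond, target = "Gapdh",
          replicate = rep,
          ct = cfg$ct_base_hk + stats::rnorm(1, 0, cfg$ct_noise_sd))
      }
    }
  }
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL

  targets <- names(cfg$cyto_enrichment)
  frac <- do.call(rbind, lapply(targets, function(tg) {
    tot <- cfg$ct_base_target + stats::rnorm(1, 0, cfg$ct_noise_sd)
    data.frame(target = tg,
               fraction = c("total", "cytoplasmic", "nuclear"),
               ct = c(tot,
                      tot - log2(cfg$cyto_enrichment[[tg]]) +
                        stats::rnorm(1, 0, cfg$ct_noise_sd),
                      tot - log2(cfg$nuc_enrichment[[tg]]) +
                        stats::rnorm(1, 0, cfg$ct_noise_sd)))
  }))

  slope <- -1 / log10(1 + cfg$primer_efficiency_true)
  dilution <- data.frame(
    log10_dilution = cfg$dilution_points,
    ct = 20 + slope * cfg$dilution_points +
      stats::rnorm(length(cfg$dilution_points), 0, cfg$ct_noise_sd / 10))

  smfish <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(cfg$smfish_cells)),
    cytoplasmic_spots = stats::rbinom(cfg$smfish_cells, cfg$smfish_spots,
                                      cfg$smfish_cyto_fraction))
  smfish$nuclear_spots <- cfg$smfish_spots - smfish$cytoplasmic_spots
  smfish <- smfish[, c("cell_id", "nuclear_spots", "cytoplasmic_spots")]

  list(ct = ct, fractionation = frac, dilution = dilution, smfish = smfish,
       truth = list(kd_fraction = cfg$kd_fraction,
                    cyto_enrichment = cfg$cyto_enrichment,
                    nuc_enrichment = cfg$nuc_enrichment,
                    primer_efficiency = cfg$primer_efficiency_true,
                    smfish_cyto_fraction = cfg$smfish_cyto_fraction))
}

#' Generate a knockdown RNA-seq dataset with a planted pathway signature
#'
#' Two cell types (LSK and CMP by default), a control shRNA and two
#' knockdown shRNAs. A planted "oxphos" pathway set is coordinately
#' downregulated in knockdown CMP samples only (both shRNAs); a further
#' planted set is more strongly downregulated (for recovery of the
#' consistent-downregulation call); a fraction of the pathway genes is
#' induced between the origin and destination cell type in all conditions.
#' Decoy gene sets of matched size are drawn from the background.
#'
#' @param cfg [sim_config()].
#' @return List: `ds` (ExpressionDataset whose sample sheet carries a
#'   `condition` column), `gene_sets` (named list incl. `"oxphos"`),
#'   `truth` (planted memberships and folds).
#' @export
generate_knockdown_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed + 55)
  n <- cfg$kd_n_genes
  gid <- sprintf("kg%04d", seq_len(n))
  oxphos <- gid[seq_len(cfg$oxphos_size)]
  down_extra <- gid[cfg$oxphos_size + seq_len(cfg$kd_down_n)]
  induced <- oxphos[seq_len(round(cfg$induction_frac * cfg$oxphos_size))]
  conds <- c(cfg$kd_control, cfg$kd_sh_labels)
  samples <- expand.grid(replicate = seq_len(cfg$kd_reps),
                         condition = conds,
                         cell_type = cfg$kd_cell_types,
                         stringsAsFactors = FALSE)
  samples$species <- "mouse"
  samples$sample_id <- sprintf("k_%s_%s_r%d", samples$cell_type,
                               samples$condition, samples$replicate)
  samples <- samples[, c("sample_id", "species", "cell_type", "replicate",
                         "condition")]
  base <- stats::runif(n, cfg$base_log2_min, cfg$base_log2_max)
  dest <- cfg$kd_cell_types[2]
  mu <- sapply(seq_len(nrow(samples)), function(j) {
    lm <- base
    if (samples$cell_type[j] == dest) {
      lm[gid %in% induced] <- lm[gid %in% induced] + log2(cfg$induction_fold)
      if (samples$condition[j] != cfg$kd_control) {
        lm[gid %in% oxphos] <- lm[gid %in% oxphos] - log2(cfg$oxphos_down_fold)
        lm[gid %in% down_extra] <- lm[gid %in% down_extra] -
          log2(cfg$kd_down_fold)
      }
    }
    2^lm
  })
  dimnames(mu) <- list(gid, samples$sample_id)
  counts <- .rnb(mu, cfg$dispersion)
  ds <- expression_dataset(counts, samples,
                           data.frame(gene_id = gid, biotype = "protein_coding"))
  bg <- setdiff(gid, c(oxphos, down_extra))
  sets <- list(oxphos = oxphos)
  for (d in seq_len(cfg$n_decoy_sets)) {
    sets[[sprintf("decoy%02d", d)]] <- sample(bg, cfg$oxphos_size)
  }
  list(ds = ds, gene_sets = sets,
       truth = list(oxphos = oxphos, down_extra = down_extra,
                    induced = induced,
                    oxphos_down_fold = cfg$oxphos_down_fold,
                    kd_down_fold = cfg$kd_down_fold,
                    induction_fold = cfg$induction_fold))
}

#' Serialize a truth table to JSON
#'
#' @param truth Any truth object from the generators.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}
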