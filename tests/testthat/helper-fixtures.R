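# small in-code fixtures shared across test files

# dataset in which every cell type has the given per-gene means (list of
# name -> mean vector), NB noise optional (sd = 0 gives deterministic counts)
make_ds <- function(means, reps = 3, dispersion = NULL, seed = 1,
                    species = "mouse", biotype = "lncRNA") {
  set.seed(seed)
  cts <- names(means)
  ng <- length(means[[1]])
  cols <- list(); samp <- list()
  for (ct in cts) for (r in seq_len(reps)) {
    mu <- means[[ct]]
    cnt <- if (is.null(dispersion)) round(mu) else
      stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
    sid <- sprintf("%s_%s_r%d", species, ct, r)
    cols[[sid]] <- cnt
    samp[[sid]] <- data.frame(sample_id = sid, species = species,
                              cell_type = ct, replicate = r)
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("g%03d", seq_len(ng))
  expression_dataset(counts, do.call(rbind, samp),
                     data.frame(gene_id = rownames(counts),
                                biotype = rep(biotype, ng)))
}

# one identity chain covering [0, len) of chrom -> hchrom
identity_chain <- function(len = 1000, chrom = "chr1", hchrom = "chrH1") {
  structure(list(list(score = 100, t_name = chrom, t_size = len,
                      t_strand = "+", t_start = 0, t_end = len,
                      q_name = hchrom, q_size = len, q_strand = "+",
                      q_start = 0, q_end = len, id = "1",
                      blocks = data.frame(size = len, dt = 0, dq = 0))),
            class = "chain_map")
}

# random chain generator for property tests: random blocks/gaps, random
# strand, placed on chrT mapping to chrQ
random_chain <- function(id, t_size = 100000, q_size = 100000) {
  nb <- sample(1:5, 1)
  sizes <- sample(5:400, nb, replace = TRUE)
  dt <- c(sample(0:200, nb - 1, replace = TRUE), 0)
  dq <- c(sample(0:200, nb - 1, replace = TRUE), 0)
  span_t <- sum(sizes) + sum(dt)
  span_q <- sum(sizes) + sum(dq)
  t_start <- sample(0:(t_size - span_t), 1)
  q_start <- sample(0:(q_size - span_q), 1)
  list(score = 1, t_name = "chrT", t_size = t_size, t_strand = "+",
       t_start = t_start, t_end = t_start + span_t,
       q_name = "chrQ", q_size = q_size,
       q_strand = sample(c("+", "-"), 1),
       q_start = q_start, q_end = q_start + span_q,
       id = as.character(id),
       blocks = data.frame(size = sizes, dt = dt, dq = dq))
}
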