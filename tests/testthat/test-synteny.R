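test_that("chain parsing handles identity chains and rejects malformed input", {
  f <- withr::local_tempfile()
  writeLines(c("chain 100 chr1 1000 + 0 1000 chrH1 1000 + 0 1000 1",
               "1000", ""), f)
  cm <- parse_chain(f)
  expect_length(cm, 1)
  expect_equal(cm[[1]]$blocks$size, 1000)

  bad <- withr::local_tempfile()
  writeLines(c("chain 100 chr1 1000 + 0 1000 chrH1 1000 + 0 1000 1",
               "400 -5 -5", "590"), bad)
  expect_error(parse_chain(bad), "negative gap")

  bad2 <- withr::local_tempfile()
  writeLines("chain oops", bad2)
  expect_error(parse_chain(bad2), "line 1")
})

test_that("generated chains satisfy span invariants and round-trip through the writer", {
  syn <- generate_synteny_dataset(sim_config(seed = 2))
  cm <- syn$chain
  expect_gt(length(cm), 0)
  for (ch in cm) {
    expect_equal(sum(ch$blocks$size) + sum(ch$blocks$dt), ch$t_end - ch$t_start)
    expect_equal(sum(ch$blocks$size) + sum(ch$blocks$dq), ch$q_end - ch$q_start)
  }
  expect_true(any(vapply(cm, function(ch) ch$q_strand == "-", logical(1))))
  f <- withr::local_tempfile()
  write_chain(cm, f)
  expect_equal(unclass(parse_chain(f)), unclass(cm))
})

test_that("liftover through an identity chain is the identity", {
  cm <- identity_chain(1000)
  r <- liftover_interval(genomic_interval("chr1", 100, 200), cm)
  expect_equal(r$chrom, "chrH1")
  expect_equal(r$start, 100L)
  expect_equal(r$end, 200L)
  expect_equal(r$mapped_fraction, 1)
  # outside the chain: unmapped
  expect_null(liftover_interval(genomic_interval("chr2", 100, 200), cm))
})

test_that("intervals inside chain gaps and ambiguous placements are rejected", {
  # chain with a 100 bp gap between two 100 bp blocks
  ch <- list(score = 1, t_name = "chr1", t_size = 1000, t_strand = "+",
             t_start = 0, t_end = 300, q_name = "chrH1", q_size = 1000,
             q_strand = "+", q_start = 0, q_end = 300, id = "1",
             blocks = data.frame(size = c(100, 100), dt = c(100, 0),
                                 dq = c(100, 0)))
  cm <- structure(list(ch), class = "chain_map")
  expect_null(liftover_interval(genomic_interval("chr1", 110, 190), cm))
  # reaches into the gap: mapped fraction 90/180 < 0.95
  expect_null(liftover_interval(genomic_interval("chr1", 10, 190), cm))
  # but accepted at a permissive min_match, truncated to the mapped block
  r <- liftover_interval(genomic_interval("chr1", 10, 190), cm, min_match = 0.5)
  expect_equal(c(r$start, r$end), c(10L, 100L))
  expect_equal(r$mapped_fraction, 90 / 180)
  # straddling both blocks: the result spans the query gap
  r2 <- liftover_interval(genomic_interval("chr1", 10, 290), cm, min_match = 0.5)
  expect_equal(c(r2$start, r2$end), c(10L, 290L))
  expect_equal(r2$mapped_fraction, 180 / 280)

  # a second chain covering the same target region makes mapping ambiguous
  ch2 <- ch; ch2$q_start <- 500; ch2$q_end <- 800; ch2$id <- "2"
  cm2 <- structure(list(ch, ch2), class = "chain_map")
  expect_null(liftover_interval(genomic_interval("chr1", 10, 90), cm2,
                                min_match = 0.5))
})

test_that("negative-strand chains reverse coordinates and strand", {
  ch <- list(score = 1, t_name = "chr1", t_size = 1000, t_strand = "+",
             t_start = 100, t_end = 200, q_name = "chrH1", q_size = 1000,
             q_strand = "-", q_start = 300, q_end = 400, id = "1",
             blocks = data.frame(size = 100, dt = 0, dq = 0))
  cm <- structure(list(ch), class = "chain_map")
  r <- liftover_interval(genomic_interval("chr1", 100, 110, "+"), cm)
  # strand-space 300..310 -> plus strand [1000-310, 1000-300)
  expect_equal(c(r$start, r$end), c(690L, 700L))
  expect_equal(r$strand, "-")
  expect_true(same_lift(r, liftover_bruteforce(genomic_interval("chr1", 100, 110, "+"), cm)))
})

test_that("liftover matches the per-base brute-force mapper on random chains", {
  set.seed(33)
  for (rep in 1:25) {
    cm <- structure(lapply(1:6, random_chain), class = "chain_map")
    for (i in 1:8) {
      s <- sample(0:99000, 1)
      w <- sample(1:800, 1)
      iv <- genomic_interval("chrT", s, min(s + w, 100000),
                             sample(c("+", "-", "."), 1))
      expect_true(same_lift(liftover_interval(iv, cm),
                            liftover_bruteforce(iv, cm)))
    }
  }
})

test_that("annotation intersection follows half-open semantics and matches a naive scan", {
  mapped <- data.frame(gene_id = "m1", chrom = "chrH1", start = 100, end = 200)
  annot <- data.frame(gene_id = c("h1", "h2"), chrom = "chrH1",
                      start = c(199, 200), end = c(300, 300))
  hits <- intersect_annotations(mapped, annot)
  expect_equal(hits$annot_id, "h1")  # 1 bp overlap in; adjacency out

  two <- data.frame(gene_id = c("hA", "hB"), chrom = "chrH1",
                    start = c(50, 150), end = c(150, 250))
  expect_equal(nrow(intersect_annotations(mapped, two)), 2)

  set.seed(44)
  for (i in 1:10) {
    q <- data.frame(gene_id = sprintf("q%02d", 1:15),
                    chrom = sample(c("c1", "c2"), 15, replace = TRUE),
                    start = sample(0:500, 15))
    q$end <- q$start + sample(1:100, 15, replace = TRUE)
    a <- data.frame(gene_id = sprintf("a%02d", 1:15),
                    chrom = sample(c("c1", "c2"), 15, replace = TRUE),
                    start = sample(0:500, 15))
    a$end <- a$start + sample(1:100, 15, replace = TRUE)
    got <- intersect_annotations(q, a)
    want <- oracle_intersect(q, a)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("annotation files round-trip through GTF and BED", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chrM1",
                      start = c(1000L, 5000L), end = c(3000L, 7000L),
                      strand = c("+", "-"), biotype = "lncRNA")
  gtf <- withr::local_tempfile(fileext = ".gtf")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(genes, gtf_path = gtf, bed_path = bed)
  expect_equal(read_gene_annotation(gtf), genes)
  got_bed <- read_gene_annotation(bed)
  expect_equal(got_bed[, 1:5], genes[, 1:5])
})

test_that("human expression filter uses strict 'more than' semantics", {
  counts <- rbind(at20 = rep(20L, 4), at21 = rep(21L, 4),
                  zero = rep(0L, 4), high = rep(200L, 4))
  samp <- data.frame(sample_id = paste0("s", 1:4), species = "human",
                     cell_type = c("HSC", "CMP", "GMP", "CLP"), replicate = 1)
  colnames(counts) <- samp$sample_id
  ds <- expression_dataset(counts, samp)
  res <- human_expression_filter(ds, c("at20", "at21", "zero", "absent"))
  expect_equal(res$expressed, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$missing, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$mean_norm[1], 20)
})

test_that("syntelog correlation is exact on identical profiles and separates planted pairs", {
  m <- list(HSC = c(10, 400), CMP = c(40, 100), GMP = c(160, 30),
            CLP = c(640, 10))
  mouse <- make_ds(m, reps = 3, dispersion = NULL)
  human <- make_ds(m, reps = 2, dispersion = NULL, species = "human")
  pairs <- data.frame(mouse_id = c("g001", "g002"),
                      human_id = c("g001", "g002"))
  r <- correlate_syntelogs(mouse, human, pairs)
  expect_equal(r$pearson_r, c(1, 1), tolerance = 1e-12)
  expect_error(correlate_syntelogs(mouse, human, pairs, cell_types = "HSC"),
               "2 distinct")

  x <- generate_expression_dataset(sim_config(seed = 19))
  tr <- x$truth
  prof <- tr[tr$syntenic & is.na(tr$pattern_class) &
               !is.na(tr$human_expressed) & tr$human_expressed, ]
  pr <- correlate_syntelogs(x$mouse, x$human,
                            data.frame(mouse_id = prof$gene_id,
                                       human_id = prof$human_id))
  cons <- pr$pearson_r[prof$conserved]
  nonc <- pr$pearson_r[!prof$conserved]
  expect_gt(mean(cons, na.rm = TRUE) - mean(nonc, na.rm = TRUE), 0.5)
})

test_that("candidate ranking orders by correlation with missing values last", {
  expect_equal(nrow(rank_candidates(data.frame(mouse_id = character(),
                                               pearson_r = numeric()))), 0)
  p <- data.frame(mouse_id = c("m1", "m2", "m3", "m0"),
                  pearson_r = c(0.1, 0.9, NA, 0.9))
  r <- rank_candidates(p)
  expect_equal(r$mouse_id, c("m0", "m2", "m1", "m3"))
  expect_equal(r$rank, 1:4)
})

test_that("pipeline stage counts shrink monotonically", {
  cfg <- sim_config(seed = 23)
  x <- generate_expression_dataset(cfg)
  syn <- generate_synteny_dataset(cfg, truth = x$truth)
  cand <- select_candidates(classify_patterns(x$mouse), x$mouse$genes)
  cand_loci <- syn$mouse_genes[syn$mouse_genes$gene_id %in% cand, ]
  lifted <- list()
  for (i in seq_len(nrow(cand_loci))) {
    g <- cand_loci[i, ]
    r <- liftover_interval(genomic_interval(g$chrom, g$start, g$end, g$strand),
                           syn$chain)
    if (!is.null(r)) {
      lifted[[length(lifted) + 1]] <-
        data.frame(gene_id = g$gene_id, chrom = r$chrom,
                   start = r$start, end = r$end)
    }
  }
  lifted <- do.call(rbind, lifted)
  pairs <- intersect_annotations(lifted, syn$human_genes)
  expr <- human_expression_filter(x$human, pairs$annot_id)
  syntenic_mouse <- unique(pairs$query_id)
  expressed_mouse <- unique(pairs$query_id[expr$expressed])
  expect_gte(length(cand), length(syntenic_mouse))
  expect_gte(length(syntenic_mouse), length(expressed_mouse))
  expect_gt(length(expressed_mouse), 0)
})
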