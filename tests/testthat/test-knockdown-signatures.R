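test_that("knockdown DE detects planted downregulation and stays quiet on nulls", {
  kd <- generate_knockdown_dataset(sim_config(seed = 7))
  de <- knockdown_de(kd$ds, "CMP", c("sh1", "sh2"), "Renilla")
  hits <- de$pooled$gene_id[de$pooled$fdr < 0.05 & de$pooled$log2fc < 0]
  # majority of the planted 2-fold set recovered; parity with DESeq2, the
  # reference engine this test approximates, checked on the same fixture
  n_mine <- sum(kd$truth$down_extra %in% hits)
  expect_gte(n_mine, 25)

  suppressMessages(library(DESeq2))
  sel <- kd$ds$samples$cell_type == "CMP"
  cond <- factor(ifelse(kd$ds$samples$condition[sel] == "Renilla",
                        "ctrl", "kd"), levels = c("ctrl", "kd"))
  dds <- suppressMessages(DESeqDataSetFromMatrix(
    kd$ds$counts[, sel], S4Vectors::DataFrame(cond = cond), ~cond))
  res <- results(suppressMessages(DESeq(dds, quiet = TRUE)))
  ref_hits <- rownames(res)[!is.na(res$padj) & res$padj < 0.05 &
                              res$log2FoldChange < 0]
  expect_gte(n_mine, sum(kd$truth$down_extra %in% ref_hits) - 5)

  # null: no planted effect in LSK beyond the (shared) induction structure
  de_lsk <- knockdown_de(kd$ds, "LSK", c("sh1", "sh2"), "Renilla")
  expect_lte(mean(de_lsk$pooled$fdr < 0.05), 0.02)

  expect_error(knockdown_de(kd$ds, "CMP", c("sh1", "sh2"), "shMissing"),
               "absent")
})

test_that("consistent downregulation intersects pooled significance with per-shRNA direction", {
  pooled <- data.frame(gene_id = c("g1", "g2", "g3"),
                       log2fc = c(-2, -2, 1), pvalue = 0.001,
                       fdr = c(0.01, 0.01, 0.01), contrast = "p")
  sh1 <- pooled; sh1$log2fc <- c(-1, -1, 1)
  sh2 <- pooled; sh2$log2fc <- c(-1, 0.5, 1)  # g2 up in sh2 -> excluded
  expect_equal(consistent_downregulated(pooled, list(sh1, sh2)), "g1")

  empty <- pooled[0, ]
  expect_equal(consistent_downregulated(empty, list(empty, empty)),
               character(0))

  kd <- generate_knockdown_dataset(sim_config(seed = 7))
  de <- knockdown_de(kd$ds, "CMP", c("sh1", "sh2"), "Renilla")
  down <- consistent_downregulated(de$pooled, de$per_sh)
  pooled_down <- de$pooled$gene_id[de$pooled$fdr < 0.05 & de$pooled$log2fc < 0]
  expect_true(all(down %in% pooled_down))
  # shrinking the threshold never grows the set
  strict <- consistent_downregulated(de$pooled, de$per_sh, fdr = 0.01)
  expect_true(all(strict %in% down))
  # planted genes passing pooled FDR are all recovered
  planted_pass <- intersect(kd$truth$down_extra, pooled_down)
  expect_true(all(planted_pass %in% down))
})

test_that("gene-set enrichment matches the shared hypergeometric oracle", {
  sets <- list(s5 = sprintf("u%02d", 1:5), other = sprintf("u%02d", 6:9))
  universe <- sprintf("u%02d", 1:10)
  r <- enrich_gene_sets(sprintf("u%02d", 1:4), sets, universe)
  expect_equal(r$pvalue[r$set == "s5"], 5 / 210)
  expect_equal(r$pvalue[r$set == "s5"],
               oracle_hypergeom(4, 4, 5, 10))
  expect_equal(r$p_bonferroni, pmin(1, r$pvalue * 2))

  disjoint <- enrich_gene_sets("u10", list(s = sprintf("u%02d", 1:5)),
                               universe)
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$p_bonferroni, disjoint$pvalue)  # one set tested
  expect_error(enrich_gene_sets("a", list(s = "a"), character(0)), "universe")
})

test_that("signature fraction reports k/N as a rounded percent", {
  uni <- sprintf("g%04d", 1:5000)
  path <- uni[1:130]
  query <- c(uni[1:43], uni[200:500])
  r <- signature_fraction(query, path, uni)
  expect_equal(r$k, 43)
  expect_equal(r$N, 130)
  expect_equal(r$percent, 33.1)
  expect_equal(signature_fraction(path, path, uni)$percent, 100)
  expect_equal(signature_fraction(uni[300:310], path, uni)$percent, 0)
  expect_error(signature_fraction("x", "y", "z"), "no genes")
})

test_that("induction counting recovers planted LSK-to-CMP upregulation", {
  cfg <- sim_config(seed = 17, oxphos_size = 30, induction_frac = 2 / 3,
                    induction_fold = 3, kd_reps = 5, kd_down_n = 0)
  kd <- generate_knockdown_dataset(cfg)
  ind <- induction_counts(kd$ds, kd$truth$oxphos, "LSK", "CMP", "Renilla")
  expect_equal(ind$n_total, 30)
  expect_gte(ind$n_up_significant, 16)
  expect_lte(ind$n_up_significant, 22)
  expect_gt(ind$mean_log2fc, 0)

  flat <- induction_counts(kd$ds, setdiff(kd$ds$genes$gene_id,
                                          kd$truth$oxphos)[1:20],
                           "LSK", "CMP", "Renilla")
  expect_lte(flat$n_up_significant, 2)
  expect_equal(induction_counts(kd$ds, character(), "LSK", "CMP",
                                "Renilla")$n_total, 0)
  withmiss <- induction_counts(kd$ds, c(kd$truth$oxphos[1], "ghost"),
                               "LSK", "CMP", "Renilla")
  expect_equal(withmiss$untested, "ghost")
  expect_equal(withmiss$n_total, 2)
})

test_that("neighbor effect converts per-shRNA fold changes to mean percent reduction", {
  tab <- function(lfc) data.frame(gene_id = "gN", log2fc = lfc, pvalue = 0.5,
                                  fdr = 0.5, contrast = "c")
  expect_equal(neighbor_effect(list(tab(0), tab(0)), "gN"), 0)
  expect_equal(neighbor_effect(list(tab(-1), tab(-1)), "gN"), 50)
  expect_equal(neighbor_effect(list(tab(-0.234), tab(-0.234)), "gN"),
               100 * (1 - 2^-0.234))
  expect_lt(abs(neighbor_effect(list(tab(-0.234), tab(-0.234)), "gN") - 15),
            1)
  expect_error(neighbor_effect(list(tab(0)), "ghost"), "ghost")
})

test_that("GMT files round-trip", {
  sets <- list(oxphos = c("g1", "g2", "g3"), other = c("g9", "g2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
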