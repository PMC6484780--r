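#!/usr/bin/env Rscript

# Stage 2: lift candidate mouse lncRNA loci onto the human genome through
# the chain file, intersect with the human lncRNA annotation, keep pairs
# whose human partner is expressed (> 20 normalized counts on average), and
# rank by cross-species expression correlation. This is the candidate ->
# syntenic -> expressed -> ranked funnel.

library(crosslinc)

cand <- readLines("results/candidates.txt")
genes <- read_gene_annotation("results/sim/mouse_lnc.gtf")
annot <- read_gene_annotation("results/sim/human_lnc.gtf")
cm <- parse_chain("results/sim/mouse_to_human.chain")
human <- read_expression_dataset("results/sim/human_counts.tsv",
                                 "results/sim/human_samples.csv")
mouse <- read_expression_dataset("results/sim/mouse_counts.tsv",
                                 "results/sim/mouse_samples.csv",
                                 "results/sim/mouse_genes.tsv")

loci <- genes[genes$gene_id %in% cand, ]
lifted <- list()
for (i in seq_len(nrow(loci))) {
  g <- loci[i, ]
  r <- liftover_interval(genomic_interval(g$chrom, g$start, g$end, g$strand),
                         cm, min_match = 0.95)
  if (!is.null(r)) {
    lifted[[length(lifted) + 1]] <-
      data.frame(gene_id = g$gene_id, chrom = r$chrom, start = r$start,
                 end = r$end, mapped_fraction = r$mapped_fraction)
  }
}
lifted <- do.call(rbind, lifted)

pairs <- intersect_annotations(lifted, annot)
names(pairs) <- c("mouse_id", "human_id")
expr <- human_expression_filter(human, pairs$human_id, threshold = 20)
pairs$human_expressed <- expr$expressed
expressed <- pairs[pairs$human_expressed, ]

expressed <- correlate_syntelogs(mouse, human, expressed)
ranked <- rank_candidates(expressed)
write.table(ranked, "results/candidates_ranked.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("funnel: %d candidates -> %d syntenic pairs -> %d expressed -> ranked",
                length(cand), nrow(pairs), nrow(expressed)))
message("top of the ranking:")
print(utils::head(ranked, 5))
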