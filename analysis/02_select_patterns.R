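#!/usr/bin/env Rscript

# Stage 1 of the prioritization: classify mouse lncRNAs into the three
# candidate expression-pattern classes (progenitor-enriched, lineage-
# enriched, downregulated-in-differentiation) and emit the candidate list.

library(crosslinc)

mouse <- read_expression_dataset("results/sim/mouse_counts.tsv",
                                 "results/sim/mouse_samples.csv",
                                 "results/sim/mouse_genes.tsv")
res <- classify_patterns(mouse, pattern_config())
cand <- select_candidates(res, mouse$genes)

write.table(res$calls, "results/pattern_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$support, "results/pattern_support.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(cand, "results/candidates.txt")

truth <- jsonlite::read_json("results/sim/expression_truth.json",
                             simplifyVector = TRUE)
planted <- truth$gene_id[!is.na(truth$pattern_class)]
message(sprintf("labelled genes: %d of %d", sum(res$calls$n_labels > 0),
                nrow(res$calls)))
message(sprintf("lncRNA candidates: %d (planted pattern lncRNAs recovered: %d/%d)",
                length(cand), sum(planted %in% cand), length(planted)))
message(sprintf("per class: progenitor %d | lineage %d | differentiation %d",
                sum(res$calls$progenitor_enriched),
                sum(res$calls$lineage_enriched),
                sum(res$calls$downregulated_in_differentiation)))
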