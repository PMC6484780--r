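#!/usr/bin/env Rscript

# Generate every synthetic input of the study, with planted ground truth,
# and write them to results/sim/ in the interchange formats the pipeline
# reads back (counts TSV + sample sheet CSV, GTF/BED annotations, UCSC
# chain, GMT gene sets, per-animal flow CSVs, qPCR Ct CSVs, truth JSON).

library(crosslinc)

seed <- 1
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = seed)

message("simulating expression data (mouse + human) ...")
expr <- generate_expression_dataset(cfg)
write_expression_dataset(expr$mouse, "results/sim/mouse_counts.tsv",
                         "results/sim/mouse_samples.csv",
                         "results/sim/mouse_genes.tsv")
write_expression_dataset(expr$human, "results/sim/human_counts.tsv",
                         "results/sim/human_samples.csv")
write_truth(expr$truth, "results/sim/expression_truth.json")

message("simulating toy genomes + liftover chain ...")
syn <- generate_synteny_dataset(cfg, truth = expr$truth)
write_gene_annotation(syn$mouse_genes, gtf_path = "results/sim/mouse_lnc.gtf",
                      bed_path = "results/sim/mouse_lnc.bed")
write_gene_annotation(syn$human_genes, gtf_path = "results/sim/human_lnc.gtf",
                      bed_path = "results/sim/human_lnc.bed")
write_chain(syn$chain, "results/sim/mouse_to_human.chain")
write_truth(syn$truth, "results/sim/synteny_truth.json")

message("simulating transplant cohorts + TMRM ...")
tx <- generate_transplant_dataset(cfg)
write.csv(tx$records, "results/sim/animal_records.csv", row.names = FALSE)
write.csv(tx$tmrm, "results/sim/tmrm_events.csv", row.names = FALSE)
write_truth(tx$truth, "results/sim/transplant_truth.json")

message("simulating qPCR / fractionation / smFISH assays ...")
assays <- generate_assay_dataset(cfg)
write.csv(assays$ct, "results/sim/knockdown_ct.csv", row.names = FALSE)
write.csv(assays$fractionation, "results/sim/fractionation_ct.csv",
          row.names = FALSE)
write.csv(assays$dilution, "results/sim/dilution_series.csv",
          row.names = FALSE)
write.csv(assays$smfish, "results/sim/smfish_spots.csv", row.names = FALSE)
write_truth(assays$truth, "results/sim/assay_truth.json")

message("simulating knockdown RNA-seq + gene sets ...")
kd <- generate_knockdown_dataset(cfg)
write_expression_dataset(kd$ds, "results/sim/kd_counts.tsv",
                         "results/sim/kd_samples.csv")
write_gmt(kd$gene_sets, "results/sim/gene_sets.gmt")
write_truth(kd$truth, "results/sim/kd_truth.json")

message("done: inputs under results/sim/")
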