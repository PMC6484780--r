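#!/usr/bin/env Rscript

# Molecular validation of the knockdowns: delta-delta-Ct expression
# relative to the control shRNA (Gapdh-normalized), primer efficiency from
# the dilution series, subcellular fractionation enrichment, and smFISH
# localization fractions.

library(crosslinc)

ct <- read.csv("results/sim/knockdown_ct.csv")
kd <- ddct_expression(ct, target = "lncX", housekeeping = "Gapdh",
                      control_condition = "Renilla")
write.table(kd$per_sample, "results/knockdown_per_line.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("relative expression per condition (control = 1):")
print(kd$per_condition)

dil <- read.csv("results/sim/dilution_series.csv")
eff <- primer_efficiency(dil$log10_dilution, dil$ct)
message(sprintf("primer efficiency: %.3f (slope %.3f, R^2 %.4f)",
                eff$efficiency, eff$slope, eff$r_squared))

fr <- read.csv("results/sim/fractionation_ct.csv")
enr <- do.call(rbind, lapply(split(fr, fr$target), function(d) {
  tot <- d$ct[d$fraction == "total"]
  data.frame(target = d$target[1],
             cytoplasmic = fraction_enrichment(
               d$ct[d$fraction == "cytoplasmic"], tot),
             nuclear = fraction_enrichment(d$ct[d$fraction == "nuclear"], tot))
}))
write.table(enr, "results/fractionation_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("fractionation enrichment (2^-(fraction Ct - total Ct)):")
print(enr)

spots <- read.csv("results/sim/smfish_spots.csv")
loc <- smfish_localization(spots)
message(sprintf("smFISH: mean cytoplasmic fraction %.3f over %d cells (%d excluded)",
                loc$cohort_mean, nrow(loc$per_cell),
                length(loc$excluded_cells)))
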