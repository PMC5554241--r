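#!/usr/bin/env Rscript
# Stage 3: isomiR structure of the cohort.
#
# Per-miRNA isoform diversity, the dominant-isoform offset table, how often
# the canonical form is absent or dominant, and the correlation between
# isoform diversity and expression.

suppressMessages(library(tallmir))

if (!file.exists("scratch/quant.rds")) {
  stop("run analysis/02_quantify.R first (scratch/quant.rds is missing)")
}
q <- readRDS("scratch/quant.rds")

dt <- diversity_table(q$isomir)
readr::write_tsv(dt$summary, "results/isomir_summary.tsv")
readr::write_tsv(dt$histogram, "results/isomir_histogram.tsv")
readr::write_tsv(dominant_isoform_table(q$isomir), "results/dominant_isoforms.tsv")

cf <- canonical_fractions(q$isomir)
readr::write_tsv(cf, "results/canonical_fractions.tsv")
corr <- diversity_expression_correlation(dt$summary)

message(nrow(dt$summary), " miRNAs summarised; ",
        sum(dt$summary$n_isomirs == 1), " carry a single isomiR; max ",
        max(dt$summary$n_isomirs), " isoforms.")
message("Canonical form dominant for ", cf$n_canonical_dominant, "/",
        cf$n_total, " miRNAs, absent for ", cf$n_canonical_absent, "/",
        cf$n_total, ".")
message("Diversity-expression correlation r = ",
        round(corr$r_log, 3), " (log10 scale; raw scale r = ",
        round(corr$r_raw, 3), ").")
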