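#!/usr/bin/env Rscript
# Stage 5: subtype-specific miRNA signatures.
#
# One-vs-rest NB Wald contrasts across the four subgroups, the heatmap row
# selection (most significant per subgroup), and the top-10 highest
# expressed significantly-up miRNAs per subgroup.

suppressMessages(library(tallmir))

if (!file.exists("scratch/normalized.rds")) {
  stop("run analysis/04_filter_normalize.R first (scratch/normalized.rds is missing)")
}
nrm <- readRDS("scratch/normalized.rds")
truth <- readRDS("scratch/truth.rds")
grp <- stats::setNames(truth$sample_sheet$group, truth$sample_sheet$sample_id)

ovr <- one_vs_rest_signatures(nrm$filtered, grp, sf = nrm$sf)
saveRDS(ovr, "scratch/ovr.rds")
readr::write_tsv(ovr$signatures, "results/subtype_signatures.tsv")

sel <- heatmap_selection(ovr, k = 50)
readr::write_tsv(tibble::tibble(rank = seq_along(sel), mirna = sel),
                 "results/heatmap_mirnas.tsv")

top10 <- top_expressed_signature(ovr, nrm$normalized, grp, k = 10)
readr::write_tsv(top10, "results/top10_signatures.tsv")

for (g in names(ovr$tests)) {
  s <- ovr$signatures[ovr$signatures$subgroup == g, ]
  message(g, ": ", sum(s$direction == "up"), " up / ",
          sum(s$direction == "down"), " down at adjusted p < 0.05")
}
message(length(sel), " miRNAs selected for the signature heatmap; top-10 ",
        "tables cover ", length(unique(top10$mirna)), " distinct miRNAs.")
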