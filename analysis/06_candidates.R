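#!/usr/bin/env Rscript
# Stage 6: thymocyte contrasts and candidate classification.
#
# Contrasts the two normal thymocyte subsets (CD34+ vs CD4+CD8+), each
# leukemia subtype against its matched subset (immature vs CD34+, TAL-R vs
# CD4+CD8+), and classifies subtype-specific miRNAs as differentiation
# arrest markers and/or oncomiR / suppressor candidates. Finally runs the
# pooled all-T-ALL vs all-thymocyte contrast.

suppressMessages(library(tallmir))

if (!file.exists("scratch/ovr.rds")) {
  stop("run analysis/05_signatures.R first (scratch/ovr.rds is missing)")
}
nrm <- readRDS("scratch/normalized.rds")
ovr <- readRDS("scratch/ovr.rds")
truth <- readRDS("scratch/truth.rds")
grp <- stats::setNames(truth$sample_sheet$group, truth$sample_sheet$sample_id)

thy_de <- nb_wald_test(nrm$filtered, grp, "CD34", "DP", sf = nrm$sf)
readr::write_tsv(thy_de, "results/thymocyte_de.tsv")
n_thy <- sum(!is.na(thy_de$padj) & thy_de$padj < 0.05)
message(n_thy, " miRNAs differ between CD34+ and CD4+CD8+ thymocytes ",
        "(adjusted p < 0.05).")

svm <- list(
  immature = nb_wald_test(nrm$filtered, grp, "immature", "CD34", sf = nrm$sf),
  `TAL-R` = nb_wald_test(nrm$filtered, grp, "TAL-R", "DP", sf = nrm$sf))
readr::write_tsv(svm$immature, "results/immature_vs_cd34_de.tsv")
readr::write_tsv(svm$`TAL-R`, "results/talr_vs_dp_de.tsv")

top10 <- top_expressed_signature(ovr, nrm$normalized, grp, k = 10)
calls <- classify_candidates(top10[, c("mirna", "subgroup")], thy_de, svm)
readr::write_tsv(calls, "results/candidate_calls.tsv")
message("Candidate calls over ", nrow(calls), " subtype-specific miRNAs: ",
        sum(calls$arrest_marker), " arrest markers, ",
        sum(calls$onco_candidate), " oncomiR candidates, ",
        sum(calls$suppressor_candidate), " suppressor candidates (",
        sum(calls$arrest_marker & calls$onco_candidate),
        " carry both arrest and oncomiR flags).")

glob <- global_tall_contrast(nrm$filtered, grp, sf = nrm$sf)
readr::write_tsv(glob$de, "results/global_tall_contrast.tsv")
message("Pooled T-ALL vs thymus: ", length(glob$up), " up / ",
        length(glob$down), " down at adjusted p < 0.05.")
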