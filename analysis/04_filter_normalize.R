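#!/usr/bin/env Rscript
# Stage 4: background filtering, normalization and sample structure.
#
# Applies the background rule (>= 4 reads in >= ceil(60%) of one subgroup,
# or in all samples of one thymocyte subset), computes median-of-ratios
# size factors, log2-normalizes, and projects the patient samples onto
# principal components.

suppressMessages(library(tallmir))

if (!file.exists("scratch/quant.rds")) {
  stop("run analysis/02_quantify.R first (scratch/quant.rds is missing)")
}
q <- readRDS("scratch/quant.rds")
truth <- readRDS("scratch/truth.rds")
grp <- stats::setNames(truth$sample_sheet$group, truth$sample_sheet$sample_id)

f <- background_filter(q$mirna, grp)
readr::write_tsv(attr(f, "report"), "results/filter_report.tsv")

sf <- size_factors(round(f))
readr::write_tsv(tibble::tibble(sample_id = names(sf), size_factor = c(sf)),
                 "results/size_factors.tsv")
nm <- normalize_counts(f, sf)
saveRDS(list(filtered = f, sf = sf, normalized = nm), "scratch/normalized.rds")

subgroups <- c("immature", "TLX", "TAL-R", "HOXA")
patients <- names(grp)[grp %in% subgroups]
p <- pca_samples(nm[, patients])
coords <- tibble::as_tibble(p$scores[, 1:4], rownames = "sample_id")
coords$group <- grp[coords$sample_id]
readr::write_tsv(coords, "results/pca_coordinates.tsv")

message(nrow(f), " of ", nrow(q$mirna), " miRNAs pass the background filter.")
message("PC1/PC2 explain ",
        paste(round(100 * p$explained_variance[1:2], 1), collapse = "% / "),
        "% of patient-sample variance.")
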