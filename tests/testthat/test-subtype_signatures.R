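# shared simulated cohort with strong planted subtype effects
signature_cohort <- function() {
  cfg <- sim_config(seed = 111, n_mirnas = 120,
                    groups = c(immature = 6, TLX = 6, `TAL-R` = 6, HOXA = 4,
                               CD34 = 2, DP = 2),
                    reads_per_sample = 3e4, de_fraction = 0)
  ann <- simulate_annotation(cfg)
  prof <- simulate_isomir_profiles(cfg, ann)
  top <- order(-prof$baseline$base_mean)[1:12]
  cfg$effects <- tibble::tibble(
    mirna = prof$baseline$mirna[top],
    group = rep(c("immature", "TLX", "TAL-R", "HOXA"), each = 3),
    log2fc = 3)
  truth <- simulate_counts(cfg, prof)
  grp <- stats::setNames(truth$sample_sheet$group, truth$sample_sheet$sample_id)
  f <- background_filter(truth$mirna_counts, grp)
  list(truth = truth, groups = grp, mat = f,
       sf = size_factors(round(f)), effects = cfg$effects)
}

cohort <- signature_cohort()

test_that("one-vs-rest signatures recover planted subtype-specific miRNAs", {
  ovr <- one_vs_rest_signatures(cohort$mat, cohort$groups, sf = cohort$sf)
  sig <- ovr$signatures
  for (g in unique(cohort$effects$group)) {
    planted <- intersect(cohort$effects$mirna[cohort$effects$group == g],
                         rownames(cohort$mat))
    up_g <- sig$mirna[sig$subgroup == g & sig$direction == "up"]
    expect_true(all(planted %in% up_g))
    # a miRNA planted only in g must not be up-significant elsewhere
    other_up <- sig$mirna[sig$subgroup != g & sig$direction == "up"]
    expect_false(any(planted %in% other_up))
  }
  # every signature entry passed the background filter
  expect_true(all(sig$mirna %in% rownames(cohort$mat)))
  expect_error(one_vs_rest_signatures(cohort$mat, cohort$groups,
                                      subgroups = c("immature", "CD34")),
               NA)
  relabelled <- replace(cohort$groups, cohort$groups == "immature", "HOXA")
  expect_error(one_vs_rest_signatures(cohort$mat, relabelled,
                                      subgroups = c("immature", "TLX")),
               "fewer than 2")
})

test_that("heatmap selection caps, deduplicates and breaks ties deterministically", {
  ovr <- one_vs_rest_signatures(cohort$mat, cohort$groups, sf = cohort$sf)
  pick_all <- heatmap_selection(ovr, k = 50)
  expect_lte(length(pick_all), 50 * 4)
  expect_false(any(duplicated(pick_all)))
  pick_small <- heatmap_selection(ovr, k = 2)
  expect_lte(length(pick_small), 2 * 4)
  n_sig <- length(unique(ovr$signatures$mirna))
  expect_equal(length(pick_all), n_sig)  # k larger than the significant set
  # tie in adjusted p broken by |log2FC| descending, then name
  fake <- list(tests = list(g = tibble::tibble(
    mirna = c("mA", "mB", "mC"),
    log2_fold_change = c(1, -3, 2),
    padj = c(0.01, 0.01, 0.01))))
  expect_equal(heatmap_selection(fake, k = 3), c("mB", "mC", "mA"))
})

test_that("top-expressed signature ranks by within-subgroup expression", {
  ovr <- one_vs_rest_signatures(cohort$mat, cohort$groups, sf = cohort$sf)
  nm <- normalize_counts(cohort$mat, cohort$sf)
  top <- top_expressed_signature(ovr, nm, cohort$groups, k = 10)
  for (g in unique(top$subgroup)) {
    tg <- top[top$subgroup == g, ]
    expect_true(all(diff(tg$mean_expression) <= 1e-12))
    expect_equal(tg$rank, seq_len(nrow(tg)))
    # only up-significant miRNAs may enter, however highly expressed others are
    up_g <- ovr$signatures$mirna[ovr$signatures$subgroup == g &
                                   ovr$signatures$direction == "up"]
    expect_true(all(tg$mirna %in% up_g))
  }
  # the overall highest-expressed miRNA is excluded when not significant
  overall <- names(sort(rowMeans(nm), decreasing = TRUE))
  not_sig <- setdiff(overall, ovr$signatures$mirna)[1]
  expect_false(not_sig %in% top$mirna)
})

test_that("signature evaluation reports within-sample percentiles", {
  v <- stats::setNames(c(1, 5, 9, 2, 7), paste0("m", 1:5))
  out <- evaluate_signature_in_sample(c("m3", "m1"), v)
  expect_equal(out$percentiles$percentile[out$percentiles$mirna == "m3"], 100)
  expect_equal(out$percentiles$percentile[out$percentiles$mirna == "m1"], 20)
  expect_equal(out$median_percentile, 60)
  expect_warning(res <- evaluate_signature_in_sample(c("zz"), v), "no signature miRNA")
  expect_true(is.na(res$median_percentile))
})

test_that("a matched simulated sample scores its own subtype's signature higher", {
  ovr <- one_vs_rest_signatures(cohort$mat, cohort$groups, sf = cohort$sf)
  nm <- normalize_counts(cohort$mat, cohort$sf)
  top <- top_expressed_signature(ovr, nm, cohort$groups, k = 10)
  own <- top$mirna[top$subgroup == "immature"]
  other <- top$mirna[top$subgroup == "TAL-R"]
  samp <- nm[, which(cohort$groups == "immature")[1]]
  s_own <- evaluate_signature_in_sample(own, samp)$median_percentile
  s_other <- evaluate_signature_in_sample(other, samp)$median_percentile
  expect_gt(s_own, s_other)
})

test_that("candidate classification derives flags purely from the DE tables", {
  de_thy <- tibble::tibble(
    mirna = c("m1", "m2", "m3", "m4"),
    log2_fold_change = c(2, 0.1, -1.5, 1.8),
    padj = c(0.001, 0.9, 0.01, 0.002))
  de_imm <- tibble::tibble(
    mirna = c("m1", "m2", "m3", "m4"),
    log2_fold_change = c(1.7, 2.2, 0.05, -2.0),
    padj = c(0.003, 0.01, 0.8, 0.001))
  sig <- tibble::tibble(mirna = c("m1", "m2", "m3", "m4"),
                        subgroup = "immature")
  out <- classify_candidates(sig, de_thy, list(immature = de_imm))
  # m1: up in CD34 and further up in leukemia -> both flags
  expect_true(out$arrest_marker[out$mirna == "m1"])
  expect_true(out$onco_candidate[out$mirna == "m1"])
  # m2: only up vs matched subset -> oncomiR candidate only
  expect_false(out$arrest_marker[out$mirna == "m2"])
  expect_true(out$onco_candidate[out$mirna == "m2"])
  # m3: up in DP, not immature-relevant -> no flags for an immature miRNA
  expect_false(any(unlist(out[out$mirna == "m3",
                              c("arrest_marker", "onco_candidate",
                                "suppressor_candidate")])))
  # m4: down in subtype vs matched subset -> suppressor candidate
  expect_true(out$suppressor_candidate[out$mirna == "m4"])
  expect_false(out$onco_candidate[out$mirna == "m4"])
  # permuting DE table rows changes nothing
  out2 <- classify_candidates(sig, de_thy[c(3, 1, 4, 2), ],
                              list(immature = de_imm[c(4, 2, 3, 1), ]))
  expect_equal(out, out2)
  # a TAL-R miRNA needs the DP-side orientation
  sig_tal <- tibble::tibble(mirna = "m3", subgroup = "TAL-R")
  out3 <- classify_candidates(sig_tal, de_thy, list(`TAL-R` = de_imm))
  expect_true(out3$arrest_marker)  # m3 is higher in DP (lfc < 0 in CD34-vs-DP)
  expect_error(classify_candidates(sig_tal, de_thy, list(immature = de_imm)),
               "missing subtype-vs-matched")
})

test_that("the global leukemia-vs-thymocyte contrast partitions disjointly", {
  res <- global_tall_contrast(cohort$mat, cohort$groups, sf = cohort$sf)
  expect_equal(length(intersect(res$up, res$down)), 0L)
  expect_true(all(c(res$up, res$down) %in% res$de$mirna))
  hit <- !is.na(res$de$padj) & res$de$padj < 0.05
  expect_equal(sort(c(res$up, res$down)), sort(res$de$mirna[hit]))
})
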