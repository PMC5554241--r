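test_that("background filter implements the subgroup and subset clauses", {
  spec <- filter_spec(subgroups = c("g1", "g2"), thymocyte_subsets = "t1")
  groups <- c(rep("g1", 5), rep("g2", 3), rep("t1", 2))
  mk <- function(row) matrix(row, 1, 10,
                             dimnames = list("m", paste0("s", 1:10)))
  # 3 of 5 qualifying samples meets ceil(0.6 * 5) = 3
  expect_equal(nrow(background_filter(mk(c(4, 4, 4, 0, 0, 0, 0, 0, 0, 0)),
                                      groups, spec)), 1L)
  # counts of 3 everywhere never qualify
  expect_equal(nrow(background_filter(mk(rep(3, 10)), groups, spec)), 0L)
  # all samples of a thymocyte subset qualify on their own
  expect_equal(nrow(background_filter(mk(c(rep(0, 8), 4, 4)), groups, spec)), 1L)
  # one subset sample below threshold is not enough
  expect_equal(nrow(background_filter(mk(c(rep(0, 8), 4, 3)), groups, spec)), 0L)
  expect_error(background_filter(mk(rep(4, 10)), c(groups[-1], "mystery"), spec),
               "unknown group label")
})

test_that("the background filter is monotone in added reads", {
  set.seed(19)
  spec <- filter_spec(subgroups = c("g1", "g2"), thymocyte_subsets = "t1")
  groups <- c(rep("g1", 4), rep("g2", 6), "t1", "t1")
  for (rep_i in 1:20) {
    m <- matrix(rpois(10 * 12, 3), 10, 12,
                dimnames = list(paste0("m", 1:10), paste0("s", 1:12)))
    kept1 <- rownames(background_filter(m, groups, spec))
    bump <- m
    cells <- sample(length(m), 8)
    bump[cells] <- bump[cells] + sample(1:5, 8, replace = TRUE)
    kept2 <- rownames(background_filter(bump, groups, spec))
    expect_true(all(kept1 %in% kept2))
  }
})

test_that("size factors recover known column scalings", {
  m <- matrix(rpois(40, 50) + 1, 10, 4,
              dimnames = list(paste0("m", 1:10), paste0("s", 1:4)))
  same <- cbind(m[, 1], m[, 1], m[, 1], m[, 1])
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(c(size_factors(same))), rep(1, 4))
  two <- cbind(s1 = m[, 1], s2 = 2 * m[, 1])
  sf <- c(size_factors(two))
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # scaling any column by c multiplies its factor by c (after the common
  # geometric-mean rescaling, ratios to other columns scale by c)
  sf0 <- size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 5
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[3] / sf2[1]), unname(5 * sf0[3] / sf0[1]),
               tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  set.seed(23)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 5) + 1, 200, 6,
              dimnames = list(paste0("m", 1:200), paste0("s", 1:6)))
  m[, 2] <- m[, 2] * 3
  ours <- c(size_factors(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]), tolerance = 1e-10)
})

test_that("no all-nonzero reference miRNA raises an actionable error", {
  m <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(m), "min_nonzero_prop = 0.9")
})

test_that("normalization applies log2(count/s + 1)", {
  m <- matrix(c(0, 3, 7, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  sf <- c(s1 = 1, s2 = 2)
  n <- normalize_counts(m, sf)
  expect_equal(n["a", "s1"], 0)
  expect_equal(n["b", "s1"], 2)
  expect_equal(n["a", "s2"], log2(4.5))
  # common column scaling leaves the size factors unchanged (they are
  # constrained to geometric mean 1) and normalization stays monotone in
  # counts within a sample
  m2 <- matrix(rpois(40, 60) + 1, 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(c(size_factors(3 * m2)), c(size_factors(m2)))
  n2 <- normalize_counts(m2, size_factors(m2))
  for (j in 1:4) expect_equal(order(n2[, j]), order(m2[, j]))
})

test_that("sample PCA is orthonormal with non-increasing explained variance", {
  set.seed(29)
  m <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("s", 1:8)))
  m[, 5:8] <- m[, 5:8] + 3
  p <- pca_samples(m)
  expect_false(p$degenerate)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), 1)
  rot <- crossprod(p$scores)
  expect_equal(rot[upper.tri(rot)], rep(0, sum(upper.tri(rot))), tolerance = 1e-8)
  # identical samples project to identical coordinates
  m2 <- cbind(m, s9 = m[, 1])
  p2 <- pca_samples(m2)
  expect_equal(p2$scores["s1", ], p2$scores["s9", ], tolerance = 1e-8)
  # degenerate input is reported, not crashed on
  flat <- matrix(1, 5, 4, dimnames = list(NULL, paste0("s", 1:4)))
  expect_true(pca_samples(flat)$degenerate)
})

test_that("samples separate by subgroup in PCA under strong planted effects", {
  cfg <- sim_config(seed = 101, n_mirnas = 150, groups = c(A = 8, B = 8),
                    reads_per_sample = 3e4, de_fraction = 0.2, de_log2fc = 3,
                    de_groups = "B")
  truth <- simulate_counts(cfg, simulate_isomir_profiles(cfg, simulate_annotation(cfg)))
  grp <- stats::setNames(truth$sample_sheet$group, truth$sample_sheet$sample_id)
  spec <- filter_spec(subgroups = c("A", "B"), thymocyte_subsets = character())
  f <- background_filter(truth$mirna_counts, grp, spec)
  nm <- normalize_counts(f, size_factors(round(f)))
  p <- pca_samples(nm)
  sil <- silhouette_mean(p$scores[, 1:2], grp[rownames(p$scores)])
  expect_gt(sil, 0)
})

test_that("the NB Wald fit matches an independent GLM at fixed dispersion", {
  set.seed(31)
  n1 <- 8; n2 <- 9
  x <- c(rep(1, n1), rep(0, n2))
  sf <- exp(rnorm(n1 + n2, 0, 0.2))
  sf <- sf / exp(mean(log(sf)))
  mat <- t(sapply(1:40, function(i) {
    mu <- exp(rnorm(1, 4, 1))
    fc <- sample(c(1, 4), 1)
    rnbinom(n1 + n2, mu = sf * mu * ifelse(x == 1, fc, 1), size = 5)
  }))
  rownames(mat) <- paste0("m", 1:40)
  colnames(mat) <- paste0("s", 1:(n1 + n2))
  groups <- ifelse(x == 1, "A", "B")
  res <- nb_wald_test(mat, groups, "A", "B", sf = sf)
  ok <- which(res$status == "ok")
  expect_gt(length(ok), 30)
  for (i in sample(ok, 10)) {
    y <- mat[i, ]
    theta <- 1 / res$dispersion[i]
    fit <- suppressWarnings(
      stats::glm(y ~ x + offset(log(sf)),
                 family = MASS::negative.binomial(theta = theta)))
    expect_equal(res$log2_fold_change[i], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-4)
    # dispersion fixed at 1: the Wald SE comes straight from the Fisher
    # information at the given theta
    se <- summary(fit, dispersion = 1)$coefficients["x", "Std. Error"]
    expect_equal(res$lfc_se[i], unname(se) / log(2), tolerance = 0.005)
  }
})

test_that("identical groups give null fold-changes and all-zero rows a status", {
  m <- matrix(rep(c(5, 9, 14, 0), each = 6), 4, 6, byrow = TRUE,
              dimnames = list(paste0("m", 1:4), paste0("s", 1:6)))
  res <- nb_wald_test(m, rep(c("A", "B"), 3), "A", "B")
  expect_equal(res$log2_fold_change[1:3], rep(0, 3), tolerance = 1e-6)
  expect_true(all(res$pvalue[1:3] > 0.95))
  expect_equal(res$status[4], "all_zero")
  expect_true(is.na(res$padj[4]))
  # adjusted p never drops below raw p and is monotone in p rank
  ok <- res$status == "ok"
  expect_true(all(res$padj[ok] >= res$pvalue[ok]))
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # sorted p * n / rank = (0.02, 0.04, 0.04, 0.9); cumulative minima from
  # the largest rank keep each value here
  expect_equal(bh_adjust(c(0.005, 0.02, 0.03, 0.9)), c(0.02, 0.04, 0.04, 0.9))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
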