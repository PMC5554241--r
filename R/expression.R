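# Background filtering, median-of-ratios normalization, PCA, and a
# negative-binomial Wald test for two-group contrasts with BH adjustment.

#' Background filter specification
#'
#' Retention rule: a miRNA is kept iff it has at least `min_reads` reads in
#' at least ceiling(`min_fraction` x group size) samples of one patient
#' subgroup, or at least `min_reads` reads in every sample of one thymocyte
#' subset.
#'
#' @param min_reads Minimum read count (default 4).
#' @param min_fraction Minimum fraction of subgroup samples (default 0.6,
#'   applied with ceiling).
#' @param subgroups Patient subgroup labels.
#' @param thymocyte_subsets Thymocyte subset labels (all-samples rule).
#' @param ignore_groups Labels present in the sample sheet that take part in
#'   neither rule (e.g. cell lines).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_reads = 4L, min_fraction = 0.6,
                        subgroups = c("immature", "TLX", "TAL-R", "HOXA"),
                        thymocyte_subsets = c("CD34", "DP"),
                        ignore_groups = character()) {
  stopifnot(min_reads >= 1L, min_fraction > 0, min_fraction <= 1)
  structure(list(min_reads = as.integer(min_reads),
                 min_fraction = min_fraction,
                 subgroups = subgroups,
                 thymocyte_subsets = thymocyte_subsets,
                 ignore_groups = ignore_groups),
            class = "filter_spec")
}

#' Apply the background filter to a miRNA count matrix
#'
#' Fractional counts are rounded half-to-even before comparison against the
#' read threshold.
#'
#' @param mat miRNA x sample count matrix.
#' @param groups Character vector of group labels, one per column (or named
#'   by sample id).
#' @param spec A [filter_spec()].
#' @return The retained-row submatrix, with a `report` attribute: a tibble
#'   of `mirna`, `retained`, `by_subgroup`, `by_subset`.
#' @export
background_filter <- function(mat, groups, spec = filter_spec()) {
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  stopifnot(length(groups) == ncol(mat))
  known <- c(spec$subgroups, spec$thymocyte_subsets, spec$ignore_groups)
  if (!all(groups %in% known)) {
    stop("unknown group label(s): ", paste(setdiff(groups, known), collapse = ", "))
  }
  cnt <- round(mat)
  hit <- cnt >= spec$min_reads
  by_subgroup <- rep(FALSE, nrow(mat))
  for (g in spec$subgroups) {
    idx <- which(groups == g)
    if (!length(idx)) next
    need <- ceiling(spec$min_fraction * length(idx))
    by_subgroup <- by_subgroup |
      (rowSums(hit[, idx, drop = FALSE]) >= need)
  }
  by_subset <- rep(FALSE, nrow(mat))
  for (g in spec$thymocyte_subsets) {
    idx <- which(groups == g)
    if (!length(idx)) next
    by_subset <- by_subset |
      (rowSums(hit[, idx, drop = FALSE]) == length(idx))
  }
  retained <- by_subgroup | by_subset
  out <- mat[retained, , drop = FALSE]
  attr(out, "report") <- tibble::tibble(
    mirna = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    retained = retained, by_subgroup = by_subgroup, by_subset = by_subset)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-of-ratios size factors
#'
#' Per-sample factor: median, over miRNAs with nonzero counts in at least
#' `min_nonzero_prop` of samples, of the ratio of the sample's count to the
#' miRNA's geometric mean across samples; factors are rescaled to geometric
#' mean 1.
#'
#' @param mat miRNA x sample count matrix.
#' @param min_nonzero_prop Proportion of samples in which a miRNA must be
#'   nonzero to enter the reference set (default 1, i.e. all samples).
#' @return Named numeric vector of size factors with attribute `ref`
#'   (the per-miRNA geometric means used).
#' @export
size_factors <- function(mat, min_nonzero_prop = 1) {
  stopifnot(ncol(mat) >= 1L)
  use <- rowMeans(mat > 0) >= min_nonzero_prop
  if (!any(use)) {
    stop("no miRNA is nonzero in at least ", round(100 * min_nonzero_prop),
         "% of samples; rerun with min_nonzero_prop = 0.9")
  }
  sub <- mat[use, , drop = FALSE]
  loggeo <- rowMeans(log(sub))
  finite <- is.finite(loggeo)
  if (!any(finite)) {
    stop("no usable reference miRNAs; rerun with min_nonzero_prop = 0.9")
  }
  logratios <- log(sub[finite, , drop = FALSE]) - loggeo[finite]
  s <- exp(apply(logratios, 2L, stats::median, na.rm = TRUE))
  s <- s / exp(mean(log(s)))
  if (any(!is.finite(s) | s <= 0)) stop("non-positive size factor computed")
  structure(s, ref = exp(loggeo[finite]), names = colnames(mat))
}

#' Normalize counts to the log2 scale
#'
#' @param mat miRNA x sample count matrix.
#' @param sf Size factors from [size_factors()].
#' @return Matrix of `log2(count / s + 1)` values.
#' @export
normalize_counts <- function(mat, sf) {
  stopifnot(length(sf) == ncol(mat))
  log2(sweep(mat, 2L, sf, "/") + 1)
}

#' Sample-space principal component analysis
#'
#' Rows (miRNAs) are centered; samples are projected onto orthonormal
#' components with non-increasing explained variance.
#'
#' @param normmat Normalized expression matrix (miRNA x sample).
#' @param rows Optional row subset (names or indices).
#' @return List with `scores` (sample x PC matrix), `explained_variance`
#'   (proportions), `sdev`, and `degenerate` (`TRUE` when the matrix has no
#'   variance).
#' @export
pca_samples <- function(normmat, rows = NULL) {
  if (!is.null(rows)) normmat <- normmat[rows, , drop = FALSE]
  stopifnot(nrow(normmat) >= 2L, ncol(normmat) >= 2L)
  x <- t(normmat)
  if (all(apply(x, 2L, stats::var) == 0)) {
    return(list(scores = matrix(0, nrow(x), 0L), explained_variance = numeric(),
                sdev = numeric(), degenerate = TRUE))
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = p$x,
       explained_variance = p$sdev^2 / sum(p$sdev^2),
       sdev = p$sdev, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA`s preserved).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# method-of-moments dispersion on normalized counts, pooled within groups:
# Var(y/s) = mu/s + alpha mu^2 per group
mom_dispersion <- function(y, s, x) {
  num <- 0; den <- 0
  for (g in unique(x)) {
    j <- x == g
    n <- sum(j)
    if (n < 2L) next
    q <- y[j] / s[j]
    m <- mean(q)
    v <- stats::var(q)
    num <- num + (n - 1) * (v - m * mean(1 / s[j]))
    den <- den + (n - 1) * m^2
  }
  if (den <= 0) return(0)
  num / den
}

# IRLS fit of NB log-link model mu_j = s_j exp(b0 + b1 x_j) at fixed alpha
nb_irls <- function(y, s, x, alpha, tol = 1e-8, max_iter = 100L) {
  X <- cbind(1, x)
  o <- log(s)
  m1 <- mean(y[x == 1] / s[x == 1]); m0 <- mean(y[x == 0] / s[x == 0])
  b <- c(log(m0 + 0.5), log(m1 + 0.5) - log(m0 + 0.5))
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(o + X %*% b, -30), 30)
    mu <- exp(eta)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- (eta - o) + (y - mu) / mu
    XtWX <- crossprod(X, w * X)
    if (!is.finite(determinant(XtWX)$modulus) || abs(det(XtWX)) < 1e-12) break
    bnew <- solve(XtWX, crossprod(X, w * z))
    delta <- max(abs(bnew - b))
    b <- as.vector(bnew)
    if (!all(is.finite(b))) break
    if (delta < tol) { converged <- TRUE; break }
  }
  se <- if (!is.null(XtWX) && all(is.finite(XtWX))) {
    v <- tryCatch(solve(XtWX)[2L, 2L], error = function(e) NA_real_)
    if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  } else NA_real_
  list(beta = b, se = se, converged = converged && is.finite(se) && abs(b[2L]) < 50)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Per miRNA: gene-wise dispersion by method of moments on size-factor
#' normalized counts pooled within groups (floored at `alpha_floor`); an NB
#' log-link model `mu_ij = s_j exp(b0 + b x_j)` fitted by iteratively
#' reweighted least squares; Wald z = b / SE(b) against the normal
#' reference; BH-adjusted p-values over the tested rows. Fold-changes are
#' reported in log2 units, positive when expression is higher in `group_a`.
#' Fractional counts are rounded half-to-even before fitting.
#'
#' @param mat miRNA x sample count matrix.
#' @param groups Group labels per column (or named by sample id).
#' @param group_a,group_b Labels (or character vectors of labels) defining
#'   the contrast; `group_a` is the numerator.
#' @param sf Size factors for the used columns; computed from the submatrix
#'   when `NULL`.
#' @param alpha_floor Dispersion floor (default 1e-8).
#' @return Tibble with `mirna`, `base_mean`, `log2_fold_change`, `lfc_se`,
#'   `dispersion`, `stat`, `pvalue`, `padj`, `status` (`"ok"`,
#'   `"all_zero"` or `"non_converged"`).
#' @export
nb_wald_test <- function(mat, groups, group_a, group_b, sf = NULL,
                         alpha_floor = 1e-8) {
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  stopifnot(length(groups) == ncol(mat))
  ja <- groups %in% group_a
  jb <- groups %in% group_b
  if (sum(ja) < 2L || sum(jb) < 2L) stop("need at least 2 samples per group")
  use <- ja | jb
  sub <- round(mat[, use, drop = FALSE])
  x <- as.integer(ja[use])
  if (is.null(sf)) {
    sf <- size_factors(sub)
  } else {
    if (!is.null(names(sf))) sf <- sf[colnames(mat)[use]]
    stopifnot(length(sf) == sum(use))
  }
  n <- nrow(sub)
  mirna <- rownames(sub) %||% as.character(seq_len(n))
  base_mean <- numeric(n); lfc <- rep(NA_real_, n); se <- rep(NA_real_, n)
  disp <- rep(NA_real_, n); stat <- rep(NA_real_, n); pval <- rep(NA_real_, n)
  status <- rep("ok", n)
  for (i in seq_len(n)) {
    y <- sub[i, ]
    base_mean[i] <- mean(y / sf)
    if (all(y == 0)) { status[i] <- "all_zero"; next }
    a <- max(mom_dispersion(y, sf, x), alpha_floor)
    disp[i] <- a
    fit <- nb_irls(y, sf, x, a)
    if (!fit$converged) { status[i] <- "non_converged"; pval[i] <- 1; next }
    lfc[i] <- fit$beta[2L] / log(2)
    se[i] <- fit$se / log(2)
    stat[i] <- fit$beta[2L] / fit$se
    pval[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  padj <- rep(NA_real_, n)
  tested <- status != "all_zero"
  padj[tested] <- bh_adjust(pval[tested])
  tibble::tibble(mirna = mirna, base_mean = base_mean,
                 log2_fold_change = lfc, lfc_se = se, dispersion = disp,
                 stat = stat, pvalue = pval, padj = padj, status = status)
}
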