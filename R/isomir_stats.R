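# Per-miRNA isomiR summaries: diversity, dominant isoforms, canonical
# fractions, and the diversity-expression correlation.

# modal isomiR row per miRNA; tie-break: smaller |d5|+|d3|, canonical
# first, then lexicographic (d5, d3, nta)
modal_key_rows <- function(im, totals) {
  key <- im$key
  ord <- order(key$mirna, -totals, abs(key$d5) + abs(key$d3),
               !(key$d5 == 0L & key$d3 == 0L & key$nta == ""),
               key$d5, key$d3, key$nta)
  sel <- ord[!duplicated(key$mirna[ord])]
  stats::setNames(sel, key$mirna[sel])
}

#' IsomiR diversity summary per miRNA
#'
#' Summarises, over a chosen sample subset, the number of distinct expressed
#' isomiRs per miRNA, its mean normalized miRNA-level expression, its
#' dominant (modal) isoform, and whether the canonical form is expressed /
#' dominant. IsomiRs with zero total count over the subset are excluded;
#' miRNAs with no expressed isomiR are dropped.
#'
#' @param im An `isomir_matrix`.
#' @param samples Character vector of sample ids (default: all columns).
#' @param size_factors Optional per-sample normalization factors; if `NULL`,
#'   median-of-ratios factors are attempted on the miRNA-level matrix, with
#'   total-count scaling as fallback.
#' @return A list with `summary` (tibble: `mirna`, `n_isomirs`,
#'   `mean_expression`, `dominant_d5`, `dominant_d3`, `dominant_nta`,
#'   `canonical_expressed`, `canonical_dominant`) and `histogram` (tibble of
#'   `n_isomirs` bins 1..10 and ">10" with miRNA counts).
#' @export
diversity_table <- function(im, samples = NULL, size_factors = NULL) {
  if (is.null(samples)) samples <- colnames(im$counts)
  if (!length(samples)) stop("empty sample subset")
  if (!all(samples %in% colnames(im$counts))) stop("unknown sample id(s)")
  counts <- im$counts[, samples, drop = FALSE]
  totals <- rowSums(counts)
  keep <- totals > 0
  if (!any(keep)) stop("no expressed isomiRs in the chosen samples")
  sub <- isomir_matrix(im$key[keep, , drop = FALSE],
                       counts[keep, , drop = FALSE])
  totals <- totals[keep]
  mir_mat <- aggregate_mirna(sub)
  if (is.null(size_factors)) {
    size_factors <- tryCatch(size_factors(mir_mat), error = function(e) {
      cs <- colSums(mir_mat)
      cs / exp(mean(log(cs)))
    })
  }
  norm_mean <- rowMeans(sweep(mir_mat, 2L, size_factors, "/"))
  key <- sub$key
  n_isomirs <- as.integer(table(key$mirna)[rownames(mir_mat)])
  modal <- modal_key_rows(sub, totals)
  modal <- modal[rownames(mir_mat)]
  canon <- key$d5 == 0L & key$d3 == 0L & key$nta == ""
  canon_expr <- rownames(mir_mat) %in% key$mirna[canon]
  summary <- tibble::tibble(
    mirna = rownames(mir_mat),
    n_isomirs = n_isomirs,
    mean_expression = unname(norm_mean),
    dominant_d5 = key$d5[modal],
    dominant_d3 = key$d3[modal],
    dominant_nta = key$nta[modal],
    canonical_expressed = canon_expr,
    canonical_dominant = canon[modal])
  bin <- ifelse(summary$n_isomirs > 10L, ">10", as.character(summary$n_isomirs))
  levels <- c(as.character(1:10), ">10")
  histogram <- tibble::tibble(
    n_isomirs = factor(levels, levels = levels),
    n_mirnas = as.integer(table(factor(bin, levels = levels))))
  list(summary = summary, histogram = histogram)
}

#' Dominant-isoform table over (d5, d3) offsets
#'
#' For each miRNA the modal isomiR by summed count is found (ties broken
#' toward smaller |d5| + |d3|, canonical first, then lexicographically); the
#' result counts how many miRNAs have each (d5, d3) offset pair as their
#' dominant form.
#'
#' @param im An `isomir_matrix`.
#' @param samples Sample subset (default all).
#' @return Tibble with `d5`, `d3`, `n_mirnas`, sorted by `n_mirnas`
#'   descending; counts sum to the number of summarized miRNAs.
#' @export
dominant_isoform_table <- function(im, samples = NULL) {
  if (is.null(samples)) samples <- colnames(im$counts)
  counts <- im$counts[, samples, drop = FALSE]
  totals <- rowSums(counts)
  keep <- totals > 0
  if (!any(keep)) stop("no expressed isomiRs")
  sub <- isomir_matrix(im$key[keep, , drop = FALSE], counts[keep, , drop = FALSE])
  modal <- modal_key_rows(sub, totals[keep])
  key <- sub$key[modal, c("d5", "d3")]
  out <- dplyr::count(key, .data$d5, .data$d3, name = "n_mirnas")
  dplyr::arrange(out, dplyr::desc(.data$n_mirnas), .data$d5, .data$d3)
}

#' Canonical expression and dominance tallies
#'
#' @param im An `isomir_matrix`.
#' @param samples Sample subset (default all).
#' @return Tibble with one row: `n_canonical_absent` (miRNAs whose canonical
#'   form has zero count), `n_canonical_dominant` (canonical form is modal)
#'   and `n_total` (miRNAs with at least one expressed isomiR).
#' @export
canonical_fractions <- function(im, samples = NULL) {
  dt <- diversity_table(im, samples)$summary
  tibble::tibble(
    n_canonical_absent = sum(!dt$canonical_expressed),
    n_canonical_dominant = sum(dt$canonical_dominant),
    n_total = nrow(dt))
}

#' Correlation between isomiR diversity and expression
#'
#' Pearson correlation between the per-miRNA number of expressed isomiRs
#' and its mean normalized expression; reported on the log10(x + 1) scale
#' (primary) and on the raw scale.
#'
#' @param summary The `summary` tibble from [diversity_table()].
#' @return A list with `r_log`, `r_raw`, `n` and `status` (`"ok"` or
#'   `"undefined"` when either variable has zero variance); correlations are
#'   `NA` when undefined.
#' @export
diversity_expression_correlation <- function(summary) {
  if (nrow(summary) < 3L) stop("need at least 3 miRNAs")
  x <- summary$n_isomirs
  y <- summary$mean_expression
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r_log = NA_real_, r_raw = NA_real_, n = nrow(summary),
                status = "undefined"))
  }
  list(r_log = stats::cor(x, log10(y + 1)),
       r_raw = stats::cor(x, y),
       n = nrow(summary), status = "ok")
}
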