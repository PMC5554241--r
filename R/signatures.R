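# Subtype-specific miRNA signatures and the differentiation-arrest vs
# oncomiR-candidate classification against normal thymocyte subsets.
#
# "Subtype-specific" is operationalized as one-vs-rest significance among
# the patient subgroups. The matched normal subset mapping is fixed by the
# biology of the differentiation arrest: immature T-ALL <-> CD34+ early
# thymocytes, TAL-rearranged T-ALL <-> CD4+CD8+ double-positive thymocytes.

#' One-vs-rest differential expression per subgroup
#'
#' For each subgroup g, runs [nb_wald_test()] of g against the pooled
#' remaining subgroups (thymocyte or other columns are excluded).
#'
#' @param mat Filtered miRNA x sample count matrix.
#' @param groups Group labels per column (or named by sample id).
#' @param subgroups Subgroup labels to contrast (default the four T-ALL
#'   subgroups).
#' @param sf Optional size factors (named by sample id) to reuse across
#'   contrasts.
#' @param threshold Adjusted-p significance threshold (default 0.05).
#' @return A list with `tests` (named list of DE tibbles, one per subgroup)
#'   and `signatures` (tibble of significant entries: `mirna`, `subgroup`,
#'   `direction`, `log2_fold_change`, `padj`).
#' @export
one_vs_rest_signatures <- function(mat, groups,
                                   subgroups = c("immature", "TLX", "TAL-R", "HOXA"),
                                   sf = NULL, threshold = 0.05) {
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  if (length(subgroups) < 2L) stop("need at least 2 subgroups")
  for (g in subgroups) {
    if (sum(groups == g) < 2L) stop("subgroup with fewer than 2 samples: ", g)
  }
  tests <- lapply(subgroups, function(g) {
    nb_wald_test(mat, groups, group_a = g,
                 group_b = setdiff(subgroups, g), sf = sf)
  })
  names(tests) <- subgroups
  sig <- do.call(rbind, lapply(subgroups, function(g) {
    de <- tests[[g]]
    hit <- !is.na(de$padj) & de$padj < threshold
    if (!any(hit)) return(NULL)
    tibble::tibble(mirna = de$mirna[hit], subgroup = g,
                   direction = ifelse(de$log2_fold_change[hit] > 0, "up", "down"),
                   log2_fold_change = de$log2_fold_change[hit],
                   padj = de$padj[hit])
  }))
  if (is.null(sig)) {
    sig <- tibble::tibble(mirna = character(), subgroup = character(),
                          direction = character(), log2_fold_change = numeric(),
                          padj = numeric())
  }
  list(tests = tests, signatures = tibble::as_tibble(sig))
}

#' Select miRNAs for a signature heatmap
#'
#' Per subgroup, the k most significant miRNAs (either direction, smallest
#' adjusted p; ties broken by larger |log2 fold-change|, then name); the
#' union across subgroups is de-duplicated keeping the first occurrence in
#' subgroup order.
#'
#' @param ovr Output of [one_vs_rest_signatures()].
#' @param k Number of miRNAs per subgroup (default 50).
#' @param threshold Adjusted-p threshold (default 0.05).
#' @return Character vector of miRNA names, stable order.
#' @export
heatmap_selection <- function(ovr, k = 50L, threshold = 0.05) {
  picked <- character()
  for (g in names(ovr$tests)) {
    de <- ovr$tests[[g]]
    de <- de[!is.na(de$padj) & de$padj < threshold, , drop = FALSE]
    if (!nrow(de)) next
    ord <- order(de$padj, -abs(de$log2_fold_change), de$mirna)
    picked <- c(picked, de$mirna[ord][seq_len(min(k, nrow(de)))])
  }
  picked[!duplicated(picked)]
}

#' Top expressed significantly-up miRNAs per subgroup
#'
#' Among the up-significant miRNAs of each subgroup, ranks by mean
#' normalized expression within that subgroup (descending) and keeps the
#' top k.
#'
#' @param ovr Output of [one_vs_rest_signatures()].
#' @param normmat Normalized expression matrix (miRNA x sample).
#' @param groups Group labels per column (or named by sample id).
#' @param k Number of miRNAs per subgroup (default 10).
#' @return Tibble with `mirna`, `subgroup`, `mean_expression`, `padj`,
#'   `rank`.
#' @export
top_expressed_signature <- function(ovr, normmat, groups, k = 10L) {
  if (!is.null(names(groups))) groups <- groups[colnames(normmat)]
  sig <- ovr$signatures
  up <- sig[sig$direction == "up", , drop = FALSE]
  out <- do.call(rbind, lapply(unique(up$subgroup), function(g) {
    m <- up$mirna[up$subgroup == g]
    m <- intersect(m, rownames(normmat))
    if (!length(m)) return(NULL)
    expr <- rowMeans(normmat[m, groups == g, drop = FALSE])
    ord <- order(-expr, m)
    m <- m[ord][seq_len(min(k, length(m)))]
    tibble::tibble(mirna = m, subgroup = g,
                   mean_expression = unname(expr[ord][seq_len(length(m))]),
                   padj = up$padj[up$subgroup == g][match(m, up$mirna[up$subgroup == g])],
                   rank = seq_along(m))
  }))
  if (is.null(out)) {
    out <- tibble::tibble(mirna = character(), subgroup = character(),
                          mean_expression = numeric(), padj = numeric(),
                          rank = integer())
  }
  tibble::as_tibble(out)
}

#' Evaluate a signature inside one sample's expression profile
#'
#' Reports, for each signature miRNA, its expression percentile within the
#' sample's full expression distribution (the sample maximum scores 100),
#' and the median percentile as a summary.
#'
#' @param signature Character vector of miRNA names.
#' @param sample_expr Named numeric vector: one sample's normalized
#'   expression over all miRNAs.
#' @return List with `percentiles` (tibble `mirna`, `percentile`, `present`)
#'   and `median_percentile` (`NA` with a warning when no signature miRNA is
#'   present).
#' @export
evaluate_signature_in_sample <- function(signature, sample_expr) {
  stopifnot(!is.null(names(sample_expr)))
  pct <- 100 * rank(sample_expr, ties.method = "max") / length(sample_expr)
  present <- signature %in% names(sample_expr)
  out <- tibble::tibble(mirna = signature,
                        percentile = ifelse(present, pct[signature], NA_real_),
                        present = present)
  if (!any(present)) {
    warning("no signature miRNA present in the sample's expression vector")
    med <- NA_real_
  } else {
    med <- stats::median(out$percentile[present])
  }
  list(percentiles = out, median_percentile = med)
}

#' Classify subtype-specific miRNAs as arrest markers and/or candidates
#'
#' For each subtype-specific miRNA with a matched normal subset (immature:
#' CD34+, TAL-R: CD4+CD8+ double-positive), three flags are derived from the
#' DE tables at the given threshold: `arrest_marker` (significantly up in
#' the matched subset versus the other subset), `onco_candidate`
#' (significantly up in the subtype versus its matched subset) and
#' `suppressor_candidate` (significantly down in the subtype versus its
#' matched subset). Flags are not mutually exclusive: a miRNA already high
#' in the matched subset but further increased in leukemia carries both the
#' arrest and the oncomiR flag.
#'
#' @param signature Tibble with `mirna` and `subgroup` (e.g. from
#'   [top_expressed_signature()]).
#' @param thymocyte_de DE tibble for the CD34-vs-DP contrast (log2FC > 0
#'   means higher in CD34).
#' @param subtype_vs_matched Named list of DE tibbles, one per subtype with
#'   a matched subset, for subtype-vs-matched-subset contrasts (log2FC > 0
#'   means higher in the subtype).
#' @param matched_map Named character vector mapping subtypes to matched
#'   subsets; default `c(immature = "CD34", "TAL-R" = "DP")`.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @return Tibble with `mirna`, `subgroup`, `matched_subset`,
#'   `arrest_marker`, `onco_candidate`, `suppressor_candidate`.
#' @export
classify_candidates <- function(signature, thymocyte_de, subtype_vs_matched,
                                matched_map = c(immature = "CD34", "TAL-R" = "DP"),
                                threshold = 0.05) {
  sub <- signature[signature$subgroup %in% names(matched_map), , drop = FALSE]
  if (!nrow(sub)) {
    return(tibble::tibble(mirna = character(), subgroup = character(),
                          matched_subset = character(), arrest_marker = logical(),
                          onco_candidate = logical(), suppressor_candidate = logical()))
  }
  missing <- setdiff(unique(sub$subgroup), names(subtype_vs_matched))
  if (length(missing)) {
    stop("missing subtype-vs-matched DE table(s) for: ",
         paste(missing, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(sub)), function(r) {
    m <- sub$mirna[r]; g <- sub$subgroup[r]
    subset <- unname(matched_map[g])
    thy <- thymocyte_de[thymocyte_de$mirna == m, , drop = FALSE]
    # thymocyte_de is oriented CD34 vs DP: up in CD34 means lfc > 0
    arrest <- FALSE
    if (nrow(thy) == 1L && !is.na(thy$padj) && thy$padj < threshold) {
      arrest <- if (subset == "CD34") thy$log2_fold_change > 0 else thy$log2_fold_change < 0
    }
    svm <- subtype_vs_matched[[g]]
    de <- svm[svm$mirna == m, , drop = FALSE]
    onco <- nrow(de) == 1L && !is.na(de$padj) && de$padj < threshold &&
      de$log2_fold_change > 0
    supp <- nrow(de) == 1L && !is.na(de$padj) && de$padj < threshold &&
      de$log2_fold_change < 0
    tibble::tibble(mirna = m, subgroup = g, matched_subset = subset,
                   arrest_marker = arrest, onco_candidate = onco,
                   suppressor_candidate = supp)
  })
  do.call(rbind, rows)
}

#' Global T-ALL versus thymocyte contrast
#'
#' Single two-group test of all leukemia samples against all thymocyte
#' samples, partitioned into up- and downregulated sets at the threshold.
#'
#' @param mat Filtered miRNA x sample count matrix.
#' @param groups Group labels per column (or named by sample id).
#' @param tall_groups Labels forming the leukemia side (default the four
#'   subgroups).
#' @param thymo_groups Labels forming the normal side (default CD34 and DP).
#' @param sf Optional size factors.
#' @param threshold Adjusted-p threshold (default 0.05).
#' @return List with `de` (full DE tibble, log2FC > 0 means higher in
#'   T-ALL), `up` and `down` (disjoint miRNA name vectors).
#' @export
global_tall_contrast <- function(mat, groups,
                                 tall_groups = c("immature", "TLX", "TAL-R", "HOXA"),
                                 thymo_groups = c("CD34", "DP"),
                                 sf = NULL, threshold = 0.05) {
  de <- nb_wald_test(mat, groups, group_a = tall_groups,
                     group_b = thymo_groups, sf = sf)
  hit <- !is.na(de$padj) & de$padj < threshold
  list(de = de,
       up = de$mirna[hit & de$log2_fold_change > 0],
       down = de$mirna[hit & de$log2_fold_change < 0])
}
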