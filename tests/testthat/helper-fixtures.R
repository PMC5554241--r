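# Shared fixtures and independent oracles for the test suite.

# Three hand-built precursors. pre-a carries mir-A with a G immediately
# after the mature 3' end (so an appended A is non-templated); pre-b
# carries mir-B with an A after the 3' end (so an appended A is a templated
# extension); pre-c carries mir-C. mir-P is a paralog pair: two mature
# names (mir-P1 on pre-a, mir-P2 on pre-c) with an identical sequence.
tiny_annotation <- function(with_paralogs = FALSE) {
  mirA <- "ACGTGGCTGTAACTGCATGA"          # 20 nt
  mirB <- "TGCAAGTCGGATCCTTGCAC"          # 20 nt
  mirC <- "GGATTCAGCAATGCCTGTCA"          # 20 nt
  mirP <- "CCTAGGTTACACGGAGTCTA"          # 20 nt, shared when paralogs on
  pre_a <- paste0("TTGACATG", mirA, "G", "TCCAGTTAC",
                  if (with_paralogs) paste0(mirP, "ACCGT") else "GGCCATTACGGATC")
  pre_b <- paste0("CATTCGGA", mirB, "A", "ACGGATCCATTGCAAGG")
  pre_c <- paste0("GATCCAATTG", mirC, "CGTTAAGCAT",
                  if (with_paralogs) paste0(mirP, "TTGCA") else "")
  precursors <- tibble::tibble(
    id = c("pre-a", "pre-b", "pre-c"),
    sequence = c(pre_a, pre_b, pre_c))
  matures <- tibble::tibble(
    name = c("mir-A", "mir-B", "mir-C"),
    precursor_id = c("pre-a", "pre-b", "pre-c"),
    start = c(8L, 8L, 10L),
    end = c(28L, 28L, 30L),
    canonical_sequence = c(mirA, mirB, mirC))
  if (with_paralogs) {
    matures <- rbind(matures, tibble::tibble(
      name = c("mir-P1", "mir-P2"),
      precursor_id = c("pre-a", "pre-c"),
      start = c(38L, 40L), end = c(58L, 60L),
      canonical_sequence = mirP))
  }
  list(precursors = precursors, matures = matures,
       index = build_index(precursors, matures))
}

# Independent brute-force isomiR classifier: naive scanning of every
# precursor position, no index structure shared with the implementation.
brute_force_assign <- function(sequence, precursors, matures,
                               max_trim = 2L, max_offset = 5L,
                               min_overlap = 15L) {
  empty <- data.frame(mirna = character(), d5 = integer(), d3 = integer(),
                      nta = character(), weight = numeric())
  n <- nchar(sequence)
  if (n < 15L || n > 30L) return(list(status = "unassigned", hits = empty))
  for (t in 0:max_trim) {
    clen <- n - t
    if (clen < 15L) break
    core <- substr(sequence, 1L, clen)
    cand <- NULL
    for (pi in seq_len(nrow(precursors))) {
      pseq <- precursors$sequence[pi]
      plen <- nchar(pseq)
      if (clen > plen) next
      mt <- matures[matures$precursor_id == precursors$id[pi], , drop = FALSE]
      for (pos in 0:(plen - clen)) {
        if (substr(pseq, pos + 1L, pos + clen) != core) next
        for (mi in seq_len(nrow(mt))) {
          d5 <- pos - mt$start[mi]
          d3 <- pos + clen - mt$end[mi]
          ov <- min(pos + clen, mt$end[mi]) - max(pos, mt$start[mi])
          if (abs(d5) <= max_offset && abs(d3) <= max_offset && ov >= min_overlap) {
            cand <- rbind(cand, data.frame(mirna = mt$name[mi], d5 = d5, d3 = d3))
          }
        }
      }
    }
    if (!is.null(cand) && nrow(cand)) {
      cand <- unique(cand)
      sc <- abs(cand$d5) + abs(cand$d3)
      cand <- cand[sc == min(sc), , drop = FALSE]
      ord <- order(cand$mirna, !(cand$d5 == 0L & cand$d3 == 0L), cand$d5, cand$d3)
      cand <- cand[ord, , drop = FALSE]
      cand <- cand[!duplicated(cand$mirna), , drop = FALSE]
      cand$nta <- if (t > 0L) substr(sequence, clen + 1L, n) else ""
      cand$weight <- 1 / nrow(cand)
      rownames(cand) <- NULL
      status <- if (nrow(cand) == 1L) "assigned" else "ambiguous-split"
      return(list(status = status, hits = cand))
    }
  }
  list(status = "unassigned", hits = empty)
}

# canonical string form of an assignment result, for cross-implementation
# comparison
assignment_signature <- function(res) {
  if (!nrow(res$hits)) return(res$status)
  h <- res$hits[order(res$hits$mirna), , drop = FALSE]
  paste(res$status,
        paste(h$mirna, h$d5, h$d3, h$nta, sprintf("%.6f", h$weight),
              collapse = ";"))
}

# naive substring scan over precursors, oracle for the lookup index
naive_scan <- function(query, precursors) {
  out <- NULL
  qlen <- nchar(query)
  for (pi in seq_len(nrow(precursors))) {
    pseq <- precursors$sequence[pi]
    plen <- nchar(pseq)
    if (qlen > plen) next
    for (pos in 0:(plen - qlen)) {
      if (substr(pseq, pos + 1L, pos + qlen) == query) {
        out <- rbind(out, data.frame(precursor_id = precursors$id[pi], pos = pos))
      }
    }
  }
  if (is.null(out)) data.frame(precursor_id = character(), pos = integer()) else out
}

# mean silhouette coefficient on euclidean distances, computed by hand
silhouette_mean <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(unique(labels[!own]), function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# brute-force evaluation of the background-retention rule for one miRNA row
brute_force_retain <- function(counts, groups, subgroups, subsets,
                               min_reads = 4, min_fraction = 0.6) {
  counts <- round(counts)
  for (g in subgroups) {
    idx <- which(groups == g)
    if (!length(idx)) next
    if (sum(counts[idx] >= min_reads) >= ceiling(min_fraction * length(idx))) {
      return(TRUE)
    }
  }
  for (g in subsets) {
    idx <- which(groups == g)
    if (!length(idx)) next
    if (all(counts[idx] >= min_reads)) return(TRUE)
  }
  FALSE
}
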