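# Read-level quantification: adapter trimming, collapsing, isomiR-resolved
# assignment in precursor space, and count-matrix construction.
#
# An isomiR key is (mature name, d5, d3, nta): d5 = read start minus
# canonical start on the precursor (d5 < 0 is a 5' extension, d5 > 0 a 5'
# trimming), d3 = read end minus canonical end (d3 > 0 is a 3' extension),
# and nta is a non-templated 3' tail. The canonical form is (0, 0, "").

#' Trim a 3' adapter and apply the read length filter
#'
#' The leftmost exact occurrence of the adapter's first 8 nt truncates the
#' read; reads without a match are kept whole. Reads whose post-trimming
#' length falls outside `[min_len, max_len]` are rejected.
#'
#' @param reads Character vector of read sequences.
#' @param adapter 3' adapter sequence (>= 8 nt) or `NULL` for none.
#' @param min_len,max_len Retained length range (defaults 15 and 30 nt).
#' @return Character vector of the same length; rejected reads are `NA`.
#' @export
trim_adapter <- function(reads, adapter = NULL, min_len = 15L, max_len = 30L) {
  out <- reads
  if (!is.null(adapter)) {
    if (nchar(adapter) < 8L) stop("adapter must be at least 8 nt")
    key <- substr(adapter, 1L, 8L)
    pos <- regexpr(key, out, fixed = TRUE)
    hit <- pos > 0L
    out[hit] <- substr(out[hit], 1L, pos[hit] - 1L)
  }
  len <- nchar(out)
  out[len < min_len | len > max_len] <- NA_character_
  out
}

#' Collapse reads to unique sequences with multiplicities
#'
#' @param reads Character vector of read sequences (`NA`s are dropped).
#' @return A tibble with columns `sequence` and `count`, sorted by sequence;
#'   counts sum to the number of non-`NA` input reads.
#' @export
collapse_reads <- function(reads) {
  reads <- reads[!is.na(reads)]
  if (!length(reads)) return(tibble::tibble(sequence = character(), count = integer()))
  tab <- table(reads)
  tibble::tibble(sequence = names(tab), count = as.integer(tab))
}

#' Assign one read sequence to isomiR keys
#'
#' For suffix trims t = 0, 1, 2 in order, the read minus its last t nt is
#' searched as an exact precursor substring; the first t yielding at least
#' one valid candidate wins and the trimmed suffix becomes the non-templated
#' tail. Each occurrence is converted to an isomiR key against every mature
#' window it overlaps by at least `min_overlap` nt with |d5|, |d3| within
#' `max_offset`. Candidates are ranked by |d5| + |d3| (the tail length is
#' constant within a trim level); all top-rank candidates with distinct
#' mature names share weight equally; an identical key reached through
#' several precursors counts once.
#'
#' @param sequence A single read sequence, length 15-30 nt.
#' @param index An `annotation_index`.
#' @param max_trim Maximum 3' suffix length considered non-templated (2).
#' @param max_offset Hard cap on |d5| and |d3| (5).
#' @param min_overlap Minimum overlap with the mature window (15 nt).
#' @return A list with `status` (`"assigned"`, `"ambiguous-split"` or
#'   `"unassigned"`) and `hits`, a data.frame with columns `mirna`, `d5`,
#'   `d3`, `nta`, `weight` (weights sum to 1 unless unassigned).
#' @export
assign_read <- function(sequence, index, max_trim = 2L, max_offset = 5L,
                        min_overlap = 15L) {
  empty <- data.frame(mirna = character(), d5 = integer(), d3 = integer(),
                      nta = character(), weight = numeric())
  n <- nchar(sequence)
  if (n < 15L || n > 30L) return(list(status = "unassigned", hits = empty))
  for (t in 0:min(max_trim, n - index$k)) {
    core <- if (t > 0L) substr(sequence, 1L, n - t) else sequence
    sites <- site_hits(index, core)
    if (is.null(sites)) next
    clen <- n - t
    cand_name <- character(); cand_d5 <- integer(); cand_d3 <- integer()
    for (si in seq_len(nrow(sites))) {
      mt <- index$mature_by_prec[[index$precursor_ids[sites[si, 1L]]]]
      if (is.null(mt) || !nrow(mt)) next
      pos <- sites[si, 2L]
      d5 <- pos - mt$start
      d3 <- (pos + clen) - mt$end
      ov <- pmin(pos + clen, mt$end) - pmax(pos, mt$start)
      keep <- abs(d5) <= max_offset & abs(d3) <= max_offset & ov >= min_overlap
      if (any(keep)) {
        cand_name <- c(cand_name, mt$name[keep])
        cand_d5 <- c(cand_d5, d5[keep])
        cand_d3 <- c(cand_d3, d3[keep])
      }
    }
    if (!length(cand_name)) next
    nta <- if (t > 0L) substr(sequence, n - t + 1L, n) else ""
    # dedupe identical keys reached via different precursors
    keykey <- paste(cand_name, cand_d5, cand_d3)
    dup <- duplicated(keykey)
    cand_name <- cand_name[!dup]; cand_d5 <- cand_d5[!dup]; cand_d3 <- cand_d3[!dup]
    score <- abs(cand_d5) + abs(cand_d3)
    top <- score == min(score)
    cand_name <- cand_name[top]; cand_d5 <- cand_d5[top]; cand_d3 <- cand_d3[top]
    # one key per mature name: canonical first, then lexicographic (d5, d3)
    ord <- order(cand_name, !(cand_d5 == 0L & cand_d3 == 0L), cand_d5, cand_d3)
    first <- !duplicated(cand_name[ord])
    sel <- ord[first]
    k <- length(sel)
    hits <- data.frame(mirna = cand_name[sel], d5 = as.integer(cand_d5[sel]),
                       d3 = as.integer(cand_d3[sel]), nta = nta,
                       weight = rep(1 / k, k))
    status <- if (k == 1L) "assigned" else "ambiguous-split"
    return(list(status = status, hits = hits))
  }
  list(status = "unassigned", hits = empty)
}

#' Assign a collapsed read table for one sample
#'
#' @param collapsed Tibble from [collapse_reads()].
#' @param index An `annotation_index`.
#' @param ... Passed to [assign_read()].
#' @return A tibble with one row per (sequence, key) pair: `sequence`,
#'   `count`, `status`, `mirna`, `d5`, `d3`, `nta`, `weight`. Unassigned
#'   sequences keep one row with `NA` key fields and weight 0.
#' @export
assign_sample <- function(collapsed, index, ...) {
  if (!nrow(collapsed)) {
    return(tibble::tibble(sequence = character(), count = integer(),
                          status = character(), mirna = character(),
                          d5 = integer(), d3 = integer(), nta = character(),
                          weight = numeric()))
  }
  res <- lapply(collapsed$sequence, assign_read, index = index, ...)
  rows <- Map(function(seqc, cnt, r) {
    if (nrow(r$hits)) {
      data.frame(sequence = seqc, count = cnt, status = r$status, r$hits)
    } else {
      data.frame(sequence = seqc, count = cnt, status = r$status,
                 mirna = NA_character_, d5 = NA_integer_, d3 = NA_integer_,
                 nta = NA_character_, weight = 0)
    }
  }, collapsed$sequence, collapsed$count, res)
  tibble::as_tibble(do.call(rbind, rows))
}

#' Construct isomiR- and miRNA-level count matrices
#'
#' @param assigned Named list (one element per sample) of tibbles from
#'   [assign_sample()]. Names must cover every sample in `sample_sheet`.
#' @param sample_sheet Tibble with columns `sample_id` and `group`; column
#'   order of the matrices follows it.
#' @return A list with `isomir` (an `isomir_matrix`), `mirna` (numeric
#'   matrix, miRNA x sample), and `summary` (per-sample assigned /
#'   ambiguous-split / unassigned multiplicities).
#' @export
build_matrices <- function(assigned, sample_sheet) {
  samples <- sample_sheet$sample_id
  missing <- setdiff(samples, names(assigned))
  if (length(missing)) {
    stop("no assignments provided for sample(s): ", paste(missing, collapse = ", "))
  }
  hit_rows <- lapply(assigned[samples], function(df) df[!is.na(df$mirna), , drop = FALSE])
  allhits <- do.call(rbind, hit_rows)
  if (is.null(allhits) || !nrow(allhits)) {
    key <- tibble::tibble(mirna = character(), d5 = integer(),
                          d3 = integer(), nta = character())
    counts <- matrix(0, 0L, length(samples), dimnames = list(NULL, samples))
  } else {
    key <- unique(allhits[, c("mirna", "d5", "d3", "nta")])
    key <- key[order(key$mirna, key$d5, key$d3, key$nta), , drop = FALSE]
    keyid <- paste(key$mirna, key$d5, key$d3, key$nta, sep = "\r")
    counts <- matrix(0, nrow(key), length(samples),
                     dimnames = list(NULL, samples))
    for (s in samples) {
      df <- hit_rows[[s]]
      if (!nrow(df)) next
      row <- match(paste(df$mirna, df$d5, df$d3, df$nta, sep = "\r"), keyid)
      v <- df$count * df$weight
      agg <- rowsum(v, row)
      counts[as.integer(rownames(agg)), s] <- agg[, 1L]
    }
    key <- tibble::as_tibble(key)
  }
  zero_read <- samples[vapply(assigned[samples], function(df) sum(df$count) == 0, TRUE)]
  if (length(zero_read)) {
    warning("sample(s) with no reads: ", paste(zero_read, collapse = ", "))
  }
  summary <- do.call(rbind, lapply(samples, function(s) {
    df <- assigned[[s]]
    per_seq <- df[!duplicated(df$sequence), c("count", "status")]
    data.frame(sample_id = s,
               assigned = sum(per_seq$count[per_seq$status == "assigned"]),
               ambiguous = sum(per_seq$count[per_seq$status == "ambiguous-split"]),
               unassigned = sum(per_seq$count[per_seq$status == "unassigned"]))
  }))
  im <- isomir_matrix(key, counts)
  list(isomir = im, mirna = aggregate_mirna(im), summary = tibble::as_tibble(summary))
}

#' Quantify FASTQ files into isomiR and miRNA count matrices
#'
#' Runs trimming, collapsing, assignment (each unique sequence is assigned
#' once across the whole batch) and matrix construction.
#'
#' @param files Named character vector of FASTQ paths; names are sample ids.
#' @param sample_sheet Tibble with `sample_id` and `group`.
#' @param index An `annotation_index`.
#' @param adapter 3' adapter to trim, or `NULL`.
#' @param ... Passed to [assign_read()].
#' @return As [build_matrices()].
#' @export
quantify_fastq <- function(files, sample_sheet, index, adapter = NULL, ...) {
  stopifnot(all(sample_sheet$sample_id %in% names(files)))
  collapsed <- lapply(files[sample_sheet$sample_id], function(f) {
    collapse_reads(trim_adapter(read_fastq_sequences(f), adapter))
  })
  uniq <- sort(unique(unlist(lapply(collapsed, `[[`, "sequence"), use.names = FALSE)))
  res <- lapply(uniq, assign_read, index = index, ...)
  assigned <- lapply(collapsed, function(cc) {
    idx <- match(cc$sequence, uniq)
    rows <- Map(function(seqc, cnt, r) {
      if (nrow(r$hits)) {
        data.frame(sequence = seqc, count = cnt, status = r$status, r$hits)
      } else {
        data.frame(sequence = seqc, count = cnt, status = r$status,
                   mirna = NA_character_, d5 = NA_integer_, d3 = NA_integer_,
                   nta = NA_character_, weight = 0)
      }
    }, cc$sequence, cc$count, res[idx])
    if (length(rows)) tibble::as_tibble(do.call(rbind, rows)) else assign_sample(cc, index)
  })
  build_matrices(assigned, sample_sheet)
}

#' Read sequences from a FASTQ file
#'
#' @param path FASTQ path (plain or gzipped).
#' @return Character vector of read sequences.
#' @export
read_fastq_sequences <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(set)
}

#' IsomiR count matrix container
#'
#' Pairs a key table (`mirna`, `d5`, `d3`, `nta`) with a numeric count
#' matrix whose rows align with the key table and whose columns are samples.
#' Counts may be fractional (ambiguous reads are split).
#'
#' @param key Tibble with columns `mirna`, `d5`, `d3`, `nta`.
#' @param counts Numeric matrix, `nrow(key)` rows, sample columns.
#' @return An `isomir_matrix` object.
#' @export
isomir_matrix <- function(key, counts) {
  stopifnot(nrow(key) == nrow(counts), !is.null(colnames(counts)),
            all(c("mirna", "d5", "d3", "nta") %in% names(key)))
  if (any(counts < 0)) stop("negative counts")
  structure(list(key = tibble::as_tibble(key), counts = counts),
            class = "isomir_matrix")
}

#' @export
print.isomir_matrix <- function(x, ...) {
  cat("isomir_matrix:", nrow(x$key), "isomiRs,",
      length(unique(x$key$mirna)), "miRNAs,", ncol(x$counts), "samples\n")
  invisible(x)
}

#' @export
dim.isomir_matrix <- function(x) dim(x$counts)

#' Aggregate an isomiR matrix to miRNA-level counts
#'
#' @param im An `isomir_matrix`.
#' @return Numeric matrix (miRNA x sample), rows sorted by miRNA name;
#'   exactly the row aggregation of the isomiR counts.
#' @export
aggregate_mirna <- function(im) {
  if (!nrow(im$key)) {
    return(matrix(0, 0L, ncol(im$counts), dimnames = list(NULL, colnames(im$counts))))
  }
  rowsum(im$counts, group = im$key$mirna, reorder = TRUE)
}

#' Render isomiR keys as display labels
#'
#' Offsets are rendered in the 5'/3' overhang-deletion convention: a 5'
#' extension (d5 < 0) prints as `5'+n`, a 5' trimming as `5'-n`, a 3'
#' extension (d3 > 0) as `3'+n`, a 3' trimming as `3'-n`.
#'
#' @param key Key tibble (`mirna`, `d5`, `d3`, `nta`).
#' @return Character vector of labels.
#' @export
isomir_labels <- function(key) {
  lab5 <- ifelse(key$d5 == 0L, "0", ifelse(key$d5 < 0L,
                 paste0("5'+", -key$d5), paste0("5'-", key$d5)))
  lab3 <- ifelse(key$d3 == 0L, "0", ifelse(key$d3 > 0L,
                 paste0("3'+", key$d3), paste0("3'-", -key$d3)))
  tail <- ifelse(nzchar(key$nta), paste0("+", key$nta), "")
  paste0(key$mirna, "|", lab5, "|", lab3, tail)
}

#' Write an isomiR count matrix as TSV
#'
#' @param im An `isomir_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isomir_tsv <- function(im, path) {
  df <- cbind(as.data.frame(im$key), as.data.frame(im$counts))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an isomiR count matrix from TSV
#'
#' @param path Path written by [write_isomir_tsv()].
#' @return An `isomir_matrix`.
#' @export
read_isomir_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  key <- tibble::as_tibble(df[, c("mirna", "d5", "d3", "nta")])
  key$nta[is.na(key$nta)] <- ""
  counts <- as.matrix(df[, setdiff(names(df), c("mirna", "d5", "d3", "nta")), drop = FALSE])
  isomir_matrix(key, counts)
}
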