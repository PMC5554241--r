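# Annotation ingestion and indexing: precursor FASTA + mature-miRNA GFF3.
# Internal coordinates are 0-based half-open on the precursor; the GFF3
# boundary is 1-based inclusive (miRBase dialect). U is normalised to T on
# ingestion and never emitted.

#' Read miRNA precursor (hairpin) sequences from FASTA
#'
#' @param path Path to a FASTA file of precursor sequences.
#' @return A tibble with columns `id` (record identifier, first whitespace
#'   token of the header) and `sequence` (uppercase DNA; U converted to T),
#'   one row per record in file order.
#' @export
read_precursor_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1], " is not a header line")
  }
  if (!length(nonblank)) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(toupper(chartr("Uu", "Tt", as.character(set))))
  if (anyDuplicated(ids)) {
    stop("duplicate precursor id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty precursor sequence(s)")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("non-ACGT/U characters in precursor(s): ",
         paste(ids[bad], collapse = ", "))
  }
  tibble::tibble(id = ids, sequence = seqs)
}

#' Write precursor sequences to FASTA
#'
#' @param precursors Tibble as returned by [read_precursor_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  set <- Biostrings::DNAStringSet(precursors$sequence)
  names(set) <- precursors$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read mature miRNA coordinates from a miRBase-style GFF3
#'
#' Expects `miRNA` feature rows whose coordinates are expressed on the
#' precursor: either the seqid is the precursor id, or a `Derives_from`
#' attribute points at a `miRNA_primary_transcript` row whose `ID` or `Name`
#' matches a precursor id.
#'
#' @param path Path to the GFF3 file.
#' @param precursors Precursor tibble from [read_precursor_fasta()].
#' @return A tibble with columns `name`, `precursor_id`, `start`, `end`
#'   (0-based half-open on the precursor) and `canonical_sequence`. The same
#'   mature name may appear on several precursors only with an identical
#'   canonical sequence.
#' @export
read_mature_gff3 <- function(path, precursors) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  mi <- gr[type == "miRNA"]
  if (!length(mi)) {
    return(tibble::tibble(name = character(), precursor_id = character(),
                          start = integer(), end = integer(),
                          canonical_sequence = character()))
  }
  # map Derives_from targets (primary-transcript ID/Name) to precursor ids
  prim <- gr[type == "miRNA_primary_transcript"]
  prim_map <- character()
  if (length(prim)) {
    pid <- if (!is.null(prim$ID)) as.character(prim$ID) else rep(NA_character_, length(prim))
    pname <- if (!is.null(prim$Name)) as.character(prim$Name) else rep(NA_character_, length(prim))
    pseq <- as.character(GenomicRanges::seqnames(prim))
    target <- ifelse(pname %in% precursors$id, pname,
                     ifelse(pseq %in% precursors$id, pseq, NA_character_))
    prim_map <- stats::setNames(target, pid)
  }
  seqid <- as.character(GenomicRanges::seqnames(mi))
  derives <- if (!is.null(mi$Derives_from)) as.character(mi$Derives_from) else rep(NA_character_, length(mi))
  prec_id <- ifelse(seqid %in% precursors$id, seqid,
                    unname(prim_map[derives]))
  if (anyNA(prec_id)) {
    stop("cannot resolve precursor for miRNA record(s): ",
         paste(utils::head(as.character(mi$Name)[is.na(prec_id)], 5), collapse = ", "))
  }
  name <- as.character(mi$Name)
  if (any(is.na(name) | !nzchar(name))) stop("miRNA record without a Name attribute")
  start0 <- GenomicRanges::start(mi) - 1L
  end0 <- GenomicRanges::end(mi)
  plen <- stats::setNames(nchar(precursors$sequence), precursors$id)
  if (any(start0 < 0L | start0 >= end0 | end0 > plen[prec_id])) {
    stop("mature coordinates outside precursor for: ",
         paste(name[start0 < 0L | start0 >= end0 | end0 > plen[prec_id]], collapse = ", "))
  }
  len <- end0 - start0
  if (any(len < 15L | len > 30L)) {
    stop("mature length outside [15, 30] nt for: ",
         paste(name[len < 15L | len > 30L], collapse = ", "))
  }
  seqv <- stats::setNames(precursors$sequence, precursors$id)
  canon <- substr(seqv[prec_id], start0 + 1L, end0)
  out <- tibble::tibble(name = name, precursor_id = prec_id,
                        start = as.integer(start0), end = as.integer(end0),
                        canonical_sequence = unname(canon))
  nseq <- tapply(out$canonical_sequence, out$name, function(x) length(unique(x)))
  if (any(nseq > 1L)) {
    stop("mature name mapped to different canonical sequences: ",
         paste(names(nseq)[nseq > 1L], collapse = ", "))
  }
  out
}

#' Write mature miRNA coordinates to a miRBase-style GFF3
#'
#' @param matures Mature tibble from [read_mature_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mature_gff3 <- function(matures, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = matures$precursor_id,
    ranges = IRanges::IRanges(start = matures$start + 1L, end = matures$end),
    strand = "+")
  gr$type <- "miRNA"
  gr$source <- "tallmir"
  gr$Name <- matures$name
  gr$ID <- paste0("MIMAT_sim_", seq_along(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Build a substring-lookup index over precursors
#'
#' Indexes every k-mer (default k = 15) of every precursor so that exact
#' substring occurrences of reads can be located without scanning. Queries
#' shorter than k are not supported (the pipeline never emits them: the read
#' length filter floor is 15 nt).
#'
#' @param precursors Precursor tibble.
#' @param matures Mature tibble.
#' @param k Seed length for the prefix hash (default 15).
#' @return An `annotation_index` object.
#' @export
build_index <- function(precursors, matures, k = 15L) {
  stopifnot(nrow(precursors) >= 1L)
  if (!all(matures$precursor_id %in% precursors$id)) {
    stop("mature precursor_id not found among precursors")
  }
  seqv <- stats::setNames(precursors$sequence, precursors$id)
  n <- nchar(seqv)
  kmers <- vector("list", length(seqv))
  precv <- vector("list", length(seqv))
  posv <- vector("list", length(seqv))
  for (i in seq_along(seqv)) {
    if (n[[i]] < k) next
    starts <- seq_len(n[[i]] - k + 1L)
    kmers[[i]] <- substring(seqv[[i]], starts, starts + k - 1L)
    precv[[i]] <- rep.int(i, length(starts))
    posv[[i]] <- starts - 1L
  }
  kmer_all <- unlist(kmers, use.names = FALSE)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (length(kmer_all)) {
    prec_all <- unlist(precv, use.names = FALSE)
    pos_all <- unlist(posv, use.names = FALSE)
    grp <- split(seq_along(kmer_all), kmer_all)
    vals <- lapply(grp, function(r) cbind(prec = prec_all[r], pos = pos_all[r]))
    list2env(vals, envir = env)
  }
  mature_by_prec <- split(matures[, c("name", "start", "end")], matures$precursor_id)
  structure(list(
    precursor_ids = precursors$id,
    seqs = seqv,
    seq_len = unname(n),
    matures = matures,
    k = as.integer(k),
    kmer = env,
    mature_by_prec = mature_by_prec
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", length(x$seqs), "precursors,",
      nrow(x$matures), "mature records,",
      length(unique(x$matures$name)), "mature names; k =", x$k, "\n")
  invisible(x)
}

#' Locate all exact occurrences of a query among the precursors
#'
#' @param index An `annotation_index`.
#' @param query A DNA string of length >= the index seed length.
#' @return A data.frame with columns `precursor_id` and `pos` (0-based start
#'   on the precursor), one row per occurrence.
#' @export
lookup_sites <- function(index, query) {
  m <- site_hits(index, query)
  if (is.null(m)) {
    return(data.frame(precursor_id = character(), pos = integer()))
  }
  data.frame(precursor_id = index$precursor_ids[m[, 1L]], pos = as.integer(m[, 2L]))
}

# lean exact-occurrence search: integer matrix (prec index, pos) or NULL
site_hits <- function(index, query) {
  qlen <- nchar(query)
  if (qlen < index$k) return(NULL)
  hits <- index$kmer[[substr(query, 1L, index$k)]]
  if (is.null(hits)) return(NULL)
  pr <- hits[, 1L]
  pos <- hits[, 2L]
  ok <- (pos + qlen) <= index$seq_len[pr]
  if (any(ok)) {
    ok[ok] <- substr(index$seqs[pr[ok]], pos[ok] + 1L, pos[ok] + qlen) == query
  }
  if (!any(ok)) return(NULL)
  cbind(pr[ok], pos[ok])
}
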