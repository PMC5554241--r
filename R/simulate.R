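# Synthetic small RNA-seq data with known ground truth.
#
# The generator emulates the study design the analysis assumes: four T-ALL
# patient subgroups (13 immature, 14 TLX, 15 TAL-R, 6 HOXA) plus two CD34+
# and two CD4+CD8+ (DP) thymocyte samples; log-normal baseline abundances;
# negative-binomial sample-to-sample variation; per-miRNA isomiR mixtures in
# which roughly half of the miRNAs are canonical-dominant; isomiR diversity
# increasing with abundance; and planted subgroup-specific fold-changes.
# Reads per sample default to 5e4, a desk-scale reduction of the study's
# sequencing depth (~14.4 million reads per sample).

#' Simulation configuration
#'
#' @param seed Integer seed; every stage derives its RNG state from it.
#' @param n_mirnas Number of simulated miRNAs (one precursor each, unless
#'   paralogs are requested).
#' @param groups Named integer vector of group sizes. Default is the study
#'   design: immature 13, TLX 14, TAL-R 15, HOXA 6, CD34 2, DP 2.
#' @param reads_per_sample Reads emitted per sample (default 5e4).
#' @param baseline_log_mean_sd SD of log10 baseline abundance (default 1.2;
#'   baselines are log-normal around log10 mean 2).
#' @param nb_dispersion Negative-binomial dispersion alpha shared across
#'   miRNAs (default 0.2, a typical patient-cohort value).
#' @param isomir_concentration Dirichlet concentration for isoform
#'   proportions (default 1).
#' @param p_canonical_dominant Probability that a miRNA's canonical form is
#'   its modal isoform (default 0.5).
#' @param p_canonical_present Probability that the canonical form is in the
#'   support at all when it is not modal (default 0.5; drives the
#'   canonical-absent fraction).
#' @param diversity_coupling Slope tying the expected number of extra
#'   isoforms to log10 baseline abundance (default 2).
#' @param de_fraction Fraction of miRNAs given a planted subgroup effect
#'   (default 0.05).
#' @param de_log2fc Planted log2 fold-change (default 2).
#' @param de_groups Groups eligible as planted-effect targets (default the
#'   four T-ALL subgroups).
#' @param adapter 3' adapter appended to every read, or `NULL` (default).
#' @param paralog_fraction Fraction of miRNAs duplicated onto a second
#'   precursor with an identical mature sequence (default 0).
#' @param effects Optional tibble (`mirna`, `group`, `log2fc`) of explicit
#'   planted effects, applied in addition to the random plan; `mirna` may be
#'   an index into the simulated miRNA list.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_mirnas = 200L,
                       groups = c(immature = 13L, TLX = 14L, `TAL-R` = 15L,
                                  HOXA = 6L, CD34 = 2L, DP = 2L),
                       reads_per_sample = 5e4,
                       baseline_log_mean_sd = 1.2,
                       nb_dispersion = 0.2,
                       isomir_concentration = 1,
                       p_canonical_dominant = 0.5,
                       p_canonical_present = 0.5,
                       diversity_coupling = 2,
                       de_fraction = 0.05,
                       de_log2fc = 2,
                       de_groups = c("immature", "TLX", "TAL-R", "HOXA"),
                       adapter = NULL,
                       paralog_fraction = 0,
                       effects = NULL) {
  stopifnot(n_mirnas >= 1L, length(groups) >= 1L, all(groups >= 1L),
            reads_per_sample >= 1, nb_dispersion >= 0,
            isomir_concentration > 0,
            p_canonical_dominant >= 0, p_canonical_dominant <= 1,
            p_canonical_present >= 0, p_canonical_present <= 1,
            diversity_coupling >= 0, de_fraction >= 0, de_fraction <= 1,
            paralog_fraction >= 0, paralog_fraction <= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector")
  }
  structure(list(seed = as.integer(seed), n_mirnas = as.integer(n_mirnas),
                 groups = groups, reads_per_sample = reads_per_sample,
                 baseline_log_mean_sd = baseline_log_mean_sd,
                 nb_dispersion = nb_dispersion,
                 isomir_concentration = isomir_concentration,
                 p_canonical_dominant = p_canonical_dominant,
                 p_canonical_present = p_canonical_present,
                 diversity_coupling = diversity_coupling,
                 de_fraction = de_fraction, de_log2fc = de_log2fc,
                 de_groups = de_groups, adapter = adapter,
                 paralog_fraction = paralog_fraction, effects = effects),
            class = "sim_config")
}

#' Sample sheet implied by a simulation configuration
#'
#' @param config A `sim_config`.
#' @return Tibble with `sample_id` and `group`.
#' @export
sim_sample_sheet <- function(config) {
  grp <- rep(names(config$groups), config$groups)
  tibble::tibble(
    sample_id = paste0(grp, "_", unlist(lapply(config$groups, seq_len))),
    group = grp)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample() without the length-1 surprise
safe_sample <- function(x, size) {
  if (length(x) <= 1L) return(rep(x, length.out = min(size, length(x))))
  sample(x, size)
}

#' Simulate a miRNA annotation
#'
#' Random precursors of 70-90 nt, each carrying one mature window of 20-23
#' nt placed with at least 5 nt of flank on either side. Mature sequences
#' are pairwise distinct over their first 15 nt, so assignment is
#' unambiguous unless paralogs are requested, in which case selected mature
#' names recur on a second precursor with an identical mature sequence.
#'
#' @param config A `sim_config`.
#' @return An `annotation_index`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_mirnas
  prefixes <- character(0)
  prec_id <- character(n); prec_seq <- character(n)
  m_name <- character(n); m_start <- integer(n); m_end <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      plen <- sample(70:90, 1L)
      mlen <- sample(20:23, 1L)
      start <- sample(5:(plen - mlen - 5L), 1L)
      seqc <- random_dna(plen)
      pre15 <- substr(seqc, start + 1L, start + 15L)
      if (!(pre15 %in% prefixes)) {
        prefixes <- c(prefixes, pre15)
        prec_id[i] <- sprintf("sim-mir-%03d-pre", i)
        prec_seq[i] <- seqc
        m_name[i] <- sprintf("sim-miR-%03d", i)
        m_start[i] <- start
        m_end[i] <- start + mlen
        break
      }
    }
  }
  precursors <- tibble::tibble(id = prec_id, sequence = prec_seq)
  matures <- tibble::tibble(name = m_name, precursor_id = prec_id,
                            start = m_start, end = m_end,
                            canonical_sequence = substr(prec_seq, m_start + 1L, m_end))
  if (config$paralog_fraction > 0) {
    n_par <- max(1L, round(config$paralog_fraction * n))
    pick <- sample(n, n_par)
    for (i in pick) {
      mlen <- m_end[i] - m_start[i]
      plen <- sample(70:90, 1L)
      start <- sample(5:(plen - mlen - 5L), 1L)
      left <- random_dna(start)
      right <- random_dna(plen - start - mlen)
      seqc <- paste0(left, substr(prec_seq[i], m_start[i] + 1L, m_end[i]), right)
      pid <- sprintf("sim-mir-%03d-pre-2", i)
      precursors <- rbind(precursors, tibble::tibble(id = pid, sequence = seqc))
      matures <- rbind(matures, tibble::tibble(
        name = m_name[i], precursor_id = pid, start = start,
        end = start + mlen,
        canonical_sequence = substr(seqc, start + 1L, start + mlen)))
    }
  }
  build_index(precursors, matures)
}

# Candidate isomiR keys for one mature window, restricted to keys whose
# emitted read is exactly recoverable: window within the precursor, read
# length in [15, 30], templated core >= 15 nt overlap with the mature
# window, tail not templated at the insertion point, and the full read
# sequence occurring at exactly one precursor site (checked via the index).
recoverable_keys <- function(index, mature_row, d5_range = -2:2,
                             d3_range = -4:4, tails = c("", "A", "T", "AA", "TT")) {
  prec <- index$seqs[[mature_row$precursor_id]]
  plen <- nchar(prec)
  st <- mature_row$start; en <- mature_row$end
  grid <- expand.grid(d5 = d5_range, d3 = d3_range, nta = tails,
                      stringsAsFactors = FALSE)
  a <- st + grid$d5
  b <- en + grid$d3
  ov <- pmin(en, b) - pmax(st, a)
  rlen <- (b - a) + nchar(grid$nta)
  ok <- a >= 0L & b <= plen & (b - a) >= 15L & ov >= 15L &
    rlen >= 15L & rlen <= 30L
  # a tail whose first base continues the template belongs to a longer
  # templated window, not to this key
  tailed <- nzchar(grid$nta)
  cont <- tailed & b < plen &
    substr(prec, b + 1L, b + 1L) == substr(grid$nta, 1L, 1L)
  ok <- ok & !cont
  grid <- grid[ok, , drop = FALSE]
  a <- a[ok]; b <- b[ok]
  core <- substr(rep(prec, length(a)), a + 1L, b)
  full <- paste0(core, grid$nta)
  keep <- logical(nrow(grid))
  core_cache <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_len(nrow(grid))) {
    # every core site must belong to a precursor carrying this mature name
    # (one site in the paralog-free case); a tailed read must not itself
    # occur anywhere, nor its one-base extension when the tail has two
    cc <- core_cache[[core[j]]]
    if (is.null(cc)) {
      sites <- site_hits(index, core[j])
      cc <- !is.null(sites) && all(vapply(sites[, 1L], function(p) {
        mt <- index$mature_by_prec[[index$precursor_ids[p]]]
        !is.null(mt) && mature_row$name %in% mt$name
      }, TRUE))
      core_cache[[core[j]]] <- cc
    }
    if (!cc) next
    nta <- grid$nta[j]
    if (nzchar(nta)) {
      if (!is.null(site_hits(index, full[j]))) next
      if (nchar(nta) == 2L &&
          !is.null(site_hits(index, paste0(core[j], substr(nta, 1L, 1L))))) next
    }
    keep[j] <- TRUE
  }
  out <- grid[keep, , drop = FALSE]
  out$read_sequence <- full[keep]
  out
}

#' Simulate per-miRNA isomiR profiles
#'
#' Draws, for every miRNA, a log-normal baseline abundance, a support of k
#' isoforms (k - 1 is Poisson with mean `diversity_coupling` x positive part
#' of log10 abundance), Dirichlet proportions, and a designated modal
#' isoform: the canonical form with probability `p_canonical_dominant`,
#' otherwise a non-canonical isoform (with the canonical form then present
#' as a minor isoform with probability `p_canonical_present`).
#'
#' @param config A `sim_config`.
#' @param annotation An `annotation_index` from [simulate_annotation()].
#' @return A list with `proportions` (tibble `mirna`, `d5`, `d3`, `nta`,
#'   `proportion`, `read_sequence`) and `baseline` (tibble `mirna`,
#'   `base_mean` relative abundance).
#' @export
simulate_isomir_profiles <- function(config, annotation) {
  set.seed(config$seed + 2L)
  mat <- annotation$matures[!duplicated(annotation$matures$name), , drop = FALSE]
  n <- nrow(mat)
  log10_mu <- stats::rnorm(n, mean = 2, sd = config$baseline_log_mean_sd)
  mu <- 10^log10_mu
  prof <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- recoverable_keys(annotation, mat[i, ])
    is_canon <- pool$d5 == 0L & pool$d3 == 0L & pool$nta == ""
    stopifnot(any(is_canon))  # canonical always recoverable by construction
    lambda <- config$diversity_coupling * max(0, log10_mu[i])
    k <- 1L + stats::rpois(1L, lambda)
    k <- min(k, nrow(pool))
    canon_modal <- stats::runif(1L) < config$p_canonical_dominant
    noncanon <- which(!is_canon)
    if (canon_modal || !length(noncanon)) {
      modal <- which(is_canon)
      others <- safe_sample(noncanon, min(k - 1L, length(noncanon)))
      support <- c(modal, others)
    } else {
      modal <- if (length(noncanon) == 1L) noncanon else sample(noncanon, 1L)
      support <- modal
      rest <- setdiff(seq_len(nrow(pool)), modal)
      with_canon <- stats::runif(1L) < config$p_canonical_present
      if (!with_canon) rest <- setdiff(rest, which(is_canon))
      if (k > 1L && length(rest)) {
        extra <- safe_sample(rest, min(k - 1L, length(rest)))
        if (with_canon && !(which(is_canon) %in% extra) && length(extra) >= 1L) {
          extra[1L] <- which(is_canon)
        }
        support <- c(modal, extra)
      }
    }
    support <- unique(support)
    kk <- length(support)
    w <- stats::rgamma(kk, shape = config$isomir_concentration, rate = 1)
    w <- w / sum(w)
    # designated modal isoform receives the largest proportion
    mx <- which.max(w)
    if (mx != 1L) w[c(1L, mx)] <- w[c(mx, 1L)]
    sel <- pool[support, , drop = FALSE]
    prof[[i]] <- data.frame(mirna = mat$name[i], sel[, c("d5", "d3", "nta")],
                            proportion = w, read_sequence = sel$read_sequence)
  }
  proportions <- tibble::as_tibble(do.call(rbind, prof))
  list(proportions = proportions,
       baseline = tibble::tibble(mirna = mat$name, base_mean = mu))
}

#' Simulate per-sample isomiR counts with ground truth
#'
#' Per sample, miRNA intensities are gamma-distributed around the group mean
#' (so totals are negative-binomial), conditioned on the library size by a
#' multinomial draw of `reads_per_sample` reads, and split multinomially
#' across the miRNA's isoform proportions. Planted effects multiply the
#' group mean by `2^log2fc`.
#'
#' @param config A `sim_config`.
#' @param profiles Output of [simulate_isomir_profiles()].
#' @return A `sim_truth` list: `counts` (isomiR `isomir_matrix`, realized),
#'   `mirna_counts`, `sample_sheet`, `group_means` (miRNA x group),
#'   `de_plan` (tibble `mirna`, `group`, `log2fc`), `profiles`, `config`.
#' @export
simulate_counts <- function(config, profiles) {
  set.seed(config$seed + 3L)
  sheet <- sim_sample_sheet(config)
  mirnas <- profiles$baseline$mirna
  n <- length(mirnas)
  gnames <- names(config$groups)
  # planted random effects
  plan <- tibble::tibble(mirna = character(), group = character(), log2fc = numeric())
  de_groups <- intersect(config$de_groups, gnames)
  n_de <- round(config$de_fraction * n)
  if (n_de > 0 && length(de_groups)) {
    pick <- sample(n, n_de)
    plan <- tibble::tibble(
      mirna = mirnas[pick],
      group = sample(de_groups, n_de, replace = TRUE),
      log2fc = config$de_log2fc)
  }
  if (!is.null(config$effects)) {
    eff <- tibble::as_tibble(config$effects)
    if (is.numeric(eff$mirna)) eff$mirna <- mirnas[eff$mirna]
    stopifnot(all(eff$group %in% gnames), all(eff$mirna %in% mirnas))
    plan <- rbind(plan, eff[, c("mirna", "group", "log2fc")])
  }
  group_means <- matrix(profiles$baseline$base_mean, n, length(gnames),
                        dimnames = list(mirnas, gnames))
  if (nrow(plan)) {
    for (r in seq_len(nrow(plan))) {
      i <- match(plan$mirna[r], mirnas)
      group_means[i, plan$group[r]] <-
        group_means[i, plan$group[r]] * 2^plan$log2fc[r]
    }
  }
  key <- profiles$proportions[, c("mirna", "d5", "d3", "nta")]
  prop <- profiles$proportions$proportion
  krows <- split(seq_len(nrow(key)), key$mirna)[mirnas]
  counts <- matrix(0, nrow(key), nrow(sheet),
                   dimnames = list(NULL, sheet$sample_id))
  alpha <- config$nb_dispersion
  for (j in seq_len(nrow(sheet))) {
    m <- group_means[, sheet$group[j]]
    lambda <- if (alpha > 0) stats::rgamma(n, shape = 1 / alpha, rate = 1 / (alpha * m)) else m
    lambda[lambda <= 0 | !is.finite(lambda)] <- 1e-12
    tot <- stats::rmultinom(1L, size = config$reads_per_sample, prob = lambda)[, 1L]
    for (i in which(tot > 0L)) {
      rows <- krows[[i]]
      if (length(rows) == 1L) {
        counts[rows, j] <- tot[i]
      } else {
        counts[rows, j] <- stats::rmultinom(1L, tot[i], prob = prop[rows])[, 1L]
      }
    }
  }
  structure(list(counts = isomir_matrix(tibble::as_tibble(key), counts),
                 mirna_counts = rowsum(counts, group = key$mirna, reorder = TRUE),
                 sample_sheet = sheet, group_means = group_means,
                 de_plan = plan, profiles = profiles, config = config),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$mirna_counts), "miRNAs,", nrow(x$counts$key),
      "isomiRs,", nrow(x$sample_sheet), "samples,",
      nrow(x$de_plan), "planted effects\n")
  invisible(x)
}

#' Emit FASTQ files for simulated counts
#'
#' One read per counted molecule: the isoform's templated precursor window
#' plus its non-templated tail, plus the configured adapter if any; constant
#' quality "I". Read names encode only sample and serial number.
#'
#' @param truth A `sim_truth` from [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of FASTQ paths, one per sample.
#' @export
emit_fastq <- function(truth, dir) {
  config <- truth$config
  set.seed(config$seed + 4L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- truth$profiles$proportions$read_sequence
  if (!is.null(config$adapter)) seqs <- paste0(seqs, config$adapter)
  sheet <- truth$sample_sheet
  paths <- character(nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    cnt <- truth$counts$counts[, j]
    reads <- rep(seqs, cnt)
    reads <- reads[sample.int(length(reads))]
    qual <- strrep("I", nchar(reads))
    ids <- paste0("@", sheet$sample_id[j], ":", seq_along(reads))
    path <- file.path(dir, paste0(sheet$sample_id[j], ".fastq"))
    writeLines(paste(ids, reads, "+", qual, sep = "\n"), path)
    paths[j] <- path
  }
  stats::setNames(paths, sheet$sample_id)
}

#' Run the full simulator
#'
#' @param config A `sim_config`.
#' @param fastq_dir If non-`NULL`, FASTQ files are written there.
#' @return The `sim_truth`, with an added `fastq` element when reads were
#'   emitted.
#' @export
simulate_dataset <- function(config, fastq_dir = NULL) {
  ann <- simulate_annotation(config)
  prof <- simulate_isomir_profiles(config, ann)
  truth <- simulate_counts(config, prof)
  truth$annotation <- ann
  if (!is.null(fastq_dir)) truth$fastq <- emit_fastq(truth, fastq_dir)
  truth
}
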