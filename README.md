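# tallmir

IsomiR-resolved small RNA-seq analysis of T-cell acute lymphoblastic
leukemia (T-ALL) subtypes.

## What this package is for

Bulk small RNA sequencing of leukemia cohorts poses a chain of analysis
problems that this package implements end to end, for analysts working on
T-ALL or comparable cohort designs:

1. **isomiR quantification.** Reads are assigned to miRNA precursors by
   exact substring matching and classified as isoforms of a mature miRNA.
   An isomiR is keyed by `(miRNA, d5, d3, nta)`: `d5` is the read start
   minus the canonical start on the precursor (negative = 5′ extension,
   positive = 5′ trimming), `d3` the read end minus the canonical end
   (positive = 3′ extension), and `nta` an optional 1–2 nt non-templated
   3′ tail (A/T mono- and dinucleotides are the dominant biological
   additions). The canonical form is `(0, 0, "")`.
2. **isomiR structure statistics.** Per-miRNA isoform diversity, the
   dominant isoform per miRNA, how often the canonical form is absent or
   non-dominant, and the correlation between isoform diversity and
   expression.
3. **Expression analysis.** A background filter (≥ 4 reads in
   ≥ ceil(60%) of the samples of one patient subgroup, or in all samples
   of one thymocyte subset), median-of-ratios size factors
   s_j = median_i ( k_ij / (∏_v k_iv)^(1/n) ) rescaled to geometric mean 1,
   log2(k/s + 1) normalization, sample PCA, and a negative-binomial Wald
   test per miRNA: gene-wise method-of-moments dispersion α, an NB
   log-link model μ_ij = s_j · exp(β₀ + β x_j) fitted by IRLS, z = β/SE(β),
   and Benjamini–Hochberg adjustment.
4. **Subtype signatures and candidate calls.** One-vs-rest contrasts across
   the four T-ALL subgroups (immature, TLX, TAL-R, HOXA), top-k signature
   selection, and classification of subtype-specific miRNAs against the
   matched normal thymocyte subset (immature ↔ CD34+, TAL-R ↔ CD4+CD8+):
   *arrest markers* (already high in the matched normal stage), *oncomiR
   candidates* (further elevated in leukemia) and *suppressor candidates*
   (reduced in leukemia); the flags are not exclusive.
5. **Synthetic data.** A simulator generates annotation, ground-truth
   isomiR counts and FASTQ reads with the cohort design above
   (13/14/15/6 patients + 2/2 thymocyte samples), log-normal baselines,
   NB sample variation, Dirichlet isoform mixtures with a configurable
   canonical-dominance probability, diversity coupled to abundance, and
   planted fold-changes — so every stage is testable against known truth.

## Worked example

The `analysis/` directory is a numbered workflow over the package; run it
from the repository root:

```sh
Rscript analysis/01_simulate.R       # cohort with planted effects
Rscript analysis/02_quantify.R       # FASTQ -> isomiR/miRNA count matrices
Rscript analysis/03_isomir_stats.R   # isomiR diversity and dominance
Rscript analysis/04_filter_normalize.R
Rscript analysis/05_signatures.R     # one-vs-rest subtype signatures
Rscript analysis/06_candidates.R     # arrest / oncomiR classification
```

Output printed by the run (tables land in `results/`, large intermediates
in `scratch/`):

```
Quantified 2600000 reads into 964 isomiRs over 198 miRNAs; all reads assigned uniquely.
198 miRNAs summarised; 24 carry a single isomiR; max 16 isoforms.
Canonical form dominant for 92/198 miRNAs, absent for 51/198.
Diversity-expression correlation r = 0.683 (log10 scale; raw scale r = 0.252).
135 of 198 miRNAs pass the background filter.
immature: 4 up / 6 down at adjusted p < 0.05
...
19 miRNAs differ between CD34+ and CD4+CD8+ thymocytes (adjusted p < 0.05).
Candidate calls over 10 subtype-specific miRNAs: 2 arrest markers, 7 oncomiR
candidates, 0 suppressor candidates (1 carry both arrest and oncomiR flags).
```

Reading this: quantification recovered the simulator's realised counts
exactly (no ambiguous or unassigned reads, because the generator emits only
unambiguous isoforms); about half of the expressed miRNAs have a
non-canonical dominant isoform, matching the generator's 0.5
canonical-dominance setting; isoform diversity rises with expression; and
the planted "high in CD34+, higher still in immature T-ALL" miRNA is the
one flagged as both an arrest marker and an oncomiR candidate.

## Layout

- `R/` — package code: `annotation.R` (FASTA/GFF3 + substring index),
  `simulate.R`, `quantify.R`, `isomir_stats.R`, `expression.R`,
  `signatures.R`.
- `analysis/` — the numbered workflow drivers.
- `tests/testthat/` — unit, property and acceptance tests (brute-force
  oracles live in `helper-fixtures.R`).
- `vignettes/tallmir-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations.
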