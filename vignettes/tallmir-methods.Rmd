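---
title: "Methods: isomiR quantification and subtype analysis in tallmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR quantification and subtype analysis in tallmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tallmir)
```

This vignette documents the models, rules and numerical decisions behind
the package, in the spirit of a methods section: what each stage assumes,
which parameters matter, and what the tests do and do not establish.

## 1. Reference frame: precursor space

All read assignment happens in **precursor space**: the annotation is a set
of miRNA hairpin (precursor) sequences plus mature-miRNA windows on them
(0-based half-open internally; 1-based inclusive at the GFF3 boundary, the
miRBase dialect). A genome-scale aligner would serve only to land reads on
miRNA loci; exact matching against precursors reproduces the same
per-miRNA assignment logic at desk scale, with two consequences that users
should keep in mind:

* no mismatch tolerance — sequencing errors make a read unassignable
  rather than nearly-assignable (a deliberate trade for unambiguous isomiR
  calls; genomic aligners typically allow mismatches);
* no genomic multi-mapping outside annotated precursors.

U is normalised to T on ingestion (sequencer output is DNA-alphabet) and
never emitted. Precursors are indexed by all 15-mers; a query is located by
looking up its 15-nt prefix and verifying the full string, which the test
suite checks against a naive full scan.

## 2. IsomiR classification

An isomiR key is `(miRNA, d5, d3, nta)` with the templated part of the read
equal to `precursor[canonical_start + d5 : canonical_end + d3]` exactly.
Signs follow the overhang/deletion convention: `d5 < 0` a 5′ extension,
`d5 > 0` a 5′ trimming; `d3 > 0` a 3′ extension, `d3 < 0` a 3′ trimming.
Display labels render as `5'+n`/`5'-n`, `3'+n`/`3'-n`.

The assignment rule for a trimmed read (length 15–30 nt):

1. For suffix trims `t = 0, 1, 2` in order, search the read minus its last
   `t` nt as an exact precursor substring. The first `t` that yields at
   least one **valid candidate** wins; the trimmed suffix becomes the
   non-templated tail.
2. A site is a valid candidate for every mature window it overlaps by at
   least 15 nt with `|d5|, |d3| ≤ 5` (hard caps; both configurable). The
   overlap floor and caps prevent assignment to the opposite hairpin arm.
3. Candidates are ranked by `|d5| + |d3|` (tail length is constant within a
   trim level, so the documented rank order — shorter tail first, then
   smaller offset — reduces to this). All top-rank candidates with
   *distinct* mature names split the read's weight equally
   (`ambiguous-split`); an identical key reached through several precursors
   (true paralogs sharing a mature sequence and name) counts once.

One reading decision deserves a note: "the first trim level with a site
wins" is ambiguous when a site exists but no mature window qualifies. The
package continues to the next trim level in that case, declaring
`unassigned` only after all levels fail; a random genomic-like match
without an annotated mature window should not block the recovery of a
tailed isoform. A tail that continues the template is never called
non-templated: the untrimmed (or less-trimmed) search finds the longer
templated window first, so templated extensions are classified as `d3 > 0`
rather than as tails.

Ties within one mature name (conceivable with unusual annotations) resolve
canonical-first, then lexicographically on `(d5, d3)` — deterministic and
order-independent, which the permutation tests rely on.

Adapter trimming truncates at the leftmost exact occurrence of the
adapter's first 8 nt; untrimmed reads are kept whole, and reads outside
15–30 nt after trimming are rejected. No base qualities are used anywhere.

Fractional counts (from ambiguous splits) are allowed in the matrices; the
differential expression stage rounds half-to-even before model fitting.

## 3. The synthetic cohort

The generator emulates the study design the analysis assumes; its defaults
are the cohort conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `groups` | 13/14/15/6 + 2/2 | immature, TLX, TAL-R, HOXA patients; CD34+ and CD4+CD8+ (DP) thymocyte duplicates |
| `reads_per_sample` | 5×10⁴ | documented desk-scale reduction of the study's ~14.4 M reads/sample |
| `n_mirnas` | 200 | precursors of 70–90 nt, one 20–23 nt mature each |
| `baseline_log_mean_sd` | 1.2 | SD of log10 baseline abundance (log-normal around 10²), spanning ~3 orders of magnitude as miRNA expression does |
| `nb_dispersion` | 0.2 | NB dispersion α, a typical patient-cohort value |
| `isomir_concentration` | 1 | Dirichlet concentration of isoform proportions |
| `p_canonical_dominant` | 0.5 | probability the canonical form is modal — chosen because roughly half of miRNAs in T-ALL cohorts are canonical-dominant |
| `p_canonical_present` | 0.5 | probability the canonical form appears at all when not modal (drives the canonical-absent fraction) |
| `diversity_coupling` | 2 | slope of E[extra isoforms] per log10 abundance |
| `de_fraction`, `de_log2fc` | 0.05, 2 | planted subgroup effects |

Counts are drawn as gamma–Poisson intensities conditioned on the library
size: per sample, miRNA intensities λᵢ ~ Gamma(1/α, ·) with mean equal to
the (possibly effect-shifted) group mean, and the `reads_per_sample` total
is split multinomially over λ. Conditioning keeps every sample at exactly
the configured depth (so conservation and exact-recovery tests are
well-defined) while preserving NB-like overdispersion across samples; as
α → 0 the variance/mean ratio approaches 1. It also means counts are
*compositional*: a planted fold-change on a miRNA that dominates the
library realises a smaller observed ratio. The moment-recovery test
therefore plants its effect on a mid-abundance miRNA.

Isoform supports are restricted to **exactly recoverable keys**: window
within the precursor, read length within 15–30 nt, ≥ 15 nt mature overlap,
tails that do not continue the template, and sequences occurring at exactly
one site (per mature name). Offsets span d5 ∈ [−2, 2], d3 ∈ [−4, 4] — the
short-offset regime dominant in real data — and tails come from
{A, T, AA, TT}. This is what makes the end-to-end identity property exact:
`quantify(emit_fastq(x)) == x` with no adapter and no paralogs. The
generator gives no quantitative model of real isomiR biochemistry; its only
job is to make recovery testable, and passing tests say nothing about
mismatch tolerance, quality-dependent errors, or real NTA enzymology.

Dominance is imposed by designating a modal isoform (canonical with
probability `p_canonical_dominant`) and swapping it the largest Dirichlet
proportion. FASTQ reads carry constant quality `"I"` and names encoding
only sample and serial number — no ground truth leaks through read names.
Every stage derives its RNG stream from `seed` plus a fixed per-stage
offset, so identical configurations give byte-identical FASTQ.

## 4. Filtering, normalization, differential expression

**Background filter.** A miRNA is retained iff some patient subgroup has
≥ `min_reads` (4) reads in ≥ ceil(`min_fraction`·group size) samples
(ceil is the strictest integer reading of "at least 60%"; with subgroup
sizes 13/14/15/6 this demands 8/9/9/4 samples), **or** some thymocyte
subset has ≥ 4 reads in *all* its samples. The second clause exists because
two-sample subsets can never reach a 60% quorum meaningfully; it also means
a miRNA expressed only in normal cells survives filtering. The filter is
monotone in added reads (property-tested).

**Size factors.** Median-of-ratios over miRNAs with nonzero counts in all
samples, rescaled to geometric mean 1 (an explicit identifiability
constraint; consequently a global depth constant moves into the normalized
values, not the factors — the factors' *ratios* remain scale-equivariant,
which is what the contrasts consume). If no miRNA is all-nonzero the error
message instructs lowering `min_nonzero_prop` to 0.9.

**Normalization.** `log2(count/s + 1)` — monotone, rank-preserving, and
adequate for PCA, signature ranking and heatmap ordering at desk scale. It
is *not* a variance-stabilizing transformation: low-count rows keep higher
relative variance, which is acceptable downstream of the background filter.

**NB Wald test.** Per miRNA: method-of-moments dispersion on normalized
counts pooled within groups, using Var(k/s) = μ·mean(1/s) + αμ² per group
and pooling the two group estimates with (n−1) weights, floored at 10⁻⁸;
then IRLS for `μ_ij = s_j·exp(β₀ + β x_j)` (weights μ/(1+αμ), convergence
|Δβ| < 10⁻⁸, ≤ 100 iterations, linear predictor clamped to ±30);
Wald z = β/SE from the Fisher information; two-sided normal p;
β reported in log2. All-zero rows are excluded with a status;
non-convergent fits are flagged with p = 1. There is **no**
empirical-Bayes dispersion shrinkage and no fold-change moderation: results
will differ from shrinkage-based tools, mildly liberally for low counts.
The calibration study (null cohort at the 13/14/15/6 + 2/2 design, 2000
miRNAs, background-filtered as the pipeline always is) measures a raw-p
false-positive rate of ~0.05–0.06 at α = 0.05, inside the accepted
[0.03, 0.07] band; the recovery study (planted log2FC = 2 on 5% of miRNAs)
reaches sensitivity ≥ 0.9 with FDR ≤ 0.1 at adjusted p < 0.05.

Two evaluation definitions in the recovery study are worth making
explicit. Sensitivity is computed over planted miRNAs that *pass the
background filter*: at 5×10⁴ reads over 2000 miRNAs many baselines sit
below detectability, and no method can recover what is never observed.
False discoveries are counted among *up*-significant calls in the wrong
contrast or on unplanted miRNAs; down-significant calls on planted miRNAs
in other subgroups' one-vs-rest contrasts are genuine consequences of the
mixture (the planted group sits in the "rest") and are not errors.

Multiple testing uses Benjamini–Hochberg throughout (the conventional
default where only "adjusted p-value" is specified), applied within each
contrast over its tested rows.

## 5. Signatures and candidate classification

"Subtype-specific" is operationalized as **one-vs-rest** significance among
the four patient subgroups (pairwise designs are not implemented). The
heatmap selection takes the k = 50 most significant miRNAs per subgroup
(ties: larger |log2FC|, then name) and deduplicates in subgroup order; the
top-10 tables rank *up*-significant miRNAs by mean normalized expression
within their subgroup.

Candidate classification fixes the matched normal subset by the
differentiation-arrest biology: immature ↔ CD34+, TAL-R ↔ CD4+CD8+; TLX and
HOXA have no matched subset and receive no calls. For a subtype-specific
miRNA, at adjusted p < 0.05:

* `arrest_marker` — up in the matched subset in the CD34-vs-DP contrast
  (sign interpreted per subset);
* `onco_candidate` — up in the subtype versus its matched subset;
* `suppressor_candidate` — down in the subtype versus its matched subset.

The flags are pure functions of the three DE tables and the threshold, and
deliberately not exclusive: the interesting pattern of a miRNA already high
in the matched normal stage but further increased in leukemia carries both
the arrest and the oncomiR flag. The thymocyte contrast has two samples per
subset, so only large effects reach significance there — matching the
reality that duplicate-level normal subsets support only coarse claims.

The pooled all-T-ALL vs all-thymocyte contrast reuses the same NB test with
simple pooling of the four thymocyte samples (no subset covariate — the
two-group model implemented here has no covariate slot, and four samples
would not support one).

Cell-line evaluation is reduced to within-sample percentiles of a
signature (`evaluate_signature_in_sample`): the median percentile of a
subtype's top-10 miRNAs inside one sample's expression distribution, which
is what a density-plot-with-markers display encodes; full hierarchical
clustering of cell lines is out of scope.

## 6. Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
these sizes, chosen as a deliberate desk-scale study: 200 miRNAs with
5×10⁴ reads/sample for read-level stages (one full cohort ≈ 2.6 M reads),
2000 miRNAs (counts only) for DE calibration and recovery, 10 seeds for
the canonical-dominance Monte-Carlo, 3 coupling levels × 5 seeds for the
diversity–expression monotonicity check, and 1000 random small matrices
for the filter-rule enumeration. All randomness flows from explicit integer
seeds; re-running any stage with the same configuration reproduces its
outputs byte-identically.

## 7. Known limitations

* Exact matching only: no mismatches, hence no RNA-editing or
  sequencing-error tolerance; interior variants are out of scope.
* No genomic context: reads from loci outside the supplied precursors are
  simply unassigned.
* The NB test has no dispersion shrinkage; very small groups (the HOXA
  subgroup, the thymocyte duplicates) get noisy dispersion estimates and
  correspondingly conservative discoveries only at large effects.
* The simulator does not model sequencing error, UMI structure, quality
  profiles, or real isomiR biochemistry.
* The correlation between diversity and expression is reported on
  log10(mean normalized expression + 1) as the primary scale (the raw
  scale is also returned); diversity–expression coupling in real data
  partly reflects detection depth, and the simulator reproduces that
  mechanism rather than a biological claim.
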