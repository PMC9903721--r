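---
title: "Models and methods behind mpraduo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpraduo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpraduo)
```

## The assay and the quantities this package computes

A dual-element massively parallel reporter assay (MPRAduo-style design)
pairs an activating cis-regulatory element (**E**, 150 bp) with a silencer
candidate (**S**, 200 bp) on one reporter construct, in both orders (ES,
SE), alongside single-element constructs. Constructs are identified by
synthesis barcodes — 20 nt for the S module and 10 nt for the E module —
and regulatory activity is the log2 ratio of mRNA tag counts to plasmid
(DNA) counts. The package implements the full computational path:

1. **Dictionary construction** (`build_dictionary`): merged association
   amplicons (`UMI + barcode + linker + oligo + linker`) are parsed with the
   cloning-vector adapter sequences as anchors, oligo segments are matched to
   the reference library, and every barcode whose reads map to more than one
   oligo is dropped outright. No majority vote is taken: a chimeric barcode
   is worthless however lopsided its read support.
2. **Tag counting** (`classify_tag_read`, `count_tags`): a tag read with
   fewer than 110 nt between the GFP-tail anchor and the 3' end carries one
   barcode (single construct); at or above 110 nt it carries two (duo). Duo
   reads count only when *both* barcodes are present in their dictionaries.
3. **Activity estimation** (`size_factors`, `log2_activity`,
   `summit_shift`, `quantile_normalize`): constructs are filtered on barcode
   multiplicity and mean DNA count (presets: ≥20 barcodes / DNA ≥100 for
   benchmark-scale libraries; ≥10 / ≥20 for genome-scale ones), samples are
   rescaled by median-of-ratios size factors, each RNA replicate yields
   `log2((RNA + 1) / (pooled DNA + 1))`, and the mode of the negative
   controls is shifted to zero.
4. **Statistics** (`repression_call`, `emvar_test`, `group_compare`,
   `fisher_enrichment`, `delta_median_categorize`): silencer calls against
   the empirical negative-control distribution, paired-replicate allelic
   skew (emVar) t-tests, Mann–Whitney group comparisons, Fisher enrichment,
   and cofactor Δmedian categorization, all with Benjamini–Hochberg
   correction.
5. **Motif machinery** (`scan_pwm`, `half_sites`, `pair_half_sites`,
   `scramble_motif`, `allele_delta_score`): log2-odds PWM scanning on both
   strands, half-site pairing with spacer/orientation classes, motif
   scrambling with rejection, and per-allele delta scores.
6. **The m-value** (`fit_piecewise`, `estimate_m_value`): the motif-intrinsic
   score boundary above which a REST-class motif confers silencing, estimated
   as the change point of the score-versus-repression relationship and
   averaged across element × cell combinations.
7. **The log-additive duo model** (`fit_log_additive`): ordinary least
   squares of duo activity on the two single activities and their
   interaction, `eDuo = b0 + bS*eS + bE*eE + bSE*eS*eE`.

## PWM scores

Scores are log2-odds sums, `sum_j log2(p_j(base) / 0.25)`, with one total
pseudocount per column distributed by the uniform background. `N` bases
score zero (background). Two calibrated boundaries are kept distinct on
purpose: the **m-value** (default 20.86), the strength boundary used by
`classify_strength` (strictly above = strong; a tie is weak, because the
boundary is defined as the score *above which* repression switches on), and
the genome-scan reporting threshold (default 20.89) used when screening
variants and negatives. Half-site models are columns 1–9 (left) and 12–21
(right) of the full 21-column matrix; the canonical arrangement is left
then right on the same strand with a 2-bp spacer, and the spacer is always
`right.start − left.end − 1` in 1-based closed coordinates. Orientation
classes for non-canonical pairs (spacer < 100 bp, summed score above the
m-value): `atypically_spaced` (same order, other spacer), `flipped`
(right before left), `convergent`/`divergent` (opposite strands facing
inward/outward).

The package ships a **synthetic** 21-column RE1-like PFM
(`synthetic_re1_pfm()`) with exactly uniform spacer columns 10–11, a mix of
column strengths (maximum score ≈ 32), and therefore fine enough score
granularity that `plant_motif` can hit any target in [min, max] within 0.5.
It is a constructed stand-in shaped like the canonical RE1 motif, not a
database matrix; analyses of real data should load the real matrix with
`read_jaspar()`.

## Change-point estimation

`fit_piecewise` re-implements the iterative linearization familiar from
segmented regression: at the current break ψ, regress on
`{x, U = (x − ψ)+, V = −1[x > ψ]}` and update `ψ ← ψ + coef(V)/coef(U)`.
Two numerical choices matter:

* the update is **step-halved** whenever it would increase the segmented
  residual sum of squares, so the fixed-point iteration settles instead of
  oscillating around the optimum; and
* the iteration is **seeded from the best of a coarse interior grid**
  (5%–95% quantiles of x) plus `psi0` (default 20), so it converges in the
  global RSS basin rather than a local one.

The slope-change p-value is the t-test of the `U` coefficient at the final
break; with a perfectly interpolating fit the p-value is set to 1 when the
slope change is zero and 0 otherwise. `estimate_m_value` averages the break
points over combinations after excluding fits that are not converged, have
non-positive or non-significant slope change (p ≥ 0.05 — the operational
reading of requiring an obvious shift of the correlation), have an
essentially unidentified break (`psi_se` ≥ 1 score unit), or park the break
in the outer 10% of the fitted score range. The last two criteria are this
package's additions: break-free series fitted with a free change point
typically land at a range edge with a large ψ standard error, and both
diagnostics flag exactly that failure mode without touching genuine interior
breaks. Both are configurable and every exclusion is reported with its
reason.

## The synthetic-experiment generator

`sim_design()` fixes the study conditions used throughout validation:

| parameter | default | meaning |
|---|---|---|
| `n_S`, `n_E`, `n_neg` | 500, 5, 100 | silencer candidates, activating elements, negative controls |
| `motif_score_range` | [15, 30] | planted motif scores (log2-odds) |
| `true_changepoint` | 20.86 | score above which silencing switches on |
| `silencer_slope` | −0.5 | log2 activity per score unit above the change point |
| `log_additive_betas` | (−0.03, 0.86, 0.68, −0.06) | duo composition (ES orientation) |
| `depth`, `nb_dispersion`, `n_replicates` | 100, 0.05, 5 | mean DNA count, NB dispersion, replicates |
| `barcodes_per_S`, `barcodes_per_E` | 20–40, 10–20 | barcodes per oligo |
| `multi_frac` | 1% | barcodes deliberately assigned to two oligos |

Counts are negative binomial with variance `m + α·m²` (α = 0 degenerates to
Poisson), RNA means are `depth · 2^activity · size factor` with
per-replicate size factors drawn log-uniformly in [0.5, 2], and all
randomness flows from one seed through named streams (`stream_seed`), so
identical designs reproduce bit-identical libraries, counts and reads. The
`silencer_slope` of −0.5 per log2-odds unit is a generator choice (a strong
motif ~9 units above the boundary represses by ~4.5 log2 units, the scale of
a potent silencer); barcode-per-oligo ranges are likewise generator choices
exposed in the design. True duo activity is composed log-additively from
the single-element truths, so the duo model, the m-value and the silencer
calls can all be checked against planted parameters.

What the generator deliberately does **not** emulate: PCR amplification
bias, UMI duplication structure, indel sequencing errors, GC-matched genomic
background (sequences are i.i.d. uniform outside planted spans), and
paired-end merging artifacts. Passing tests therefore demonstrate the
correctness of the computational pipeline under the stated count model, not
robustness to every artifact of real sequencing chemistry.

## Numerical and design choices

* **Pseudocount 1** on normalized counts before the log-ratio: avoids −∞ on
  RNA dropouts and matches common reporter-assay practice.
* **DNA pooled across replicates** (mean of normalized DNA): the plasmid
  pool is shared across transfections, so per-replicate DNA mostly adds
  noise; the ratio-based activity deliberately replaces a full
  dispersion-shrinkage DE analysis, and the emVar test consumes
  replicate-level ratios rather than Wald statistics.
* **Summit-shift mode estimator** is fixed and recorded: Gaussian KDE,
  Silverman (`nrd0`) bandwidth, 512-point grid over the negatives' range.
  At least 20 negative controls are required; with fewer the mode is too
  unstable to anchor a library-wide shift.
* **Quantile normalization** reassigns rank means; tied observations get
  the mean of their tied ranks' values, so exact equality of sorted columns
  holds for tie-free data.
* **Repression calls** are z-scores against the empirical negative-control
  distribution with BH correction within strata (cell type × E element by
  default). The per-construct statistic behind a "repressed at 1% FDR" call
  is the one genuinely open design point in this pipeline; the z-test was
  chosen because the negative-control set is large enough (hundreds) to
  estimate its null location and scale directly.
* **emVar testing** is the two-sided one-sample t on per-replicate skew
  `d_i = alt_i − ref_i`, flagged at BH-adjusted p ≤ 0.01. All-zero skews
  report p = 1; constant non-zero skews report p = 0 rather than an
  undefined t.
* **Exact small-sample tests**: Mann–Whitney comparisons enumerate exactly
  when both groups have ≤ 8 tie-free observations; Fisher's test reports
  the sample odds ratio `ad/bc` (∞/0 at empty cells) next to the
  hypergeometric p-value.
* **Oligo matching** (`map_oligo`) replaces aligner-based mapping with a
  defined rule: exact hash, then 15-mer seeded candidates scored by
  Levenshtein identity with a 0.95 default threshold; ties are ambiguous,
  never guessed. Amplicon linkers allow ≤2 substitutions and no indels —
  parsing is positional once the anchors are found.
* **Tag-read barcode matching is exact.** At 10–20 nt and typical depths,
  error-correcting barcodes risks chimeric counts; reads with unknown
  barcodes are tallied, never rescued.

## Problem sizes used in validation

The shipped tests and the acceptance script run the generator at its default
conditions (500 silencer candidates × 5 E elements, 5 replicates, depth
100) for activity recovery and the m-value; a benchmark-style configuration
(19 E elements × 300 S) for the duo model, where many distinct E activities
identify the E coefficient well; n = 2,000 points for single change-point
recovery; and 10 × 1,000 null variants for emVar error control. Read-level
round trips use 150–500 oligos. These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite stays
interactive.

## Known limitations

* Coefficients of the duo model fitted on *measured* single activities are
  attenuated by errors-in-variables — visibly so for the E coefficient when
  only a handful of E elements span a narrow activity range. The acceptance
  report therefore fits it on the benchmark-style simulation; on real data
  the same caveat applies to any regression of duo on single activities.
* The slope-change p-value is computed at the estimated break and inherits
  the usual anti-conservativeness of post-selection t-tests; the m-value
  exclusion rule compensates with the identifiability and edge criteria
  rather than a formal break-existence test (Davies-type tests are out of
  scope).
* FIMO p-value/q-value semantics are not reproduced; scores are compared
  only against thresholds calibrated in the same log2-odds scheme.
* Orientation of duo constructs is a sample-level label, not inferred per
  read; demultiplexing and paired-end merging are assumed upstream.
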