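# mpraduo

Analysis of **dual-element massively parallel reporter assays** (MPRAduo-style
designs): reporter libraries that pair an activating cis-regulatory element
(E) with a silencer candidate (S) on a single construct, in both orders,
alongside single-element libraries. The package is written for regulatory
genomicists quantifying silencer activity — in particular RE1/NRSE elements
bound by REST — from barcode-tagged sequencing data, and for anyone who
needs the statistical core of such an assay reproducible and testable
offline.

## What it computes

Activity of a construct is the normalized log2 ratio of mRNA tag counts to
plasmid DNA counts. From raw reads to biology, the pipeline covers:

* **Barcode→oligo dictionaries** from merged association amplicons
  (`UMI + barcode + linker + oligo + linker`), with approximate linker
  anchoring, seeded Levenshtein matching of oligo segments, and a strict
  drop rule for barcodes mapping to more than one oligo.
* **Single/duo tag counting**: reads with fewer than 110 nt between the
  GFP-tail anchor and the 3' end carry one barcode, others two; duo reads
  count only when both barcodes are in their dictionaries.
* **Normalization**: barcode/DNA filters (presets ≥20/≥100 benchmark,
  ≥10/≥20 genome-scale), median-of-ratios size factors,
  `log2((RNA + 1)/(DNA + 1))`, summit-shift normalization (the mode of the
  negative controls is moved to zero), and rank-based quantile
  normalization across libraries.
* **Statistics**: silencer calls against the empirical negative-control
  distribution, allelic-skew (emVar) t-tests on per-replicate
  `alt − ref` differences, Mann–Whitney and Fisher tests, ChIP-peak
  overlap annotation (reciprocal-50% either-rule), and cofactor Δmedian
  categorization — all BH-corrected.
* **Motif analysis**: log2-odds PWM scanning of both strands, weak/strong
  classification against the **m-value** (the empirically estimated score
  boundary, default 20.86, above which a REST-class motif silences),
  half-site pairing with spacer/orientation classes (canonical 2-bp spacer,
  atypically spaced, flipped, convergent, divergent), motif scrambling with
  rejection, and per-allele delta scores for variants.
* **Change-point regression**: the m-value itself comes from piecewise
  linear fits of motif contribution versus motif score
  (`fit_piecewise`, a damped, grid-seeded iterative linearization) pooled
  across element × cell combinations (`estimate_m_value`).
* **Log-additive duo model**: `eDuo = b0 + bS·eS + bE·eE + bSE·eS·eE`
  fitted by OLS (`fit_log_additive`, `predict_duo`).
* **A seeded synthetic-experiment generator** (`sim_design`,
  `make_library`, `simulate_counts`, `simulate_reads`) with known ground
  truth for every stage, so the whole stack is testable without sequencing
  data.

## Worked example

Simulate a genome-scale-style experiment (500 silencer candidates × 5 E
elements, 5 replicates), recover activities, call silencers, and estimate
the m-value:

```r
library(mpraduo)

design <- sim_design(seed = 42)
lib    <- make_library(design)
counts <- simulate_counts(lib$library, lib$truth, design)

filtered <- filter_constructs(counts, min_barcodes = 10, min_dna_mean = 20)
tc       <- lib$truth$constructs
neg_ids  <- tc$construct_id[!is.na(tc$S_id) & grepl("^NEG", tc$S_id) &
                            tc$orientation == "single-S"]
act <- summit_shift(log2_activity(filtered), neg_ids)
act
#> activity_table: 3605 constructs, 5 replicates, summit shift -0.1295 applied

calls <- repression_call(act, neg_ids, alternative = "less", fdr = 0.01)
sum(calls$called)
#> [1] 1137

score_of <- setNames(lib$truth$elements$motif_score, lib$truth$elements$oligo_id)
cons <- act$constructs
fits <- list()
for (e in unique(na.omit(cons$E_id))) {
  ix <- which(cons$orientation == "ES" & !is.na(cons$E_id) & cons$E_id == e &
              !is.na(cons$S_id) & grepl("^S", cons$S_id))
  fits[[e]] <- fit_piecewise(score_of[cons$S_id[ix]], -act$activity[ix], psi0 = 20)
}
fits[["E01"]]
#> changepoint_fit: psi = 20.9499 (se 0.1206), slopes 0.0087 -> 0.3784,
#>   slope-change p = 1.37e-130, R2 = 0.956, converged (n = 500)

estimate_m_value(fits)$m_value
#> [1] 20.90
```

Reading the output: 3,605 constructs pass the genome-scale filters; 1,137
are significantly repressive at 1% FDR (the generator plants silencing in
every S element whose motif score exceeds the change point, composed into
every duo); each E element's score-versus-repression relationship breaks at
ψ ≈ 20.9, and the pooled m-value estimate, 20.90, recovers the planted
boundary of 20.86.

A thin command-line wrapper over the same functions lives in
`inst/scripts/mpraduo-cli.R` (subcommands `simulate`, `pipeline`, `match`,
`count`, `scan`, `halfsites`, `delta`, `mvalue`, `duomodel`).

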