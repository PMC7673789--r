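---
title: "Scaling of mutational effects on exon inclusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling of mutational effects on exon inclusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiscale)
```

## The model

The percent spliced in (PSI) of an exon is the percentage of mature
transcripts that include it. A mutation's observed effect on inclusion,
ΔPSI, depends strongly on the exon's starting inclusion level: an exon
at 99% PSI has almost no room to move, an exon at 50% has the most. The
package separates the two with a single inclusion-independent
*efficiency effect* `A` per mutation. Given `A` and a starting level
`PSIs`,

$$PSI_{final} = \frac{100 \cdot A \cdot PSI_s}{100 - PSI_s + A \cdot PSI_s},
\qquad \Delta PSI = PSI_{final} - PSI_s.$$

`A = 1` is neutral, `A < 1` promotes skipping, `A > 1` promotes
inclusion. The map is a fixed point at `PSIs` ∈ {0, 100} for every
finite `A`, so `|ΔPSI|` vanishes at the boundaries and attains a single
interior maximum — the reason mutations rarely alter the inclusion of
highly-included (or fully skipped) exons. The algebraic inverse,

$$A = \frac{PSI_s^2 - 100\,PSI_s + \Delta PSI \cdot PSI_s - 100\,\Delta PSI}
{PSI_s\,(\Delta PSI + PSI_s - 100)},$$

recovers `A` from a measured ΔPSI. Both directions are exposed as
`predict_final_psi()` and `estimate_A()` and round-trip to relative
1e-6 across `A` ∈ [1e-3, 1e3].

A note on conventions: the forward formula is sometimes written with
"ΔPSI" on its left-hand side, but it returns `PSIs` at `A = 1` and its
printed inverse is exactly the inverse of the *final*-PSI reading. We
therefore implement the right-hand side as the final PSI and define
ΔPSI as final minus start — the only interpretation consistent with
both directions.

Degenerate inputs are handled explicitly rather than silently:

* a measured final PSI at or above 100 leaves `A` unbounded; the record
  is flagged *saturated* (`NA` plus a count) and excluded from effect
  distributions;
* a final PSI below 0 (possible under measurement noise) inverts to a
  negative `A`, which is clipped to 0 with a warning and a count;
* neutrality is exact: `predict_final_psi(1, p)` returns `p` itself,
  not `100 * p / 100`.

## Rescaling distributions and confidence bands

A set of `A` values estimated from one exon's mutagenesis data
(`effect_distribution()`) predicts the ΔPSI *distribution* for any exon
whose inclusion level is known (`rescale_effects()`) — not the effect
of any individual mutation. `density_with_band()` estimates the pooled
density of rescaled effects with a Gaussian kernel, bandwidth 5 PSI
units on a 512-point grid spanning the pooled range plus three
bandwidths on each side (no boundary reflection), and attaches a
pointwise percentile band from bootstrap resampling: each of 2500
replicates resamples every source distribution with replacement,
rescales and re-estimates the density on the same grid. The band level
is a parameter (default 0.95 from the 2.5th/97.5th percentiles; 0.99 is
the other conventional choice). All randomness flows from one integer
seed; the same seed gives bit-identical output.

Threshold summaries (`fraction_exceeding()`) default to the inclusive
convention `|ΔPSI| ≥ threshold` ("by at least 10 PSI units"); a strict
flag reproduces "more than 10" phrasings.

## DMS scoring

`score_variants()` turns a table of per-variant input/output read
counts into enrichment scores: per replicate, a variant's raw score is
its output frequency over its input frequency; normalised scores divide
by the wild type's, so WT scores exactly 1 and `psi = psi_wt * es_norm`.
Because frequencies (not counts) enter the ratio, scoring is invariant
to sequencing-depth differences between replicates. The standard error
is the package's own simplified error model: per-replicate Poisson
count variance propagated through the ratio by the delta method, plus
the empirical between-replicate variance of the normalised scores. A
pooled-input flag supports designs whose input replicates are technical
rather than biological. Variants with no input reads in any replicate
are dropped (counted, not imputed); an optional +0.5 pseudocount flag
exists for sparse libraries.

High scores can imply PSI > 100. `bayes_correct()` rescales each score
into the admissible range [0, `es_max` = 100/`psi_wt`]: 1000 evenly
spaced candidates `k`, each weighted by the Normal(`es`, `se²`) density
at `k`, returning Σ(P·k)/Σ(P) — the posterior mean under a flat prior
on the admissible range. Two numerical choices: the density (rather
than a two-sided tail probability) is used as the weight, which yields
the same posterior mean after normalisation; and the grid sum uses
trapezoid endpoint weights, since full weight on the two boundary
points biases boundary-concentrated posteriors by more than the
correction itself. The result agrees with a fine-grid numerical
posterior mean (and with the closed-form truncated-normal mean) to
better than 1e-3 for measurements within two standard errors of the
admissible range.

The corrected scores are then re-centred (`mode_adjust()`): the mode of
the corrected-score distribution, estimated by a Gaussian kernel
density with Silverman's rule-of-thumb bandwidth (the bandwidth is not
prescribed anywhere, so the default rule is used and logged), is
shifted onto the WT score. This relies on single-mutant score
distributions spiking at the WT score, which holds when a substantial
fraction of mutations are splicing-neutral.

`psi_from_junctions()` is the simple junction-based quantifier: PSI =
100·inclusion/(inclusion+exclusion), returned missing below 10 total
reads (the `minReads` convention).

## Genome-wide prediction

`summarize_bimodality()` reports the fraction of (exon, tissue) PSI
entries at intermediate inclusion (default 10–90%), both per exon and
length-weighted (each exon's PSI counted once per nucleotide — computed
with exact weights, not by materialising repeats).
`predict_genomewide()` draws `round(length × samples_per_nt)` effects
per exon from a chosen distribution (default one per nucleotide;
`samples_per_nt` can be lowered for desk-scale runs — the analysis
scripts use 0.25–0.5) and converts each through the scaling law at the
exon's inclusion level in the chosen tissue. Exons missing in a tissue
are excluded for that tissue; exons at exactly 0 or 100 contribute
zeros (fixed points). Per-exon sampling is keyed on the exon identifier,
so results are independent of row order. `pool_distributions()`
concatenates effect distributions when an analysis should combine all
available mutational datasets.

## Allele-dosage effects

`fit_allele_effect()` regresses per-sample exon PSI on allele copies
(0/1/2) by ordinary least squares: `delta_psi` is twice the slope (the
change associated with homozygosity; the model stays additive in
copies, no dominance term), and the intercept extrapolates the starting
PSI even when homozygous-reference samples are absent. Pairs with a
missing value are dropped, not imputed; fewer than 20 complete pairs
(configurable — no canonical minimum exists, so the default is
conservative) or zero dosage variance flags the record unestimable.
Fits whose intercept falls outside [0, 100] are removed outright —
never clamped. No multiple-testing correction is applied: p-values are
used only for pruning, and the analyses report effect distributions,
not significance calls.

`prune_per_event()` keeps one allele per splicing event (smallest
p-value; exact ties break by distance to the exon midpoint, then
lexical variant id) and records whether the winner is exonic or
intronic so that an event claimed by one class is excluded from the
other class's analysis. `bin_equal()` produces equally-populated
starting-PSI bins (sizes differ by at most one; ties on the key break
on variant id, so binning is order-invariant), reporting per bin the
fraction of effects beyond 10 PSI units and the median magnitude.

`classify_exons()` calls an exon constitutive when its PSI meets the
threshold (default 90) in *every* tissue with data, alternative when it
falls below the alternative threshold in at least one; with unequal
thresholds the gap between classes is labelled `NA`.
`compare_exon_classes()` fits `ΔPSI ~ starting_psi + class` and reports
the class coefficient with its t-test p-value;
`class_threshold_sweep()` recomputes the coefficient over a grid of
definitions (the conventional sweep is 50 × 50 thresholds from 50 to
99). `condition_delta()` aligns per-construct PSI between two
conditions (cell types, intron contexts) into records ready for
binning, with the first condition as the starting PSI.

## The synthetic-data generator

Every input the pipeline consumes can be generated from one
`sim_config(seed)`; all generators are pure functions of the
configuration and emit ground-truth tables alongside the data, and all
recovery tests read truth only from those tables. The defaults describe
the study conditions the analyses assume:

* **DMS block** — a 63-nt exon at `psi_wt = 49` (intermediate
  inclusion, the regime where mutations act most strongly), all 189
  single-nucleotide substitutions plus the WT, 3 replicates at 1e6
  reads each (mini-gene DMS is sequenced to ~1e4 reads per variant).
  Efficiency effects are a mixture: 60% splice-altering, log-normal
  with meanlog −0.1 and sdlog 0.5 — chosen so that roughly 43% of such
  mutations move a PSI-50 exon by ≥10 units, the magnitude typical of
  intermediate-inclusion mutagenesis — and 40% splicing-neutral,
  log-normal(0, 0.05). The neutral component is what makes the score
  distribution spike at the WT score; without it the mode adjustment
  has no mode to find. A single log-normal cannot simultaneously
  reproduce the heavy loss-of-function tail seen in real libraries
  (e.g. a few percent of mutations still shifting a 99%-included exon
  by ≥10 units); this is a known simplification. Output counts weight
  each variant by input frequency × true PSI / `psi_wt`, the
  inclusion-band readout.
* **Atlas block** — per-(exon, tissue) PSI from a three-component Beta
  mixture: sharply included Beta(40, 1), sharply skipped Beta(1, 40)
  (split 60/40, reflecting the predominance of highly-included exons
  among quantifiable events) and intermediate Beta(2, 2), with the
  intermediate weight solved analytically so the pooled 10–90% fraction
  equals a target (default 0.28). Lengths are log-normal around 120 nt
  (typical internal exons); 5% of entries are masked missing (events
  under the read threshold). It mimics the pooled bimodal shape of
  tissue atlases without claiming to reproduce any particular one.
* **Cohort block** — 300 samples, common variants (allele frequency
  uniform on [0.05, 0.5]; rarer alleles are out of scope by
  construction), Hardy–Weinberg genotypes. A variant with effect `A` on
  an exon starting at `p` gives expected PSI `p` for 0 copies,
  `predict_final_psi(A, p)` for 2, and the midpoint for 1 —
  additive-in-PSI, matching the fitted dosage model (a dominance knob
  exists but defaults off). Gaussian noise with sd 5 PSI units is added
  without re-clipping to [0, 100]: clipping would bias the planted
  effects near the boundaries, and the noise stands for estimation
  scatter rather than a physical PSI.
* **Sequence block** — random backgrounds with enhancer hexamers
  implanted at non-overlapping positions, 1.5× the rate in constitutive
  exons. The motif set itself is grown with a connectivity parameter
  (probability of adding a neighbour of an existing motif instead of a
  random hexamer), which controls the robustness-score spectrum; a
  request implying more than 18 mutual neighbours is rejected, since a
  hexamer has exactly 18 single-substitution neighbours. Classes are
  interleaved across sequence identifiers so id-based tie-breaks carry
  no class signal.

What passing tests on these data do **not** show: the generator has no
linkage disequilibrium, no read-level sequencing errors, no
splice-site-strength structure, and its PSI noise is Gaussian rather
than count-derived. Recovery results demonstrate that the estimators
are correct and calibrated under the model's own assumptions, not that
those assumptions hold in any particular experimental dataset.

## Hexamer analytics

Density analyses count *occurrences* (overlapping 6-nt windows whose
content is in the motif set), normalised by exon length; robustness
counts motif *types*. `suboptimal_set()` is the union of all 18
single-substitution neighbours over a motif set (a member of the input
appears in the output exactly when it neighbours another member).
`robustness_score()` counts how many of a motif's 18 neighbours are
themselves motifs; scores 0–18 are all reported, though published
groupings often start at 1. `mutational_motif_scan()` enumerates all
3 × length point mutations and, for each one destroying at least one
enhancer occurrence, counts occurrences lost (overlapping occurrences
can fall together), enhancer occurrences gained at *other* windows (a
same-window replacement — identical six coordinates — is not a cryptic
gain) and silencer occurrences gained. Sequences are scanned on the
annotated sense strand only. Weak/strong splice-site subsets, where
used, take the bottom/top 20% of externally supplied scores within the
dataset at hand.

## Sizes, tolerances, defaults

| Parameter | Default | Where |
|---|---|---|
| density bandwidth | 5 PSI units | `density_with_band()` |
| density grid | 512 points | `density_with_band()` |
| bootstrap replicates | 2500 | `density_with_band()` |
| band level | 0.95 | `density_with_band()` |
| Bayesian grid | 1000 points | `library_config()` |
| junction read minimum | 10 | `psi_from_junctions()` |
| effect threshold | 10 PSI units, inclusive | `fraction_exceeding()` |
| allele frequency minimum | 0.05 | `filter_common_snvs()` |
| regression sample minimum | 20 | `fit_allele_effect()` |
| constitutive / alternative threshold | 90 / 90 PSI | `classify_exons()` |
| draws per nucleotide | 1 (0.25–0.5 in the analysis scripts) | `predict_genomewide()` |

The test suite runs the DMS recovery at the default library size (189
variants, 3 × 1e6 reads), the atlas checks at 2000–10000 exons, the
cohort recovery at 120–500 variants × 300 samples and the genome-wide
mixture at up to 1e4 draws — sizes chosen so the whole suite completes
in about a minute while keeping Monte-Carlo error well inside every
asserted tolerance. Coordinates are 0-based half-open internally; PSI
is always on the 0–100 scale in every file; missing values serialise as
`NA`.

## A worked example

```{r example}
cfg <- sim_config(seed = 1)
dms <- gen_dms(cfg)
scored <- dms_pipeline(dms$counts, library_config(cfg$dms$psi_wt))
scored <- scored[scored$variant_id != "WT", ]
dist <- effects_from_deltas(scored$psi_corrected - 49,
                            rep(49, nrow(scored)), "simulated library")
# the same mutations, projected to a highly-included exon:
c(at_50 = fraction_exceeding(rescale_effects(dist, 50)),
  at_99 = fraction_exceeding(rescale_effects(dist, 99)))
```

The projected fraction of large-effect mutations collapses as the
starting PSI approaches 100 — the central prediction of the scaling
law, and the package's reason to exist.

## Known limitations

The efficiency effect is a single scalar per mutation: epistasis
between mutations and any mechanistic (thermodynamic) derivation of the
law are out of scope, as are full splicing-event annotation, raw read
processing, covariate-adjusted QTL mapping and LD-aware pruning (the
per-event pruning here is p-value-based only). Splice-site scoring is
consumed as external input, never computed.
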