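---
title: "Methods: mitochondrial DNA variation in aging tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial DNA variation in aging tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtaging)
```

## Scope and model

`mtaging` analyses three classes of somatic mitochondrial DNA variation in
bulk-tissue whole-genome sequencing cohorts: large deletions (structural loss
of at least ~50 bp producing a junction between distal positions of the
circular 16,569-bp genome), single-nucleotide variants classified by
heteroplasmy level, and mtDNA copy number estimated from relative coverage.
The package consumes upstream caller outputs (junction tables with read
support, mutserve-style allele-frequency tables, coverage summaries); it does
not align reads or call variants itself.

## Coordinates and the reference

All coordinates are 1-based inclusive on the rCRS (NC_012920.1). Spans with
`start > end` wrap through the origin. The vendored reference FASTA was
reconstructed offline from the NC_001807.4 (hg19 chrM) sequence distributed
with seqinr by applying the divergence sites between that Yoruba genome and
the rCRS; the result is verified byte-exact against the canonical rCRS MD5
(`c68f52674c9fb33aef52dcf399755519`, the `chrM` M5 tag of GRCh38 sequence
dictionaries), so it is the genuine reference, not an approximation. A unit
test asserts this checksum.

The feature catalog hard-codes the standard rCRS gene map. The respiratory
complex totals it implies are Complex III 1141 bp, IV 3010 bp, V 888 bp and
I 6356 bp; a figure of 6536 bp sometimes quoted for Complex I is not
consistent with the standard ND-gene coordinates (it appears to be a digit
transposition), so the package reports the computed 6356. Microprotein
spans: mtALTND4 11,557–11,856, SHMOOSE 12,234–12,410 (the occasionally
printed end "122,410" is treated as a typographical error; 12,410 is the
only end consistent with a microprotein under 100 aa), gau 6,288–6,590.
Humanin, MOTS-c and SHLP1–6 use literature open reading frames inside the
two rRNA genes; only their containment in 1,343–3,052 and minor-arc location
matter for impact analysis at this granularity. The minor arc is defined as
positions 110–5,798 (heavy-strand origin region through the light-strand
origin OL); this reproduces the expected arc labels for all 11
microproteins.

## Deletion conventions and burden metrics

Junction breakpoints `bp5`/`bp3` are the last and first *retained* bases, so
the deleted span is `[bp5 + 1, bp3 - 1]` and the size is `bp3 - bp5 - 1`.
This convention makes the canonical common-deletion junction 8,471–13,449
remove exactly 4,977 bp. Burden metrics per sample:

* deletions per 10k coverage — unique `(bp5, bp3)` junctions divided by MT
  benchmark coverage (mean depth of two 250-bp segments in RNR1 and CYB),
  times 10,000. No minimum-read filter is applied by default (`min_reads`
  exposes one), matching unfiltered caller output.
* cumulative deletion read % — sum of per-junction read percentages
  (supporting reads normalised to benchmark coverage, stored as percents
  0–100 throughout).
* the same stratified at 1,000 bp, the Top-30 catalog sum, and the common
  deletion alone. Top-30 membership is exact-junction match; the shipped
  default catalog contains the common deletion plus synthetic placeholders
  (the published list lives in a prior publication's supplement) and should
  be replaced for real analyses.

A deletion impacts a feature when the deleted span shares at least one base
with it (`removed` when fully contained, `truncated` otherwise); a complex
is impacted when any member gene is.

## Junction repeats

Deletion formation by mismatched pairing requires two homologous tracts in
register: one ending the retained 5' segment (around `bp5`), the other
ending the deleted segment (around `bp3 - 1`). `max_direct_repeat()`
therefore compares the two neighbourhoods on a single alignment diagonal:
the repeat is the longest consecutive run of offsets `i` in
`[-window, window]` at which the base at `bp5 + i` equals the base at
`bp3 - 1 + i` (case-insensitive, `N` never matches; ties resolved by
proximity to the junction, then leftmost). An independent-offset definition
(each copy free to slide within its window) was evaluated and rejected: it
finds spurious off-register matches that a junction caller's breakpoint
ambiguity cannot produce, and fails to reproduce known junction repeat
lengths, whereas the in-register definition recovers the canonical 13-bp
common-deletion repeat (8,470–8,482 = 13,447–13,459) and published
allele-induced repeat changes exactly. The window default reflects repeat
motifs of roughly 6–22 nt and a 10-bp association-proximity filter; it is
configurable. Circular wrap inside windows is disabled by default
(junctions of interest are far from the origin).
`repeat_delta()` re-runs the search after substituting an allele, giving the
(reference, alternate) repeat-length pair whose sign `classify_delta()`
maps to lengthens/shortens/neutral.

## Variant classes, haplogroups, copy number

A variant with caller allele frequency at least 0.9 is homoplasmic, strictly
between 0.1 and 0.9 heteroplasmic, at or below 0.1 excluded. The frequency
is taken as the caller's variant allele frequency (a literal minor-allele
frequency could never reach 0.9). Haplogroup dichotomisation is purely
label-based: labels starting with H or V (including HV precursors) are
"HV", everything else "NonHV" — K, J, T and U stay NonHV regardless of
phylogenetic ancestry, mirroring the binary split used in cohort analyses.
Copy number is `2 * mt_depth / autosomal_depth` (copies per diploid cell);
the autosomal mean depth is consumed precomputed.

## Statistics

* Age models for deletion metrics use exponential regression: OLS on
  `ln(metric + 0.01)` with covariates; `bin_delta()` converts a fit into the
  metric change over a 15-year age bin, evaluated at a user-supplied
  covariate profile (defaulting the profile to covariate means is the
  caller's choice; no canonical profile exists for covariate-adjusted bins).
* Rank-based regression minimises Jaeckel's dispersion with Wilcoxon scores
  `a(i) = sqrt(12) (i/(n+1) - 1/2)`. With one predictor the exact solution
  (weighted median of pairwise slopes) is used; with several, Nelder-Mead
  from the OLS start (the objective is piecewise-linear convex; tolerance
  1e-10, two restarts). The intercept is the residual median. Wald
  p-values use a Koul–Sievers–McKean window estimate of the scale parameter
  tau with a delta = 0.8 pairwise-difference quantile bandwidth shrunk by
  n^(1/5) and a degrees-of-freedom correction; different tau estimators
  produce slightly different p-values, which is the expected source of
  small numerical differences from other rank-regression implementations.
* Group comparisons: Kruskal–Wallis H (tie-corrected) followed by Dunn z
  tests on pooled ranks, Bonferroni-adjusted; Bonferroni is the only
  multiplicity method in the package.
* 2x2 size-distribution contrasts use Pearson's chi-squared with Yates
  continuity correction (the correction never overshoots zero).

## MT-GWAS

Within each region separately, SNP:deletion pairs are eligible when the
deletion occurs in at least 10 subjects, both SNP allele classes have at
least 10 carriers, and the SNP lies within 10 bp of either breakpoint. The
model regresses binary SNP presence on the pair's deletion read % plus
benchmark coverage, age and sex — this orientation is kept deliberately
(a `reverse_model` flag provides the conventional orientation for
sensitivity analysis). Samples lacking the deletion contribute read % 0;
the full region cohort enters every model. The genome-wide threshold is
0.05 divided by the region's number of eligible pairs, recomputed per
region and never pooled; untestable pairs (constant response) still count
toward that number. `gwas_report()` joins each association with the
repeat-length change of its alternate allele and flags mechanistic
consistency: the allele with the longer repeat should associate with more
deletion.

## Synthetic cohort

The generator emulates the structure of a two-region brain aging cohort:
143 FC-like and 149 CER-like samples, ages uniform on 0.4–100 years,
HV fractions 60/143 and 72/149, autosomal depth Normal(34.28, 4.04).
Copy number is Normal per region (FC 4536.805 ± 1376.705, CER
1367.205 ± 687.661) with linear age slopes of −193.23 and −37.14 copies per
15 years; the residual SD is reduced so the total SD matches the target.
Homoplasmic SNV counts are Normal by region and haplogroup category
(NonHV ≈ 31–34, HV ≈ 12), heteroplasmic counts Poisson with a positive age
slope in FC only.

Deletions are generated from a deterministic catalog of ~1,200 junctions
whose first entries are the common deletion and three junctions with
breakpoint-proximal catalog SNPs; sampling weights are heavy at this head
(so canonical junctions appear in nearly every sample, as needed for
association eligibility) and near-flat over the tail (supplying per-sample
junction diversity). A 50-junction catalog cannot support the ~75 unique
junctions per sample that the burden targets imply at realistic
mitochondrial coverage, which is why the catalog is this large. Per sample,
the number of observed junctions is Poisson with a rate calibrated to the
deletions-per-10k target at the sample's benchmark coverage and age; that
many distinct junctions are then drawn by weight. A drawn junction's read %
follows `exp(b0_j + b_read * age + eps) - 0.01` conditioned on clearing the
detection floor (supporting reads must round to at least one), drawn by
inverse-CDF from the left-truncated lognormal; `b0_j` is calibrated with
closed-form truncated-lognormal means, averaged over an age grid, so the
cohort mean cumulative read % matches its target (realised region means sit
within ~15% of the configured values; the region fold changes land on
target). The log-noise SD is 0.6, chosen so that the configured burden
levels remain detectable above the floor across the age range. Age growth
is split between the per-junction read % slope (FC 0.025/yr, CER 0.018/yr)
and the junction-count slope (0.015, 0.010), so cumulative read % grows at
roughly their sum — above the ln(2)/30 = 0.023 per year needed for a
15-year bin to at least double between ages 30–45 and 60–75.

Because the detection floor left-truncates read percentages, the log-scale
age slope an OLS fit can recover from an observed junction metric is
slightly below the raw `b_read` parameter. The generator therefore reports,
in `$derived$common_deletion_log_slope`, the estimand its process implies
for the common-deletion metric among carriers — the slope of
`E[log(read% + 0.01) | carrier, age]`, computed in closed form with the
inverse-Mills correction — and parameter-recovery tests target that
estimand.

`plant_association()` shifts one junction's read % by a configurable
multiple of its cohort SD in carriers of a chosen SNP allele, leaving all
other quantities untouched; it is the ground truth for association-recovery
and family-wise-error tests.

What the generator does **not** emulate: cell-to-cell heteroplasmy
heterogeneity, breakpoint micro-heterogeneity around hotspots, sequence-
context-dependent junction formation, haplogroup-specific SNV positions
(background homoplasmic positions are placed on an arbitrary grid), or any
correlation between copy number and deletion burden beyond their shared age
dependence. Passing tests therefore demonstrate that the pipeline's
estimators recover known generating parameters under realistic effect and
noise scales — not that real tissue satisfies the generative assumptions.

## Numerical choices and problem sizes

Tolerances: dispersion minimisation 1e-10; regression equalities in tests
1e-6 to 1e-9; simulation-based checks use seeded replicates with binomial
tolerances. Degenerate inputs: constant responses yield zero slopes with
p = 1 rather than errors; empty deletion tables yield all-zero metrics;
wrapping junctions are measured circularly and flagged. Test and acceptance
runs use scaled-down cohorts (20–150 samples per region, 30–100 seeded
replicates), sizes chosen to keep each property's Monte-Carlo error well
inside its asserted margin.

## Known limitations

The rank-regression tau estimator is one of several reasonable choices;
p-values differ in the third decimal from other implementations. The
association scan fits one pair at a time with no linkage or phylogenetic
correction, matching its reference design. The Top-30 default catalog is a
placeholder outside the common deletion. Haplogroup handling consumes
labels; no inference from variants is performed.
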