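---
title: "Orthogonal-protease isobaric hyperplexing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal-protease isobaric hyperplexing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultraplex)
```

## The problem

Isobaric labeling (TMT/TMTpro) lets a mass spectrometer quantify up to 18
samples in one run, one sample per reporter channel. Hyperplexing multiplies
that capacity by pooling several independently labeled sub-experiments
("subplexes") into one injection and separating them computationally. The
strategy this package models separates subplexes by *protease*: one half of
the samples is digested with LysC (cleaves C-terminal to lysine), the other
half with trypsin applied after TMT labeling of lysines, so that lysine
cleavage is chemically blocked and only arginine sites remain active
("TrypR"). Because every LysC peptide ends in K (except protein C-termini)
and every TrypR peptide ends in R, the two digests produce essentially
non-overlapping precursor populations, and a database search with the
matching enzyme rule assigns each spectrum to its digestion arm.

Capacity is then multiplicative:

$$N = n_\text{proteases} \times n_\text{barcode states} \times \sum_k |T_k|$$

where $|T_k|$ are the sizes of the tag sets used per protease. Two proteases
with TMT11 + TMTpro18 give $2 \times (11 + 18) = 58$ channels; a 35-plex
reagent set gives 92; adding a three-state peptide barcode on top of a
dual-protease 35-plex design reaches 210.

`capacity()`, `build_58plex_reference()` and `validate_design()` implement
this arithmetic and the reference layout: four subplexes (LysC-TMT11,
LysC-TMT18, TrypR-TMT11, TrypR-TMT18), a common bridge sample in channels
126, 127N, 127C, 128N of every subplex, four cell lines distributed
round-robin over the 42 remaining channels, and an E. coli lysate spiked at
1 or 0.5 micrograms per channel (expected log2 ratio 1 between the levels).
The per-channel cell-line layout is a documented balanced reference, not a
reconstruction of any particular bench run; the bridge pool, being one
physical sample, carries one spike level (1 microgram) in all subplexes.

## Digestion model

`digest()` enumerates every peptide bounded by active cleavage sites with at
most `max_missed` internal sites. A site is active when the residue is in
the rule's cleave-after set, is not chemically blocked, and — for
proline-inhibited rules — is not immediately followed by P. The three rules
share this single kernel:

| rule   | cleave after | proline-inhibited | blocked |
|--------|--------------|-------------------|---------|
| LysC   | K            | no                | —       |
| TrypR  | K, R         | yes               | K       |
| TrypKR | K, R         | yes               | —       |

TrypR is deliberately represented as trypsin with blocked lysines rather
than a bespoke R-only enzyme, so the same kernel serves the TrypKR rule used
by quality-control searches. LysC is modeled *without* proline inhibition
(it cleaves K-P bonds); this is a documented flag, since the literature on
LysC's proline behavior is mixed. Peptide coordinates are 0-based half-open
internally (`coords_to_one_based()` converts); non-canonical residues (B, J,
O, U, X, Z) are rejected outright so that masses stay deterministic.

Specificity QC follows the convention of a K/R search: a cleavage event is
the peptide's C-terminal residue (unless it is the protein C-terminus) plus
every internal K/R not followed by P. A peptide with zero R events is
"lysine-specific", one R event is "single arginine", and so on
(`specificity_profile()`). The fractions are unweighted peptide counts —
no intensity or charge weighting — because the premix QC that motivates
them reports plain percentages of peptides.

Masses use a pinned monoisotopic residue table, water 18.0105647 Da and
proton 1.007276466 Da. The label registry carries TMT6plex +229.1629 and
TMTpro +304.2071 at K/N-term, carbamidomethyl +57.0215 (C), oxidation
+15.9949 (M) and deamidation +0.984 (N/Q). `peptide_ions()` expands peptides
over charges {2, 3, 4} by default — the bulk of observed precursors for
these longer single-residue-specific peptides — and
`precursor_orthogonality()` reports the fraction of one ion population
within a 10 ppm window of the other (the typical precursor tolerance),
in both directions.

## The simulator

`simulate_quant()` generates protein-level reporter signal-to-noise tables
for any validated design from a seeded ground truth
(`make_ground_truth()`):

* human proteins: per-protein log-normal base abundance (meanlog
  $\log 100$, sdlog 1) with per-(protein, cell line) offsets of
  `cell_line_effect_sd` log2 units (default 0.5, a moderate biological
  contrast between cell lines); the bridge sample is the pool (mean) of the
  cell lines;
* E. coli proteins: per-protein base abundance times the channel's spike
  micrograms, so the truth ratio between 1 and 0.5 microgram channels is
  exactly 2.

Coisolation interference — the mechanism behind ratio compression in
MS2-based reporter quantification — is modeled with a single mixing
fraction $\alpha$:

$$\text{observed}_{pc} = (1 - \alpha)\,x_{pc} + \alpha\,\bar{x}_{p\cdot}$$

where $\bar{x}_{p\cdot}$ is the protein's mean true abundance over the
subplex's channels, standing in for the co-isolated precursor population.
Multiplicative log-normal noise with coefficient of variation
`measurement_cv` (default 0.1, median 1 so ratios stay centered), a
signal-to-noise scale factor, and uniform missingness (default 5% of
entries set to 0) follow. The defaults $\alpha_{MS2} = 0.35$ and
$\alpha_{MS3} = 0.08$ encode the *ordering* of the two acquisition modes —
MS3 with synchronous precursor selection suffers far less interference —
and were chosen so that ordering holds robustly; they are tunable and are
deliberately **not** calibrated to reproduce any particular measured median.

What the simulator does *not* emulate: spectrum-level effects
(peptide-to-protein rollup, ion statistics, injection time),
intensity-dependent dropout (missingness is uniform so the normalization
tests stay interpretable), and reporter isotope impurities (simulated
values are post-correction by construction). Passing tests therefore
demonstrate the statistical chain's correctness under the stated model, not
performance on raw instrument data.

## The normalization chain

The statistical pipeline (`normalize_pipeline()`) runs in a locked order;
each step records itself in a provenance log and refuses to run before its
prerequisite:

1. **Master-protein filter** — keep proteins with at least one nonzero
   value within a subplex (`filter_master_proteins()`); proteins quantified
   in *all* subplexes are flagged as the core set.
2. **Zero replacement** — zeros become 0.1 (linear S/N) so ratios and logs
   are defined (`replace_zeros()`; idempotent).
3. **Median normalization + log2** — each column is scaled so its median
   equals the grand median of column medians, then log2 is applied
   (`median_normalize_log2()`). The grand-median target is a choice: it
   preserves the overall scale while equalizing columns.
4. **Bridge scaling** — for each protein and subplex, the mean of the
   protein's bridge-channel log2 values is subtracted from all of that
   subplex's columns (`bridge_scale()`). This row-wise reading is the
   standard internal-reference-scaling interpretation and makes every
   protein directly comparable across subplexes; a column-wise variant (one
   scalar shift per subplex) is available behind `method = "column"` for
   comparison.
5. **Global centering** — each column is centered at zero using only core
   proteins (`global_center()`; idempotent), so subplex-specific proteins
   cannot shift the common zero.

Post-conditions, each enforced to 1e-9 in the tests: every (protein,
subplex) bridge mean is 0 after step 4; every column's core-protein mean is
0 after step 5.

`mad_harmonize()` divides each column by its raw median absolute deviation
(constant 1, **not** 1.4826): the purpose is equalizing dynamic range
between MS2-like and MS3-like tables, not estimating a normal sigma, so the
consistency factor would only introduce an arbitrary common scale.

The chain is defined for the human proteome. Spike-in accuracy is computed
separately and earlier: `spike_log2_ratios()` takes the **raw** S/N table
and, for each E. coli protein and high-spike channel, computes log2(value /
mean of the protein's nonzero low-spike channels in the same subplex). The
within-subplex low-spike mean is the chosen denominator — the natural
reference given that spike levels are assigned per channel within a
subplex. `spike_accuracy()` reports the median over all (protein, channel)
pairs plus a derived compression index $1 - \text{median}/\text{expected}$
(a convenience summary specific to this package).

Protein CVs (`protein_cv()`) use the population standard deviation
(n divisor) over linear-scale, bridge-anchored abundances; with replicate
groups from `replicate_groups()` they summarize within- and between-subplex
reproducibility.

## Numerical and design choices

* Ties and degenerate inputs: zero-MAD columns, empty core sets, empty ion
  lists and zero labelable sites raise errors naming the offender rather
  than propagating NaN.
* m/z follows $(M + z \cdot m_p)/z$ with $m_p$ = 1.007276466 Da; the
  round-trip $z \cdot m/z - z \cdot m_p = M$ holds to 1e-9.
* The simulator uses a single RNG stream per call, seeded from the noise
  model and recorded in the table metadata; identical seeds give
  bit-identical tables.
* Labeling efficiency is per-site by default (labeled / labelable over
  N-termini and lysines), with a per-PSM flag, since site-level counting is
  the finer-grained and more conservative of the two readings.
* Venn overlap reporting uses the 15 disjoint regions of a four-set
  diagram; the four-way region as a fraction of the union is the headline
  "core proteome" number.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic data
sized for a single CPU: ground truths of 150–1000 human and 50–300 E. coli
proteins, random digestion sequences up to 200 residues, and Venn sets up
to a few thousand elements. The spike-recovery check uses 300 E. coli
proteins with interference off and 10% measurement noise, where the median
spike log2 ratio lands within 0.05 of the expected 1.0.

## Known limitations

* Orthogonality is assessed at the precursor m/z level only; retention
  time, fragmentation and FDR machinery are out of scope.
* The interference model is a one-parameter mixture with a subplex-mean
  background; real coisolation depends on local precursor density and
  isolation purity, so $\alpha$ should be read as an effective, not a
  physical, fraction.
* The 35-plex tag set is represented by synthetic channel labels; only its
  size enters capacity arithmetic.
* No peptide-to-protein summarization: the simulator emits protein-level
  tables directly, which is where the published statistical chain starts.
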