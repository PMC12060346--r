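---
title: "Calling conserved sex-biased miRNA markers of thermal history in fish gonads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling conserved sex-biased miRNA markers of thermal history in fish gonads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirheat)
```

## The problem

In several farmed fish with polygenic sex determination — the European sea
bass (*Dicentrarchus labrax*) foremost — elevated water temperature during a
thermosensitive window of early development skews populations toward males.
A marker of that thermal history would have to satisfy two conditions at
once: it must separate ovary from testis reliably across species (so the
signal is about sex biology, not one lineage's idiosyncrasy), and it must
still differ between heat-treated and control gonads long after the
exposure. miRNAs are good candidates: their seed regions (nucleotides 2–8
of the mature strand, the primary determinant of target recognition) are
deeply conserved, and gonadal ovary/testis expression panels exist for many
fish species.

`mirheat` implements that two-condition screen as a tested pipeline:

1. **Differential expression** in a four-group focal design — female/male
   × control/high temperature (FCT, FHT, MCT, MHT) — via a
   negative-binomial Wald test on median-of-ratios-normalized counts.
2. **Cross-species conservation** of expressed seeds over ten fish species
   (UpSet-style exclusive intersections, relative abundance, shared top-k).
3. **A deterministic sex-bias rule**: per species, the log2 ratio of
   testis to ovary mean CPM; a conserved marker must be biased the same
   way (|log2| ≥ 1) in at least five of the ten species, the focal species
   among them.
4. **Heat-recorder calling**: the intersection of (1) and (3) — conserved
   sex-biased markers that are still differentially expressed in a
   within-sex heat contrast.

A synthetic-data module generates both the focal experiment and the
ten-species panel with planted, known effects, so every stage is testable
without any sequencing download.

## The count model and its differential-expression stage

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$ and a single dispersion $\alpha$ per miRNA. For a
contrast of groups $A$ and $B$ the test statistic is built exactly as
follows (no shrinkage, no outlier refitting, no independent filtering):

* counts are divided by median-of-ratios size factors computed on the two
  groups' samples (reference features are the rows with no zero count);
* group means $m_A, m_B$ of the normalized counts give
  $\log_2\!\mathrm{FC} = \log_2\frac{m_B + 0.5}{m_A + 0.5}$ (the 0.5
  pseudo-mean avoids a log of zero);
* a per-miRNA moment dispersion
  $\hat\alpha = \max\!\big(0, (\mathrm{pooled\ var} - \mathrm{pooled\
  mean})/\mathrm{pooled\ mean}^2\big)$, clamped at $10^{-8}$, feeds the
  delta-method standard error
  $\mathrm{SE}^2 = \big[(1/m_A + \hat\alpha)/n_A + (1/m_B +
  \hat\alpha)/n_B\big]/\ln(2)^2$;
* $z = (\log_2\mathrm{FC} - \mathrm{lfc}_0)/\mathrm{SE}$ is referred to
  the standard normal two-sided, and Benjamini–Hochberg adjustment runs
  across the miRNAs that survive the low-count filter (at least 10 reads
  in at least 10 samples of the full matrix, evaluated once globally —
  the 14-sample design makes a per-contrast "10 samples" requirement
  impossible for within-sex contrasts, so the filter is deliberately
  global).

Significance is `adj_p < 0.05` against a null log fold change of 0.

**Calibration, measured honestly.** With $n = 4$ vs $4$ and a moment
dispersion estimated from the same eight samples, the Wald $z$ behaves
like a $t$ statistic with roughly six degrees of freedom referred to a
normal: its measured null type-I error at nominal 0.05 is ≈ 0.098 (the
acceptance suite estimates it over ten replicate simulations of 2,000
null miRNAs). Two consequences worth knowing:

* raw p-values are anticonservative by about a factor of two at the 0.05
  tail, and more in the far tail;
* that far-tail inflation propagates through BH: at the default
  configuration (300 miRNAs) we measure on the order of 5–10 BH-significant
  null miRNAs per run rather than the nominal handful expected at
  FDR 0.05. A shrinkage-based engine would do better; this package
  deliberately keeps the simple moment test and documents its behaviour
  instead. Detection of strong planted effects is nevertheless reliable:
  for planted |log2 FC| in [2, 4] at mean CPM ≥ 100 the measured
  sensitivity is ≈ 0.95 (it is ≈ 0.77 exactly at the |log2 FC| = 2
  boundary — power at the boundary is genuinely modest at these sample
  sizes).

## The sex-bias rule and its conventions

For each species the per-miRNA statistic is
$\log_2(\text{testis mean CPM}/\text{ovary mean CPM})$, with a pseudocount
of 1 CPM substituted for a zero operand (a miRNA not expressed in one
tissue) so ratios stay finite. Conventions the implementation fixes, where
more than one reading was defensible:

* **Inclusive threshold.** A species is biased at $|\log_2| \ge 1$
  (boundaries inclusive).
* **Mean over replicates.** "Expressed" and the ratio operands are
  replicate-mean CPM per species and tissue; an `any-sample` alternative is
  exposed in `pipeline_config()`.
* **Absence is not zero.** A species contributes a ratio for an id only if
  the id is in that species' annotation; an annotated id missing from one
  tissue's profile counts as zero there (and takes the pseudocount).
* **Identity level.** Cross-species identity can be keyed by mature name
  or by seed (`level` argument of `sex_ratio_table()`); mature-name level
  reproduces the published marker table, seed level sums mature variants
  sharing a seed within a species before the ratio.
* **Determinism.** Marker tables are sorted by call, then descending
  maximum tally, then id; top-k ties break lexicographically.

A conserved marker needs at least five same-direction biased species
*including the focal species* (default `dla`). The bundled reference table
(`gonadal_marker_table()`) carries 33 published marker rows with their
per-species ratios, published DEM assignments, and published tallies. Note
that for several rows the published count O/count T differ by one from a
direct tally of the published ratios; the package applies the stated rule
and keeps the published tallies alongside so the discrepancy is visible
rather than silently reconciled.

## Heat-recorder calling and the concordance label

A marker is *informative* if it is a DEM in any of the four contrasts
(1 = MHT vs MCT, 2 = FHT vs FCT, 3 = MCT vs FCT, 4 = MHT vs FHT), and a
*heat-recorder* if a within-sex heat contrast (1 or 2) is among them. The
concordance label reads the sign of the heat response against the marker's
conserved signature: a positive heat log2 FC strengthens the marker's own
signal in the heated gonad (`marker_sex_concordant`, e.g. an ovary-biased
marker rising in heated testes — a feminine signature in heated males),
a negative one suppresses it (`marker_sex_discordant`, e.g. a testis-biased
marker falling in heated testes). When both heat contrasts flag a marker,
contrast 1 supplies the sign; this tie-break is arbitrary but fixed and
reported alongside the per-contrast fold changes, which are all kept in the
record.

## What the synthetic data emulates — and what it does not

`simulation_config()` defaults encode the study conditions of the focal
system: ~300 miRNAs; replicates FCT 3, FHT 3, MCT 4, MHT 4 (six ovaries,
eight testes); tissue-asymmetric library sizes (ovary 6.7×10⁵, testis
1.03×10⁶ — the reported per-library means scaled down tenfold so the test
suite runs in seconds at identical relative structure); NB dispersion 0.2,
the standard bulk small-RNA noise level; baseline expression log-normal
(log2 relative abundance ~ Normal(5, 2)) normalized to a miRNome
composition summing to 10⁶ CPM, so configured library sizes are realized
in the column sums; a ten-species panel with 60% core (shared) seeds, the
rest private to exactly one species, three replicates per species and
tissue, and a mild per-species baseline wiggle (log2 sd 0.25). Planted
sex-bias effects are applied symmetrically (half up in the biased tissue,
half down in the other, so log2 T/O equals the planted effect and total
abundance is roughly conserved); planted effect sizes in tests use
|log2| in [2, 4], within the range observed for real conserved markers.
One RNG stream per stage, seeded from `rng_seed` by fixed offsets, keeps
outputs byte-identical for a given configuration and unperturbed when a
stage is added.

The generator does **not** emulate: sequence-level reads or isomiR
structure; phylogenetic covariance among species effects (each species'
wiggle is independent, whereas real divergence is tree-structured);
compositional interference between planted effects (a large planted
change slightly rescales every other miRNA's realized CPM — negligible at
the default effect sizes); or annotation error across species. Passing
recovery tests therefore demonstrates that the *rules* behave as
specified under NB noise, not that the pipeline is robust to
misannotation or to correlated evolution.

## Numerical and degenerate-input choices

* Dispersion clamp $10^{-8}$; pseudo-mean 0.5 in the fold change; a group
  mean of zero yields an infinite SE and hence $z = 0$, $p = 1$ (a miRNA
  seen in only one group can never be called — the low-count filter
  removes almost all such rows first).
* `size_factors()` requires at least one zero-free row and errors
  otherwise; `cpm()` errors on a zero library, naming the sample.
* `bh_adjust()` validates inputs into [0, 1]; adjustment is the standard
  step-up with enforced monotonicity, capped at 1.
* DNA-style `T` in input sequences is mapped to `U` with a warning;
  sequences shorter than 8 nt are rejected rather than padded.
* All-zero profiles error on `relative_abundance()` ("empty miRNome");
  empty expressed sets are allowed.

## Problem sizes used by the test and acceptance suites

The suites simulate at the default scale (300 miRNAs × 14 samples; ten
species × two tissues × three replicates), with 2,000-miRNA matrices for
the null-calibration estimate and 10–50 replicate simulations where a
Monte-Carlo average is needed. These sizes were chosen so the full suite
exercises every stage at the study's own design shape while remaining
quick on a single CPU.

## Known limitations

* The DE stage's FDR is not controlled at its nominal level at these
  sample sizes (see the calibration note above); treat `adj_p` as a
  ranking score calibrated by simulation rather than a strict FDR bound.
* The marker rule is a deterministic threshold classifier; it comes with
  no significance statement across species, and its tallies inherit every
  convention above (pseudocount, inclusive boundary, mean-CPM operands).
* Reproduction of the published marker table is at mature-name level, the
  level of the published rows; when several mature miRNAs share a seed the
  two identity levels can genuinely disagree.
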