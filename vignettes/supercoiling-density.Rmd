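---
title: "Measuring plasmid supercoiling density by topoisomer band counting"
author: "topogel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plasmid supercoiling density by topoisomer band counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topogel)
```

## The model

A covalently closed circular DNA molecule obeys the topological identity
`Lk = Tw + Wr`: the linking number partitions into twist (winding of the
strands about the helix axis) and writhe (coiling of the axis in space).
Topoisomers — molecules identical in sequence but differing in integer
`Lk` — separate on agarose gels as discrete bands, and the writhe of the
most abundant ("major") topoisomer, normalised by the relaxed twist
`Tw = N/h`, defines the supercoiling density

$$\sigma = \frac{Wr_\mathrm{native}}{Tw}.$$

Negative $\sigma$ means underwound DNA, positive means overwound. For a
thermophile two systematic effects separate the writhe seen on a gel from
the writhe in the cell:

1. **Temperature.** The helical rotation per base pair shrinks by about
   0.011° per °C of heating. Cooling a plasmid from growth temperature
   $T_g$ to electrophoresis temperature $T_e$ tightens the helix; at
   constant `Lk` the extra twist is absorbed as negative writhe:
   $$\Delta Wr_\mathrm{temp} = (T_e - T_g)\,\frac{0.011\,N}{360}.$$
   For a 5455 bp plasmid moved from 85 °C to 24 °C this is −10.17, i.e.
   10 negative supercoils after rounding.
2. **Intercalation.** Chloroquine locally unwinds the duplex, shifting
   apparent writhe positive at constant `Lk`. Rather than modelling drug
   binding, the shift is measured operationally as the difference between
   the major-topoisomer writhes of a paired gel run with and without the
   drug on the same sample.

The native writhe is then
$Wr_\mathrm{native} = Wr_\mathrm{apparent} - \Delta Wr_\mathrm{chl} -
\Delta Wr_\mathrm{temp}$, implemented in `native_writhe()` and
orchestrated by `run_two_gel_protocol()`. Corrections are rounded to
whole supercoils by default (`round_corrections`), because a topoisomer
ladder quantises writhe in integers; the fractional values remain
available for sensitivity analyses. Reports print $\sigma$ to 4 decimal
places; internal values are full precision.

Why a *pair* of gels? A strongly supercoiled population runs as a single
saturated front band in a drug-free gel — individual topoisomers cannot be
counted. Adding chloroquine to the first dimension relaxes the apparent
writhe into the countable range. The drug-free gel of a *resolvable*
control sample then calibrates the chloroquine shift, which can be reused
for samples whose own drug-free lane saturates. `run_two_gel_protocol()`
makes this explicit: a saturated reference lane raises a
`topogel_front_band_error` unless an externally calibrated
`delta_wr_chl` is supplied — it never extrapolates silently.

A worked chain: apparent majors +14 (with 1.5 µg/ml chloroquine) and −5
(without) give $\Delta Wr_\mathrm{chl} = +19$; with $\Delta
Wr_\mathrm{temp} = -10$ the native writhe is $14 - 19 + 10 = +5$ and
$\sigma = 5/519.52 = +0.0096$. The same corrections applied to an
apparent major of −8 give $Wr = -17$ and $\sigma = -0.0327$.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `helical_repeat` | 10.5 | bp/turn | B-DNA under standard conditions; overridable per plasmid |
| `temp_coefficient` | 0.011 | deg/°C/bp | magnitude of the helix-angle change; treated as condition-independent |
| `chloroquine_unwinding` | 2.322e-3 | turns/(µg/ml)/bp | one-point calibration: 19 supercoils at 1.5 µg/ml on 5455 bp; simulator only |
| `round_corrections` | `TRUE` | — | whole-supercoil counting |
| `mobility_saturation_wr` | 30 | supercoils | front-band threshold of the virtual gel |
| `band_width` | 0.6 | position units | Gaussian band SD (band spacing is 100/30 ≈ 3.3 units) |
| `prior_df` (`simple_de_test`) | 10 | df | strength of the variance moderation |
| `r2_min` (`exponential_window`) | 0.99 | — | log-linearity required of the growth window |

## The virtual gel: what it emulates, what it does not

`sample_topoisomers()` draws a population whose integer writhe follows a
Gaussian over integers — the standard thermal-ensemble shape of topoisomer
ladders — and `render_gel()` maps each species through the correction
chain to an *effective* writhe and then to a migration position. Mobility
is a saturating piecewise-linear function of |effective writhe|: strictly
increasing up to the saturation writhe, constant beyond (the front band);
relaxed and nicked species co-migrate at position zero. Only qualitative
migration facts are available to constrain this map, so the simplest
monotone saturating form was chosen — it is easy to invert and sufficient
for round-trip validation. The linear chloroquine model is calibrated on a
single point (19 supercoils at 1.5 µg/ml); extrapolating it to
second-dimension concentrations (7.5 µg/ml would predict ~95 turns)
ignores binding saturation, so the simulator treats second-dimension
chloroquine purely as an arc-separating device and makes no quantitative
claim at high drug concentrations.

Consequences for interpretation: passing round-trip tests show that band
detection, counting, and the correction arithmetic are mutually
consistent and exactly invertible under the model's assumptions. They do
not validate the mobility law against physical electrophoresis, nor
densitometry of real gel images, lane distortions, or background
gradients — real lanes must be profiled externally before entering
`detect_bands()`.

Two honest limits of 1D counting are surfaced rather than papered over.
First, when the effective writhe of a population spans both signs, bands
at ±k co-migrate and the ladder folds; `two_gel_round_trip()` flags such
lanes unresolvable (in practice the second gel dimension resolves the
sign). Second, band counting only ever yields writhe *relative to a
reference band*; the round trip anchors the register on simulator ground
truth, mirroring the experimental requirement for an explicit reference,
and `assign_writhe()` refuses to guess one.

## The synthetic transcriptome and SRG calling

The three-strain design separates two causes of expression change: an
expression-burden effect shared by the active and catalytically dead
enzyme strains, and a supercoiling-specific effect present only in the
active strain. `generate_synthetic_counts()` plants exactly this
structure — supercoiling-responsive genes shift only in `gyrAB`,
burden-responsive genes shift equally in `Y119F` and `gyrAB`, null genes
nowhere — as negative-binomial counts. Defaults: 1000 genes in fractions
0.1/0.1/0.8, |log2FC| = 2 with random sign, dispersion 0.1, 4 replicates
per strain, baseline means log-normal(log 200, 1). The baseline
distribution and the symmetric effect direction are generic bulk-RNA-seq
choices; real transcriptomes add features the generator deliberately
omits (length and GC biases, correlated genes, operon structure,
outlier samples), so recovery results bound what the *set logic* can do,
not what any DE tool achieves on real data.

`simple_de_test()` uses median-of-ratios normalization and a two-sided t
statistic on `log2(normalized count + 1)` whose per-gene pooled variance
is shrunk toward the across-gene median with 10 prior degrees of freedom
(empirical-Bayes moderation in the style of limma). With 4 replicates a
plain per-gene t has only 6 residual degrees of freedom and cannot reach
useful power at Benjamini–Hochberg-corrected thresholds; moderation is
the standard remedy and keeps the statistic self-contained. The SRG set
is, by definition, the DEG set of the active-versus-dead comparison under
strict thresholds `p_adj < 0.05` and `|FC| > 1.25` (boundary genes
excluded, both directions pooled). Threshold strictness and
two-sidedness follow the convention of volcano-plot gating. DEG counts
published for any real dataset depend on the external DE engine and its
shrinkage and are not targets of this package.

`zscore_rows()` uses the population-SD convention (n denominator) and
maps constant rows to zeros with a warning. `fpkm()` takes the total
mapped fragment count from the caller rather than recomputing it from
alignments. `scan_consensus()` coordinates are 1-based and inclusive;
reverse-strand windows are matched against the reverse complement but
reported at the forward coordinate of the window start, and an `N` in the
subject sequence counts as a mismatch against every consensus class.

## Growth and retention

`specific_growth_rate()` fits `log2(density)` against time, so the slope
is directly in divisions·h⁻¹; the literal linear slope `dY/dt` is
available behind `log2_transform = FALSE` but carries density units, and
the two must not be mixed. `exponential_window()` automates the usual
by-eye choice of the "linear portion": the longest contiguous run with
log2-linear R² ≥ 0.99 (earlier run on ties), with a classed error rather
than a silent fallback when no run qualifies. Retention is the
selective/non-selective CFU ratio, clamped to [0, 1] with a warning since
plating noise can push raw ratios above one.

## Numerical choices and degenerate inputs

* Ties for the major band are broken toward the band nearer the
  reference (the slower-migrating side) with a warning.
* `detect_bands()` defines band intensity as peak prominence (height
  above the local baseline); peaks closer than `min_separation` are
  merged into the more prominent one. A flat profile yields an empty
  ladder, not an error.
* All simulator randomness flows through one explicit seed and the
  caller's RNG state is restored afterwards; identical seeds give
  bit-identical output.
* All-zero count rows are reported as `filtered` with `NA` statistics;
  BH adjustment runs over tested genes only.
* A zero control σ makes `fold_change_sigma()` report an infinite ratio
  with a warning; both the |σ| ratio and the signed Δσ are always
  returned because "n-fold change" is convention-dependent.

## Validation scale

The shipped test-suite exercises the pipeline at sizes chosen to keep the
suite fast while leaving no statistical ambiguity: 200 seeded round-trip
trials with planted writhe in [−25, 25] (populations of 4000 molecules),
synthetic transcriptomes of 1000 genes × 12 samples for SRG recovery and
null calibration, 10 kb random sequences for scanner-oracle equivalence,
and 40 seeded noisy growth curves for rate-recovery coverage.

## Known limitations

* No physical electrophoresis model (field strength, agarose
  concentration, reptation); the mobility map is phenomenological.
* No image processing: 2D gel images and lane densitometry are out of
  scope.
* The chloroquine model is linear with a single calibration point and
  must not be extrapolated to high concentrations.
* The helical-repeat and temperature coefficients are treated as
  sequence- and buffer-independent constants.
* The DE statistic is intentionally minimal; real studies should use a
  dedicated DE package and feed its table into `filter_degs()` /
  `build_contrasts()` via `read_de_table()`.
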