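---
title: "Methods: NMR fingerprinting and quantification of cinnamon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR fingerprinting and quantification of cinnamon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinnamr)
```

`cinnamr` turns 1-D proton NMR spectra of cinnamon extracts into three
kinds of result: whole-spectrum *fingerprints* that cluster by species,
absolute *quantifications* (mg of metabolite per g of sample) of sixteen
catalogued compounds, and a *safety screen* of coumarin against its
tolerable daily intake. This vignette is the package's own account of the
underlying models, the parameters that matter, and the choices made where
the design was genuinely open.

## The measurement model

A spectrum is a pair of equal-length vectors: a strictly increasing
chemical-shift axis (ppm) and an intensity axis. The quantitative content
of ¹H-NMR lies in integrals, not peak heights: the integrated area of a
resonance is proportional to the molar concentration of the analyte times
the number of equivalent protons producing the signal, with one
spectrometer response constant shared by all signals. That single
proportionality is both the forward model of the simulator and the
inverse model of the quantifier:

* **Forward (simulation).** A metabolite at `c` mg/g contributes, at each
  of its catalogued signals, a Lorentzian of area
  `k · M(c) · n_protons`, where `M(c) = c · m_sample / (1000 · MW · V)`
  is the molarity in the extraction tube (300 mg sample, 2.0 mL solvent,
  100% recovery assumed so that ground truth is defined at the tube) and
  `k` is the response constant (`reference_area`, default 100 area units
  per mol/L per proton).
* **Inverse (quantification).** Ratioing an analyte window integral
  against the calibration signal of known equivalent concentration
  cancels `k`:
  `C_met = (A_met / A_ref) · (n_ref / n_met) · C_ref`, converted to
  mg/g by `C_met · V · MW · 1000 / m_sample`.

Because simulator and quantifier share one metabolite catalogue (signal
windows, proton counts, molecular weights), the round trip is exact up to
discretization, and a unit-level test audits the dimensional chain
mol/L → mol → g → mg/g.

### The metabolite catalogue

The sixteen quantified compounds (cinnamaldehyde, coumarin,
methoxy cinnamaldehyde, cinnamic acid, benzoic acid, methyl salicylate,
quinic acid, eugenol, both glucose anomers, fructose, formic acid,
choline, shikimic acid, succinic acid, alanine) are bundled with
literature-standard chemical shifts as versioned constants. Two
structural rules make window integrals attributable to single analytes:
quantification windows are pairwise disjoint, and no secondary signal of
any catalogued compound falls inside another compound's quantification
window. Molecular weights are stored to 0.01 g/mol and audited against
formula-derived weights in the test suite. Choline is catalogued as the
free cation (104.17 g/mol) since the analyte's counterion is unknown;
the glucose anomers share a formula (180.16 g/mol) but have distinct
anomeric-proton signals, mirroring their separate columns in the
reference table.

## The synthetic-data generator

`sim_params()` encodes the acquisition conditions the package emulates:
400 MHz, 32768 points over −0.5 to 12.5 ppm, 1.0 Hz Lorentzian FWHM, a
TMS-region reference signal at 0.0 ppm, and methanol/water residual peaks
placed inside the standard exclusion windows. Multi-scan averaging is
modelled only through the additive Gaussian noise SD; the default of
0.002 intensity units reflects the high signal-to-noise of a 64-scan
acquisition and puts the operational detection limit near the smallest
concentrations in the reference table (about 0.03 mg/g for a one-proton
signal). Peaks are truncated to their catalogued windows and renormalized
so the in-window area equals the intended area exactly; this keeps
noise-free baselines identically zero and quantification windows free of
foreign Lorentzian tails. Grids resolving the linewidth with fewer than 3
points per FWHM are flagged in the spectrum metadata.

Cohorts are drawn from per-species profiles estimated from the bundled
reference table: for each species and metabolite, the location is the
mean observed mg/g (ND treated as 0) and the scale is the SD across that
species' samples. Draws come from a normal truncated at zero — the
arithmetic mean ± SD reported by the table parameterizes the normal
directly, and truncation enforces non-negativity — and each sample is
simulated in triplicate with independent noise. Concentrations drawn
below a configurable limit of detection (default 0.05 mg/g, the order of
the smallest nonzero value in the reference table) are flagged ND.

**What the generator does and does not emulate.** It reproduces the
bucket-level structure that drives fingerprinting and the integral-level
structure that drives quantification. It does not model shimming
artifacts, phase or baseline errors, peak-position drift (pH/ionic
effects), J-coupling fine structure, or — importantly — the
*correlation* between metabolites within a sample: each metabolite is
drawn independently. Real cinnamon samples have species-typical
compositions whose metabolite levels co-vary strongly (a dilute extract
is dilute in everything). Because the reference table mixes concentrated
powders with nearly empty extracts within each species, its within-species
SDs are of the order of the means, and independent draws therefore
produce near-zero profiles in *every* species that no classifier can tell
apart. Passing pipeline tests on separated synthetic profiles demonstrate
that the clustering and classification machinery is correct; cohorts
drawn from the reference-table moments measurably overlap between
species, so perfect purity under those conditions is not attainable and
the acceptance suite reports the achieved values honestly.

## Fingerprinting

Bucketing tiles 1–12 ppm with half-open `[lo, hi)` cells of 0.01 ppm
(1100 buckets; the last cell ends exactly at 12.0, excluded, so cells
tile without double counting). Negative intensities are clipped to zero
before integration ("positive intensities"), and each bucket value is the
exact trapezoidal integral of the piecewise-linear spectrum over its
cell — the same integral primitive used by region quantification, so
bucket totals telescope to the whole-range integral to machine precision.
A bucket is excluded when its cell has nonzero-length overlap with any
solvent window (any overlap, not containment — conservative removal);
overlaps below 10⁻⁹ ppm are treated as zero-length so floating-point
edge contact does not spuriously remove cells. With the standard windows,
31 water and 29 methanol buckets are removed (the TMSP window lies below
1 ppm), retaining 1040.

Normalization is per spectrum: with μ the mean of retained bucket values,
values ≤ μ become level 0 and values > μ are mapped onto integers 1–100
by a min–max affine map with round-half-up; if all above-mean values are
equal they map to 100, and a constant vector maps entirely to 0. The
"below mean to zero, above mean binned 1–100" wording this implements is
ambiguous between per-spectrum and global scaling; per-spectrum is
implemented, and the rule is isolated in `normalize_fingerprint()` so an
alternative reading is pluggable.

## Clustering and classification

Distances between fingerprints are Euclidean by default and the linkage
is Ward (`ward.D2`) — the standard chemometric pairing for binned NMR
data; both are configurable, and agglomeration is deterministic with ties
broken by lowest pair index. Dendrograms export to Newick (branch lengths
from merge heights) and purity is evaluated by cutting at *k* clusters
and scoring majority labels.

Ordination is PCA after ND→0 imputation (ND means "below detection",
numerically near zero) and a configurable preprocessing:
`none`, `center`, `autoscale` (center + unit variance, giving each
metabolite equal prior weight) or `pareto`. Component signs are fixed so
each component's largest-magnitude loading is positive. For the bundled
reference table the sweep of these options gives two-component variance
percentages of 94.99, 92.77, 70.27 and 84.92 respectively; `autoscale` is
pinned as the package default as the option closest to the published
ordination of this dataset, and `pca_scaling_sweep()` keeps the whole
sweep one call away. Species calls use nearest centroids in the
autoscaled space, with leave-one-out evaluation recomputing both the
scaling statistics and the centroids without the held-out sample; ties
break to the lexicographically first species and are recorded. The
marker ratios used in authentication practice
(coumarin:cinnamaldehyde, methoxycinnamaldehyde:coumarin,
cinnamic-acid:coumarin, plus the eugenol level) are exposed as features
with explicit undefined flags rather than hard-coded cutoffs.

## Quantification details

The ND rule operationalizes "not detected": a window integral below 3×
the noise floor, with the noise floor estimated as the intensity SD over
11.5–12 ppm (above every catalogued signal). In a noise-free spectrum the
rule degenerates to "ND iff the integral is non-positive". Results are
scale-equivariant (multiplying the whole spectrum by a constant cancels
in the ratio) and linear in the analyte integral. Replicate aggregation
reports the mean and sample SD at full precision; the CSV writer rounds
to 2 decimals, the reporting precision of the reference table.

## The safety screen

The tolerable daily intake for coumarin is 0.1 mg per kg body weight per
day. For a sample at `c` mg/g the allowance is
`max_daily_g = 0.1 · bw / c`, an exact identity tested to machine
precision, and a sample is flagged when `serving_g · c > 0.1 · bw`.
Defaults — 60 kg body weight, 1 g/day serving — are explicit in the
output because the published comparison of a mg/g concentration against a
mg/kg·bw limit is only meaningful once a serving size is stated.

## Numerical and design choices

* Bucket/region integration uses one exact piecewise-linear primitive
  (cumulative trapezoid evaluated analytically at arbitrary points), so
  oracle-equivalence tests hold at 10⁻⁶ relative and tighter.
* The extraction constants are 300 mg sample in 2.0 mL solvent
  (200 µL methanol-d₄ + 1800 µL methanol).
* Default problem sizes in the test and acceptance runs — cohorts of 10
  samples per species in triplicate at the full 32768-point grid, and
  100-spectrum property loops on compact grids — were chosen as the
  smallest sizes at which the stochastic properties stabilize.
* Zero-variance metabolite columns are dropped (with a warning) before
  variance-based scalings; LOO scaling guards zero SDs by substituting 1.
* The pipeline (`run_end_to_end()`) validates its whole configuration,
  including unknown-key rejection, before any stage runs; outputs are
  write-once files plus a manifest carrying the config hash and seed, so
  identical configuration and seed give byte-identical outputs.

## Known limitations

* Quantification assumes resolved, catalogue-positioned signals; real
  spectra need alignment and deconvolution for crowded regions, which are
  out of scope here.
* The reference calibration's equivalent concentration is a required
  user input — it is instrument-specific and no default is claimed
  beyond the simulator's own.
* Fingerprint normalization discards absolute intensity by design;
  samples differing only in overall concentration map to similar
  fingerprints.
* Species classification is nearest-centroid only; no PLS-DA or other
  supervised models, and no regulatory interpretation beyond the single
  TDI constant.
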