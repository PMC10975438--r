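# cinnamr

Quantitative ¹H-NMR fingerprinting and safety screening of commercial
cinnamon.

"True" cinnamon is the bark of *Cinnamomum verum*; cheaper species —
*C. cassia* and *C. burmannii* — are common substitutes in the supply
chain and can carry high levels of coumarin, a hepatotoxic coumarinoid
with a regulatory tolerable daily intake (TDI) of 0.1 mg per kg body
weight. `cinnamr` implements a complete, testable workflow for
authenticating cinnamon powders and extracts from 400 MHz 1-D proton NMR
spectra, aimed at quality-assurance scientists and NMR metabolomics
practitioners:

- **Simulation** — synthetic 32 K-point spectra (Lorentzian lines, TMS
  reference at 0.0 ppm, residual solvent peaks, additive noise) from known
  metabolite concentrations, so every downstream stage has ground truth.
- **Fingerprinting** — rectangular bucketing of positive intensities over
  1–12 ppm at 0.01 ppm width, removal of the water (4.75–5.06 ppm),
  methanol (3.16–3.45 ppm) and TMSP (−0.05–0.05 ppm) regions, and
  per-spectrum normalization of bucket areas onto levels {0} ∪ [1, 100].
- **Clustering** — Ward hierarchical clustering of fingerprints with purity
  evaluation and Newick export.
- **qNMR quantification** — absolute mg/g of 16 catalogued metabolites by
  external reference-signal calibration:

  C_met = (A_met / A_ref) · (n_ref / n_met) · C_ref,
  mg/g = C_met · V_extract · MW · 1000 / m_sample

  where A are window integrals, n proton counts, C molar concentrations,
  V the 2.0 mL extraction volume and m the 300 mg sample mass; triplicate
  means ± SD are reported and signals below 3× the noise floor are ND.
- **Classification** — PCA ordination (autoscaled by default) and
  nearest-centroid species assignment with leave-one-out evaluation, plus
  the marker ratios (coumarin:cinnamaldehyde, …) used for authentication.
- **Safety** — coumarin screening against the TDI: the grams of product
  per day that reach 0.1 mg/kg·bw, and per-sample flags for a given
  serving.

A reference concentration table (48 commercial samples × 16 metabolites,
mg/g, with ND flags) and a versioned metabolite catalogue (formulas,
molecular weights, quantification windows, proton counts) are bundled.

## Worked example

```r
library(cinnamr)

tbl <- load_concentration_table()   # bundled 48 x 16 reference table
ord <- pca_ordination(tbl)          # autoscaled PCA, ND -> 0
glance(ord)
#>   n_samples n_components scaling   pc1_pct pc2_pct pc12_pct
#> 1        48           16 autoscale    55.3    15.0     70.3

head(screen_tdi(tbl), 3)            # 60 kg adult, 1 g/day serving
#>   sample_id   species      coumarin_mg_per_g max_daily_g flagged
#> 1 Cin_cass_20 C. cassia                 9.2        0.652 TRUE
#> 2 Cin_cass_12 C. cassia                 6.94       0.865 TRUE
#> 3 Cin_burm_33 C. burmannii              5.87       1.02  FALSE
```

The first two principal components of the autoscaled table explain 70.3%
of the concentration variance, and the highest-coumarin sample
(`Cin_cass_20`, 9.2 mg/g) reaches the TDI after only 0.65 g of product per
day for a 60 kg adult — a strong authentication and safety signal for
cassia-type cinnamon.

The simulate → quantify round trip is exact at zero noise:

```r
s <- simulate_spectrum(c(Coumarin = 9.2), sim_params(noise_sd = 0))
quantify_metabolite(s, "Coumarin")
#>   metabolite mg_per_g nd
#> 1 Coumarin       9.20 FALSE
```

`run_end_to_end(pipeline_config(seed = 42))` chains all stages — cohort
simulation, fingerprinting, clustering, quantification, ordination,
classification and the TDI screen — and writes CSV/Newick outputs plus a
seeded run manifest.

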