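# meshbagr

Analysis pipeline for mesh-bag litter-decomposition experiments in forest
soil. Sand-filled bags amended with composted maize (C4) leaves are buried
in the soil; fungal hyphae colonize them through the mesh while roots are
excluded. After incubation, the chemistry and spectroscopy of the bag
contents — and the in-grown fungal community — record what the fungi did to
the organic matter. `meshbagr` implements the full inference chain for such
an experiment, driven either by field data or by its own synthetic-data
generator with known ground truth:

* **NEXAFS deconvolution** (`nexafs_*`, `fit_spectrum`): C and N K-edge
  spectra are normalized to unit edge jump and fitted as an error-function
  step plus Gaussian π\* components at canonical literature positions
  (fixed 1.2 eV FWHM) and free σ\* resonances; each chemical class is
  reported as its π\* peak area relative to the sum of all π\* areas.
* **Isotope mass balance** (`c4_fraction`, `new_carbon`, `decay_constant`,
  `cn_increase_percent`, `partition_cn_increase`): the two-pool mixing
  model `f_C4 = (δ_sample − δ_new) / (δ_C4 − δ_new)` quantifies how much
  compost-derived carbon remains; decay constants come from
  `C_final = C_initial·e^(−kt)`; the C/N-ratio increase is partitioned into
  fungal-biomass and inorganic-N-leaching contributions under a declared
  counterfactual-removal convention.
* **FTIR fingerprinting** (`area_normalize`, `band_table`,
  `pca_fingerprint`): total-area normalization, integrals over six
  diagnostic vibrational bands (carbohydrate, phenolic, nitrate/ammonium,
  aliphatic, aromatic, carbonyl), covariance PCA.
* **Community processing** (`filter_rare_otus`, `average_replicates`,
  `rarefy`, `guild_profile`, `bray_curtis`, `permanova`): rare-OTU
  filtering, technical-replicate averaging, rarefaction to a common depth,
  guild relative-abundance profiles, Bray–Curtis dissimilarity and a
  vectorized distance-based PERMANOVA.
* **Synthetic data** (`gen_nexafs_spectrum`, `gen_ftir_spectrum`,
  `gen_chemistry_table`, `gen_otu_experiment`): generative inverses of all
  of the above, so parameter recovery is testable end to end.

The methods vignette (`vignettes/meshbag-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

```r
library(meshbagr)

## isotope mass balance on tabulated mesh-bag values
f <- c4_fraction(-15.6)            # end-members -13.36 / -25.82 permil
round(f, 4)
#> [1] 0.8202                       # 82% of the carbon is still compost-derived
round(new_carbon(10.3, f), 3)
#> [1] 1.852                        # g new (fungal, C3) C per kg content
round(as.numeric(decay_constant(12.1, 10.3, 17/12)), 4)
#> [1] 0.1137                       # yr^-1, one-compartment decay
round(cn_increase_percent(11.9, c(14.7, 14.3, 14.8, 14.0)), 1)
#> [1] 21.4                         # % C/N increase over the initial material

## NEXAFS round trip: generate at known truth, deconvolve, recover
g <- gen_nexafs_spectrum(nexafs_truth("C1s",
       c("carboxyl-C" = 0.5, "aromatic-C" = 0.3, "O-alkyl-C" = 0.2),
       noise_sd = 0.01, seed = 42))
fit <- fit_spectrum(normalize_edge_jump(g$spectrum),
                    default_component_model("C1s"))
round(relative_pi_abundances(fit), 3)
#>              quinone-C substituted-aromatic-C             aromatic-C
#>                  0.000                  0.002                  0.298
#>             phenolic-C            aliphatic-C             carboxyl-C
#>                  0.000                  0.000                  0.503
#>              O-alkyl-C
#>                  0.197
```

The recovered composition matches the generating 0.5/0.3/0.2 truth to
within a few thousandths at 1% noise.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
pipeline; each is a thin script over the package functions and writes its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic chemistry, spectra, OTU tables
Rscript analysis/02_nexafs.R      # deconvolution + abundance PCA
Rscript analysis/03_isotope.R     # mixing, decay constants, C/N partition
Rscript analysis/04_ftir.R        # band areas + spectral PCA
Rscript analysis/05_community.R   # filter/average/rarefy, guilds, PERMANOVA
Rscript analysis/06_report.R      # orchestrated end-to-end run with provenance
```

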