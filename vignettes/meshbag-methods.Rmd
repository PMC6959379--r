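---
title: "Models and methods behind the mesh-bag organic-matter pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mesh-bag organic-matter pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshbagr)
```

# The experiment this package models

Sand-filled mesh bags amended with composted maize leaves are buried in
forest soil for many months. The 50 µm mesh admits fungal hyphae but
excludes roots, so any change in the bag contents — carbon loss, nitrogen
depletion, isotopic shift, spectral change, in-grown community — is
attributable to microbial (chiefly fungal) activity. Because maize is a C4
plant and the surrounding forest is C3, the carbon that grows into the bags
is isotopically distinct from the compost, which turns a simple
delta 13C measurement into a carbon-source tracer.

The package implements the full measurement-to-inference chain for such an
experiment: NEXAFS spectral deconvolution, stable-isotope mass balance,
FTIR fingerprinting, and ITS OTU community processing, plus a synthetic-data
generator that produces every input with known ground truth so each stage's
recovery error is measurable.

# NEXAFS deconvolution

A C or N K-edge spectrum is modelled as

$$I(E) = h\,\tfrac{1}{2}\left[1 + \operatorname{erf}\!\left(\frac{E - E_0}{w\sqrt{2}}\right)\right]
  + \sum_j A_j \exp\!\left(-\frac{(E - E_j)^2}{2\sigma_j^2}\right),$$

an error-function edge jump of height $h$ plus Gaussians for the pre-edge
$\pi^*$ transitions and the broad post-edge $\sigma^*$ resonances. The
canonical C1s model places $\pi^*$ components at 284.3 (quinone-C), 285.3
(substituted aromatic-C), 286.0 (aromatic-C), 286.6 (phenolic-C), 287.4
(aliphatic-C), 288.4 (carboxyl-C) and 289.3 eV (O-alkyl-C), with sigma
resonances at 294.3 and 298.8 eV and the step at 289.9 eV; the N1s model
uses 398.8 (heterocyclic-N), 400 (nitrile/aromatic-N), 401.4 (amidic-N),
402.7 (pyrrolic-N) and 405.4 eV (nitrate/ammonium-N), sigma resonances at
406 and 412.1 eV and the step at 403.2 eV.

Choices a practitioner should know about:

* **$\pi^*$ widths are fixed** at 1.2 eV FWHM; the conversion used is
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$. $\sigma^*$ widths are free in
  [1, 12] eV, the step width in [0.2, 2] eV.
* **Edge-step form**: a Gaussian-broadened step (scaled error function).
  Other forms (arctangent) differ only in tail behaviour and would change
  fitted $\pi^*$ areas negligibly at these widths.
* **Center policy**: $\pi^*$ centers are pinned at the canonical positions
  by default; `default_component_model(center_policy = "bounded")` lets them
  float ±0.2 eV for spectra with small calibration offsets. Sigma-resonance
  centers are always fixed: with widths free and amplitudes free, floating
  their centers as well makes the post-edge fit underdetermined.
* **$\pi^*$/$\sigma^*$ classification is by declared kind, not position**:
  nitrate-N at 405.4 eV lies above the 403.2 eV step yet counts as a
  $\pi^*$ transition in the relative-abundance denominator.
* **Normalization windows**: pre-edge 275–282 / post-edge 310–320 eV (C1s)
  and 390–396 / 420–430 eV (N1s) — inside the recorded ranges and clear of
  all model components; both are arguments of `normalize_edge_jump()`.
* **Fitting protocol**: the step is fitted first on the regions more than
  3 eV away from every Gaussian center (all Gaussian amplitudes
  suppressed), then every amplitude is released and refined by bounded
  Levenberg–Marquardt (cost tolerance 1e-10, up to 3 restarts from jittered
  amplitudes after a poor exit). Non-convergence is flagged in the result,
  never silent.

Relative $\pi^*$ abundances are each $\pi^*$ area over the sum of all
$\pi^*$ areas — a *composition*, invariant under global intensity rescaling
and under anything that only changes the step or the $\sigma^*$ resonances.

# Isotope mass balance

With $R$ the molar ratio of heavy to light carbon,
$\delta^{13}C = (R_{sample}/R_{standard} - 1) \cdot 1000$ against VPDB.
The two-pool mixing model assigns each sample a fraction of compost (C4)
carbon

$$f_{C4} = \frac{\delta_{sample} - \delta_{new}}{\delta_{C4} - \delta_{new}},$$

with default end-members $\delta_{C4} = -13.36$ ‰ (initial maize compost)
and $\delta_{new} = -25.82$ ‰ (mycelium extracted from comparable bags).
Fractions outside [0, 1] are *flagged, not clamped*: an out-of-range value
is diagnostic of end-member misspecification and should fail QC visibly.
Decay constants come from the one-compartment model
$C_{final} = C_{initial}\,e^{-kt}$; the incubation time is taken as
$t = 17/12$ yr exactly (placement to harvest), day-level precision being
unwarranted for a two-significant-figure rate.

The C/N-ratio increase is partitioned by a declared **counterfactual-removal
convention**: the fungal contribution is the drop in final C/N when the
new-carbon pool (fraction `new_c_frac` of final C, at fungal C/N = 20) is
removed from both C and N; the leaching contribution is the drop when the
initially present inorganic N is restored to the final N pool; shares are
percentages of the total increase and the remainder is reported as
unexplained, so the three always total 100. No published algebra exists for
this attribution, and different conventions (e.g. sequential rather than
one-at-a-time removal) give different shares — hence the convention tag
carried in every result.

# FTIR fingerprinting

Spectra are normalized to unit trapezoidal area over the displayed range
before any comparison, then integrated over six diagnostic bands:
carbohydrate C-O/C-O-C 970–1150, phenolic C-O 1150–1250, nitrate/ammonium
1380–1400, aliphatic/O-H 1350–1450, aromatic ring C-C 1500–1520 (the
assignment is the 1510 cm⁻¹ point; ±10 cm⁻¹ makes it integrable), and
carbonyl C=O 1620–1800 cm⁻¹. The nitrate band is contained in the aliphatic
band; bands are therefore integrated independently and never summed.

PCA is computed on column-centered data without variance scaling
(covariance PCA): after total-area normalization all variables share a
scale, and correlation scaling would inflate flat spectral regions.
Scores and loadings carry a deterministic sign convention (largest-magnitude
loading per component positive). No Kubelka–Munk transformation is applied;
spectra are analysed as delivered. The PCA range is a parameter, since
published fingerprinting studies vary in whether they use the full displayed
range or selected windows.

# Community processing

The processing order is: rare-OTU filter → technical-replicate averaging →
rarefaction → relative abundance. Decisions:

* **Filter modes.** The conventional removal rule — drop OTUs with fewer
  than 10 total reads *or* present in a single sample — is the default
  (`mode = "either"`); the literal conjunction (`"both"`) is available.
  Presence is counted over biological samples, not replicate columns. The
  removed ids are always returned in a removal log.
* **Averaging before rarefaction** follows the textual order of standard
  protocols; averaged counts are real-valued, so the matrix is rounded to
  integers before subsampling (rarefaction needs whole reads).
* **Rarefaction depth** defaults to the *lower* median of the sample sums —
  an achievable depth. Samples below depth raise an error naming the sample
  in `rarefy()` itself; the composed pipeline (`process_community()`) drops
  them by default, because rarefying to a median necessarily leaves up to
  half the samples shallow.
* **PERMANOVA** uses Anderson's distance-based pseudo-F with free label
  permutation (no strata — the design is an unblocked two-group
  comparison), $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, and
  $R^2 = SS_{among}/SS_{total}$. The implementation is vectorized over
  permutations (one indicator-matrix product per group) so that large null
  simulations are cheap; tests verify exact agreement of $F$ and $R^2$ with
  `vegan::adonis2` and with a brute-force enumeration of all label
  orderings on a 4-sample toy.
* The BLAST-hit rank rule (species at ≥ 96% identity, genus at 94–95.99%,
  both requiring ≥ 80% query coverage) applies the coverage gate to *both*
  tiers; applying it only to the species tier would promote low-coverage
  hits to genus, which is not defensible.

# The synthetic-data generator

The generator is the inverse of each analysis model, with defaults chosen
once to match the study conditions of the field design it emulates:

* **Chemistry** (`chemistry_scenario()`): 3 plots per treatment; initial
  C 12.1 and N 1.02 g kg⁻¹; horizon decay rates 0.11 (humus) and 0.29 yr⁻¹
  (mineral) — the unfertilized-plot rates, control being the reference
  condition; end-members −13.36/−25.82 ‰; 15% new carbon (the midpoint of
  the plausible 13–18% range the mixing model implies for such bags); a 21%
  C/N increase. Between-plot noise is lognormal for C and N (sd 0.07,
  consistent with reported standard errors at n = 3) and additive for
  delta 13C (0.35 ‰) and pH (0.05).
* **NEXAFS**: total $\pi^*$ area 2 intensity·eV shared among components;
  step width 0.8 eV; sigma resonances at 0.3 × jump height with 4 eV FWHM —
  only their presence matters for $\pi^*$ recovery. Noise is additive
  i.i.d. Gaussian on intensity, the simplest model that exercises the
  fitter; real detector noise is closer to Poisson and energy-correlated.
* **OTU experiments** (`otu_scenario()`): 50 OTUs, 6 biological samples ×
  3 technical replicates, read depths uniform in 13,810–24,843, guild mix
  ECM 0.37 / saprotroph 0.57 / pathogen 0.02 / unknown 0.04. Replicates are
  independent multinomial draws from a shared per-sample composition —
  sampling noise only, matching their later averaging. A chosen fraction of
  OTUs is *planted* to fail the rare-OTU filter (< 10 reads confined to one
  sample), and common-OTU compositions are floored at 0.002 so no common
  OTU can fail the filter by chance; the truth object records exactly which
  OTUs must be removed.

What passing tests on these data do **not** show: robustness to beamline
artifacts (energy drift, self-absorption), non-Gaussian detector noise,
baseline curvature in FTIR, PCR/primer bias, chimeras, or compositional
overdispersion between technical replicates. The generator emulates the
statistical structure of the study design, not the instruments.

# Problem sizes and numerical tolerances in the test suite

Parameter-recovery claims are verified at 50 synthetic C1s spectra with
noise at 1% of the unit edge jump (per-component abundance RMSE ≤ 0.05;
noise-free recovery within 0.01). The PERMANOVA type-I error is estimated
from 500 null communities of 12 exchangeable samples (6/6 split, 999
permutations each); 12 samples give 462 distinct balanced partitions, fine
enough that the discrete permutation p-value is close to uniform.
Rarefaction is checked for exact column-sum conservation and against its
hypergeometric expectation over 200 seeds. Optimizer results are compared
to a brute-force amplitude grid (step 0.001) on a two-component toy, and
PCA to a covariance eigendecomposition. These sizes keep the full suite
under a minute of compute while leaving Monte-Carlo error well inside each
asserted band.

# Known limitations

* The deconvolution assumes the canonical component set; organic matter
  with species outside it (e.g. carbonates at the C edge) needs a custom
  `component_model`.
* The C/N partition is convention-dependent by construction; its shares
  should be compared only within a fixed convention.
* Rarefaction discards reads; for inference tasks where that matters,
  model-based alternatives exist but are out of scope here.
* PERMANOVA with free permutation assumes exchangeability across plots;
  blocked or repeated-measures designs would need restricted permutation,
  which the implementation does not provide.
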