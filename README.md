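# PCDRadiomics

Robustness of radiomics texture features under photon-counting CT
acquisition and reconstruction variation, rebuilt as a fully synthetic,
seeded, testable R pipeline.

Radiomics features are only useful clinically if they survive ordinary
changes in how a scan is acquired: repositioning the patient, switching tube
voltage, lowering dose, reconstructing thinner slices, scanning at high
pitch, or changing the iterative-reconstruction strength or kernel. The
experimental design implemented here probes exactly that: a texture phantom
with 28 distinct materials, imaged under a reference abdomen protocol and
twelve one-factor-at-a-time variations (13 protocols total), with 93
radiomics features extracted per material per protocol and per-feature
robustness quantified by four statistics. The physical phantom scans behind
that design were never released, so this package provides the whole chain
synthetically — phantom, scanner surrogate, extractor, statistics — as a
reusable instrument for studying how acquisition factors propagate into
feature instability.

## What it computes

**Phantom and simulator.** 28 material inserts (grains, woods, sponges,
salts, water) as seeded stationary random textures on a 0.25 mm ground-truth
grid, imaged by an image-domain surrogate of the scanner chain: rigid
repositioning, per-material 140 kVp contrast factors, anti-aliased
resampling to each protocol grid (`fov/matrix` in-plane, slice thickness in
z), reconstruction-kernel blur, and correlated quantum noise with SD

    sigma = sigma_ref * sqrt(CTDI_ref / CTDI) * sqrt(t_ref / t)
            * m_pitch * a_kernel * f_QIR,        sigma_ref = 10 HU

at 10 mGy / 1.0 mm. Cylindrical ROIs of 35 pixels × 25 slices are placed per
material and propagated between scans by the known rigid transform.

**Features.** The 93-feature set: 18 first-order + GLCM (24) + GLRLM (16) +
GLSZM (16) + GLDM (14) + NGTDM (5), with fixed-bin-width discretization
(25 HU), distance-1 matrices averaged over the 13 unique 3D directions, and
no pre-processing before extraction. Matrix builders are compiled (Rcpp) and
tested voxel-by-voxel against brute-force enumeration.

**Statistics.** For each feature: ICC(A,1) — the two-way absolute-agreement
single-measurement intraclass correlation
`(MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E))` — and Lin's
concordance correlation coefficient
`2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` across the 28 materials between
reference and comparison protocol; the coefficient of variation
`100·SD/|mean|` and quartile coefficient of dispersion
`100·(Q3−Q1)/|Q3+Q1|` for variability; interpretation bins
(poor/moderate/good/excellent at 0.50 / 0.75 / 0.90; acceptable/moderate/
inadequate at 10 % / 20 %) and the study-style summary tables.

## Worked example

A reduced study — 8 materials, the reference protocol plus a repositioned
scan and a 0.47 mGy low-dose scan:

```r
library(PCDRadiomics)

suite <- defaultProtocolSuite()
sub   <- suite[suite$id %in% c("reference", "reposition", "dose05"), ]
cfg   <- studyConfig(layout = buildDefaultLayout(materials = materialTable()[1:8, ]),
                     protocols = sub)
ft    <- runSuite(cfg, seed = 20250131)

rel <- reproducibilityPerFactor(ft, "reference", "dose05")
median(rel$icc)
#> [1] 0.8805093

sm <- summarizeRobustness(ft)
factorReliability(sm)[, c("factor", "metric", "median",
                          "pct_excellent", "pct_good", "pct_moderate", "pct_poor")]
#>         factor metric median pct_excellent pct_good pct_moderate pct_poor
#> 1   Reposition    ICC  0.995          80.6      7.5          3.2      8.6
#> 2   Reposition    CCC  0.995          79.6      7.5          3.2      9.7
#> 3 Dose 0.5 mGy    ICC  0.881          48.4     14.0         15.1     22.6
#> 4 Dose 0.5 mGy    CCC  0.866          41.9     19.4         14.0     24.7
```

Reading it: repositioning barely disturbs the features (median ICC 0.995;
~80 % of the 93 features are "excellent", ICC ≥ 0.90), while dropping the
dose from 10 mGy to 0.47 mGy pulls the median ICC down to 0.88 and pushes a
fifth of the features into the "poor" bin — feature-level robustness depends
strongly on which acquisition factor moved. `writeReport(sm, ft, "out/")`
writes `summary.json`, the three CSV table analogs and the long/wide feature
tables; `plotRobustness(sm, "ICC")` draws the stacked percent-per-bin bars.

A full 13-protocol × 28-material run is `runSuite(studyConfig(), seed)`
(~35 s) and yields the complete 93 × 364 feature table. A thin CLI over the
same functions lives in `inst/cli/pcdradiomics.R`
(`generate` / `acquire` / `extract` / `run-all`), reading YAML study
configurations via `readStudyConfig()` and writing NIfTI volumes.

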