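# ectishape

Quantitative shape analysis of the epithelial-connective tissue interface
(ECTI) in nonlinear optical microscopy.

## The problem

The ECTI — the boundary between stratified epithelium and the collagen-rich
lamina propria — flattens out in healthy mucosa and deforms as rete ridges
protrude downward during epithelial dysplasia. Second-harmonic-generation
(SHG) microscopy shows this boundary directly: fibrillar collagen below the
interface generates signal, the epithelium above it generates none. For
researchers imaging epithelial neoplasia (or validating segmentation methods
against such data), `ectishape` turns a two-channel cross-section
(autofluorescence + SHG) into a single shape statistic and the downstream
group-level analysis.

The core statistic is the deviation of the traced interface from linearity.
With `l` the arc length of the interface and `L` the chord joining its two
endpoints,

    ΔL = l − L,    (ΔL)_norm = ΔL / L

so a flat interface scores 0, a semicircular arch scores π/2 − 1 ≈ 0.571,
and dysplastic undulation scores in between. The extraction chain is:
Otsu thresholding of the SHG channel → per-column topmost-border candidates
with speckle rejection → Canny-style edge detection → minimal-cost
(Dijkstra) boundary tracing with per-pixel cost `ε + 1/(1 + |∇I|)` →
sub-pixel refinement and smoothing → arc-length geometry in micrometres.

The package also measures epithelial thickness (surface-to-interface
distance at four fixed lateral positions), nuclear density in en-face
frames (multi-scale Laplacian-of-Gaussian blob detection), and the cohort
statistics used to separate dysplasia from normal mucosa: one-way ANOVA
with Tukey post hoc comparisons, empirical ROC curves with AUC, and the
Youden-optimal operating point. A synthetic phantom and cohort generator
with analytic ground truth makes every stage testable without any image
download.

## Worked example

Render a dysplastic-style phantom at the native acquisition geometry
(320 µm field, 0.625 µm/px lateral, 1 µm z-steps), trace it, and measure:

```r
library(ectishape)

m <- boundary_model(100, sine_amplitude = 14, sine_period = 90,
                    bumps = data.frame(center = 200, amplitude = 22,
                                       width = 14))
ph <- render_phantom(phantom_params(rng_seed = 7), m)

tr <- measure_ecti(ph$section)
tr
#> boundary_trace: 512 points, l = 416.94 um, L = 319.40 um, (dL)norm = 0.3054
ph$truth$true_delta_linearity
#> [1] 0.3054     # quadrature oracle for this model: exact agreement here

th <- epithelial_thickness(detect_surface(ph$section), tr)
round(th$mean_um, 1)
#> [1] 115.2      # mean of 104.7, 112.2, 135.4, 108.7 um at the 4 positions
```

The traced interface of this phantom deviates from linearity by 0.31 —
squarely in the reported dysplastic range — while a flat-interface phantom
measures ≤ 0.01. Simulating the full discrimination study (33 normal sites,
truncated Gaussian 0.11 ± 0.04; 27 dysplastic sites, lognormal
moment-matched to 0.41 ± 0.24; 200 seeded replicates):

```r
sim <- simulate_discrimination(modality = "imaging", n_reps = 200, seed = 1)
sim$summary
#> $mean_auc              0.973
#> $mean_sensitivity_pct  92.7
#> $mean_specificity_pct  97.0
#> $median_anova_p        2.78e-10
#> $frac_p_below_0.01     1
```

ΔLinearity alone separates the simulated groups with AUC ≈ 0.97 and a
Youden operating point near 93% sensitivity / 97% specificity.

A thin command-line wrapper is installed at
`inst/scripts/ectishape.R` (subcommands `simulate-phantom`,
`simulate-cohort`, `trace`, `morphometry`, `stats`, `all`); see
`inst/extdata/example-config.yaml` for the configuration format. Every run
records its seed, and fixed-seed runs are byte-identical.

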