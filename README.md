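# fcontrol

Functional brain controllability analysis for deep brain stimulation
(DBS) outcome prediction in Parkinson's disease.

Motor improvement after DBS varies between patients, and the choice of
surgical target (subthalamic nucleus, STN, vs globus pallidus interna,
GPi) lacks a mechanistic biomarker. One candidate is how far
dopaminergic medication moves each brain region's *dynamic role* in
the resting-state network — regions whose controllability normalizes
under levodopa may mark circuits that stimulation can also engage.
`fcontrol` implements that analysis end to end for researchers working
with ROI-level resting-state fMRI: network-control metrics on
functional connectivity, medication-induced delta controllability,
region screening, outcome correlation, and cross-validated outcome
prediction — plus a synthetic cohort generator with planted,
analytically checkable effects so every stage can be validated without
patient data.

## The model

Regional BOLD dynamics are treated as a discrete-time linear system
`x_{t+1} = A x_t + B_K u_K(t)` on the 90-region AAL parcellation,
where `A` is the Pearson functional-connectivity matrix scaled to
Schur stability (`A = C / (1 + σ_max(C))`). With each region `i` in
turn as the single control node:

- **Average controllability**: `AC_i = tr(W) = Σ_j v_ij² / (1 − λ_j²)`,
  the trace of the infinite-horizon controllability Gramian
  `W = Σ_τ A^τ B Bᵀ A^τ` (ability to reach nearby states cheaply).
- **Modal controllability**: `φ_i = Σ_j (1 − λ_j²) v_ij²`
  (ability to steer fast-decaying, hard-to-reach modes).
- **Delta controllability**: the on-medication minus off-medication
  difference of either metric, per region and patient.

Regions that are both *aberrant* (patients-off vs controls, ANCOVA
adjusted for age and sex) and *medication-responsive* (paired t, on vs
off) are screened; delta controllability of a-priori motor structures
is correlated with percent UPDRS-III improvement
(`(pre − post) / pre × 100`); and improvement is predicted by
epsilon-SVR under leave-one-subject-out cross-validation, evaluated by
the Pearson correlation between predicted and actual outcomes.

## Worked example

```r
library(fcontrol)

net <- make_base_network(seed = 3)                 # modular ground truth
cohort <- generate_cohort(cohort_config(seed = 3), net)
profiles <- cohort_profiles(cohort)                # band-pass -> FC -> AC/MC
deltas <- cohort_deltas(profiles)                  # on - off, per patient

screen <- screen_regions(profiles, cohort$records)
responsive <- select_responsive_regions(screen, alpha = 0.05)
head(responsive[order(responsive$group_p), ], 3)
#>      label metric  group_F      group_p direction     med_t        med_p n_pairs responsive
#> 148 PoCG.R     mc 80.02121 9.218242e-13         + -5.748668 2.022946e-06      34       TRUE
#> 168  THA.R     mc 78.09805 1.413845e-12         + -3.351413 2.026636e-03      34       TRUE
#> 147 PoCG.L     mc 74.46815 3.222648e-12         + -6.041215 8.545863e-07      34       TRUE
```

All three top regions are planted disease nodes: their modal
controllability is elevated in patients relative to controls
(`direction = "+"`, group ANCOVA F ≈ 74–80) and moves back toward
control values after medication (negative paired t across the 34
patients with both sessions) — the disease-plus-normalization
signature the generator plants. Prediction uses the screened delta
features; at the strong-plant calibration settings (see the methods
vignette) it recovers the planted outcome link:

```r
prediction_experiment(strength = 1, seed = 3001)
#> $r
#> [1] 0.519985      # LOOCV predicted-vs-actual Pearson r, n = 24
#> $feature_cor
#> [1] 0.6532149     # in-sample thalamic delta-AC vs improvement
```

A single call runs the whole chain on the default synthetic study and
writes CSV tables plus a checksummed manifest:

```r
res <- run_pipeline(list(seed = 7L, out_dir = "run7"))
```

A thin command-line wrapper with the same stages is provided at
`inst/cli/fcontrol-pipeline.R`.

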