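---
title: "Functional brain controllability and DBS outcome prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional brain controllability and DBS outcome prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcontrol)
```

## The model

`fcontrol` analyses resting-state functional connectivity through the
lens of linear network control theory. The brain is modelled as a
discrete-time linear time-invariant system on the 90 regions of the
AAL parcellation,

$$x_{t+1} = A\,x_t + B_K u_K(t),$$

where $x_t$ is the regional activity state, $A$ is a weighted symmetric
adjacency matrix derived from Pearson functional connectivity, and
$B_K$ selects the control nodes. Two node-wise summaries are computed
with each region in turn as the sole control point:

* **Average controllability (AC)** — the trace of the infinite-horizon
  controllability Gramian
  $W = \sum_{\tau \ge 0} A^\tau B B^\top A^\tau$. For symmetric
  Schur-stable $A = V \Lambda V^\top$ this has the closed form
  $\mathrm{AC}_i = \sum_j v_{ij}^2 / (1 - \lambda_j^2)$. High-AC
  regions can push the network into nearby, easy-to-reach states with
  little input energy.
* **Modal controllability (MC)** —
  $\phi_i = \sum_j (1 - \lambda_j^2)\, v_{ij}^2$, the eigenmode-weighted
  projection onto fast-decaying modes. High-MC regions can steer the
  system toward hard-to-reach states.

For patients scanned in both medication states, **delta
controllability** is the per-node difference (on − off, a convention
fixed here and used consistently downstream) of each metric; it
quantifies how far dopaminergic medication moves a region's dynamic
role, and it is the feature on which deep-brain-stimulation (DBS)
motor outcomes are screened and predicted.

### Stabilization

The infinite Gramian sum converges only for spectral radius below one,
which a raw correlation matrix does not satisfy. `stabilize()` scales
the zero-diagonal connectivity matrix $C$ as $A = C / (c +
\sigma_{\max}(C))$ with $c = 1$ by default, following the convention
of the widely used network-control reference code. The constant is
configurable (`stabilization_c`); the diagonal is zeroed *before*
scaling so self-loops do not inflate controllability. Correlations are
not Fisher-transformed beforehand — the control model consumes the raw
weighted matrix. Both choices are declared assumptions: the
controllability literature computes these metrics on raw weighted
(structural or functional) adjacency matrices.

Numerically, one symmetric eigendecomposition per session is cached
and reused for all 90 node-wise AC and MC values, and three
independent routes to AC (closed form, a Smith-doubling solve of the
discrete Lyapunov equation $A W A^\top - W = -BB^\top$, and the
truncated power sum with a spectral-radius tail bound below $10^{-10}$)
are required to agree within $10^{-8}$ in the test suite. Two exact
bounds hold for every stabilized symmetric system and are enforced as
invariants: $\mathrm{AC}_i \ge 1$ (the $\tau = 0$ term) and
$0 < \phi_i \le 1$.

## Temporal preprocessing

The pipeline starts from ROI time series (223 retained volumes at
TR = 2 s by default) and applies, in order: linear detrend plus ideal
frequency-domain band-pass (0.01–0.08 Hz), optional nuisance
regression, optional scrubbing, then Pearson correlation. Choices
worth stating:

* **Filter.** An ideal (boxcar) frequency-domain filter after linear
  detrending, the convention of the REST-family tools; the pass band
  is configurable and is validated against the Nyquist frequency.
* **Nuisance regression.** `friston24()` expands the six rigid-body
  parameters into the standard 24-regressor set (parameters, one-step
  lags, squares, squared lags). Global, white-matter or CSF signals
  enter as additional confound columns. Regression is ordinary least
  squares per node with an internal intercept; when filtering is also
  requested, confounds are filtered identically first so the
  regression cannot reintroduce out-of-band variance. The order
  (filter, then regress) is configurable because the underlying
  acquisition literature is ambiguous on this point.
* **Scrubbing.** Power-style framewise displacement
  ($\mathrm{FD}_t = \sum |\Delta \text{trans}| + r \sum |\Delta
  \text{rot}|$, head radius $r = 50$ mm), threshold 0.5 mm, optional
  removal of the following frame; sessions losing more than half
  their frames are flagged unusable. All three constants are
  configurable.

## The synthetic cohort

No patient scans are distributed with the package; every downstream
stage is validated on a generator with known ground truth
(`make_base_network()`, `generate_cohort()`). What it emulates:

* A modular "connectome": block covariance with unit variances,
  within-community covariance 0.6, between-community 0.1, six
  contiguous communities of 15 nodes, diagonally loaded so the
  smallest eigenvalue is at least 0.1.
* **Disease:** in the patient medication-off state, every off-diagonal
  covariance entry touching a designated disease node (bilateral
  caudate, putamen, pallidum, thalamus and postcentral gyrus — the
  striato-pallido-thalamo-cortical motor territory) is attenuated by
  `perturbation_scale` (default 0.6). Attenuation reduces those
  nodes' integration, which lowers their AC and raises their MC —
  the qualitative disease signature the screening stage must find.
  Positive definiteness is preserved exactly (the attenuation mask is
  a PSD unit-diagonal matrix, so the Schur product theorem applies).
* **Medication:** each patient draws a recovery fraction from a
  normal distribution (mean 0.6, SD 0.2) truncated to $[0, 1]$ — the
  distribution of levodopa response is a free design choice, not an
  inference about any study population — and the on-state covariance
  is the convex combination `(1 - recovery) * off + recovery * base`.
* **Outcomes:** percent UPDRS-III improvement is planted as
  `38.65 + 50 * recovery + noise` (SD 8), truncated to $[0, 100]$,
  and the postoperative score is backed out of the improvement-rate
  identity from a preoperative score drawn near 56 ± 16. The planted
  cause is the *latent* recovery fraction, not delta controllability
  itself, so the pipeline must genuinely re-estimate the mediating
  quantity from simulated time series. Defaults give a mean
  improvement near 68%, matching the clinical magnitudes the design
  emulates.
* **Strata and attrition:** 24 STN-DBS patients, 15 GPi-DBS patients,
  29 controls; 5 on-sessions and 2 off-sessions are marked missing to
  emulate scan exclusions. Sessions are stationary Gaussian AR(1)
  processes (coefficient 0.3) whose lag-0 covariance equals the
  generating matrix exactly.

What it does **not** emulate: hemodynamics, spatial structure,
realistic motion (beyond configurable traces for scrubbing tests),
scanner drift, or true inter-subject connectome variability. Passing
tests therefore demonstrate that the pipeline recovers planted effects
through its own estimation chain — not that the biological findings
would replicate.

### The information floor of session-level connectivity

A design fact that shaped the validation experiments: 223 volumes at
TR 2 s band-limited to 0.01–0.08 Hz carry roughly $2\,B\,T \approx 62$
statistically independent samples, so a sample-correlation entry has a
standard error near 0.13, and a node's AC estimate inherits a standard
deviation of ~0.02–0.03 between repeated sessions of the *same*
subject. Delta controllability subtracts two such estimates. Planted
between-subject signal must be comparable to this floor to be
recoverable at $n \le 24$; no pipeline can do better from this much
band-limited data. The prediction-calibration experiments therefore
use a designed strong-plant configuration (`strong_plant_design()`):
within-community covariance 0.9 (which both deepens the attenuation
contrast and shrinks correlation noise), perturbation scale
$1 - 0.95 \times \text{strength}$, recovery mean 0.5 with SD 0.3,
noise-free outcomes, and no dropped sessions. The screening
experiments run at the generator defaults, where the realized
patient-vs-control contrast at disease nodes is well above 0.8 SD.

## Statistical cascade

* Demographic comparisons reproduce printed-table conventions exactly:
  pooled-variance two-sample t (not Welch) and Pearson chi-square
  without continuity correction — the variants that reproduce the
  published statistics from published summaries.
* Region screening: per region and metric, an ANCOVA
  (`value ~ group + age + sex`; age and sex because they are the two
  demographics that differ between patients and controls) with the
  marginal F for group, plus a paired t-test of on vs off in patients
  retaining both sessions. A region is **responsive** when both tests
  fall below $\alpha = 0.05$, uncorrected — deliberately mirroring the
  uncorrected intersection convention of the clinical literature this
  design follows; an FDR switch is available but off by default, and
  the type-I cost of no correction is quantified by simulation in the
  acceptance suite.
* Outcome correlations: Pearson r between delta controllability and
  percent improvement over eight a-priori motor structures (caudate,
  putamen, pallidum, thalamus, pre/postcentral gyri, SMA, paracentral
  lobule), both hemispheres and metrics, per surgical group.

Degenerate inputs are handled explicitly: zero-variance nodes
correlate as zero with a warning; zero-variance paired differences
reject rather than returning infinite t; zero preoperative scores are
rejected by the improvement-rate formula.

## Outcome prediction

`svr_loocv()` is epsilon-SVR (libsvm via `e1071`) under
leave-one-subject-out cross-validation. Default features follow the
screened regions per target: bilateral thalamic ΔAC for STN;
bilateral postcentral ΔAC plus left postcentral and left caudate ΔMC
for GPi. Hyperparameters are the toolbox defaults (RBF kernel,
$C = 1$, $\varepsilon = 0.1$, $\gamma = 1/d$), recorded in every
result; a linear-kernel preset exists because the feature space is
2–4 dimensional. Features *and* outcomes are standardized with
training-fold statistics only, mirroring the toolbox's own scaling —
without outcome scaling, $C = 1$ on percent-scale outcomes collapses
the fit toward the training mean. Evaluation is the Pearson
correlation between held-out predictions and actual outcomes, with a
correlation t-test p by default and a label-permutation alternative
with full refits.

### A known limitation: the LOOCV correlation bias

The predicted-vs-actual correlation across LOOCV folds is *not*
centered at zero under the null hypothesis. Each held-out prediction
carries its training fold's center, and the fold center excluding
subject $i$ anticorrelates with $y_i$ by construction
($\mathrm{cov} = -\mathrm{var}(y)/(n-1)$), so the null expectation of
$r$ is roughly $-\mathrm{sd}(y) / ((n-1)\,\mathrm{sd}(\hat y))$ —
about $-0.1$ at $n = 24$ with these hyperparameters. This is a
documented property of cross-validated correlation metrics at small
$n$, not an implementation artifact; it makes the correlation t-test
slightly conservative for positive findings, and it is why
`evaluate_prediction()` offers the permutation method, which compares
against the *empirical* (negatively centered) null rather than
assuming a zero-centered one. It also means that a leakage check based
on scaling statistics is uninformative on null data — the per-fold
intercept refit absorbs any leaked center — so the leakage regression
test instead verifies that training through the held-out subject
inflates $r$ massively while honest folds do not.

## Problem sizes used in the validation suite

The packaged experiments run 50 screening replicates (planted and
null) at the full default strata, a five-point strength grid with 20
prediction replicates per point, a 500-refit permutation null at
$n = 24$, 100 random systems up to 90 nodes for the three-route
Gramian agreement, and $10^4$ randomized systems for the bound
invariants. These sizes were chosen to give stable Monte-Carlo
estimates at interactive run times on a single core.

## A worked pipeline run

```{r, eval = FALSE}
res <- run_pipeline(list(seed = 7L))
head(res$responsive)       # regions aberrant AND medication-responsive
res$correlations$STN       # motor-ROI delta vs improvement
res$predictions$STN        # LOOCV-SVR predicted vs actual
```

See the README for a smaller worked example with printed output.
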