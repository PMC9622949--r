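---
title: "Biophysical biomarkers from ERPs: model, inversion, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical biomarkers from ERPs: model, inversion, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model, the variational inversion, the model comparison, the feature
pipelines, and — because everything here is validated on synthetic cohorts —
an explicit statement of what the synthetic generator does and does not
emulate.

## The generative model

Each cortical source is a three-population Jansen–Rit unit: pyramidal
cells, excitatory (spiny stellate) interneurons, and inhibitory
interneurons. Every synaptic connection convolves presynaptic firing with
a critically damped second-order kernel, so each synaptic output `y`
satisfies

    y'' = (H / tau) * input  -  (2 / tau) * y'  -  y / tau^2

with gain `H` (mV) and time constant `tau` (ms). Firing is a centred
sigmoid of depolarisation,

    S(v) = 2 e0 / (1 + exp(r (v0 - v)))  -  2 e0 / (1 + exp(r v0)),

so `S(0) = 0` and the resting state is an exact fixed point: simulating
with no input from zero state yields identically zero activity, a property
the tests assert. The pyramidal potential `vP = y1 - y2` (excitatory minus
inhibitory postsynaptic potential) is the quantity that reaches the
sensors.

The network is the 10-source task network: V1, dACC, and bilateral ITG,
SPL, vlPFC, dlPFC. Forward edges run V1→ITG, ITG→SPL, SPL→vlPFC,
SPL→dlPFC, vlPFC→dlPFC, vlPFC→dACC per hemisphere (12 in all), backward
edges are their reciprocals, and the four homologous pairs are connected
laterally. Forward and lateral afferents drive the excitatory equation of
the target; backward afferents enter the argument of the inhibitory
population's sigmoid. That targeting is a design choice — the hierarchical
semantics standard in this model family — since nothing in the problem
fixes it uniquely.

Condition dependence: every extrinsic edge has a baseline strength scaled
by `exp(A)` in both task conditions; edges declared modulated by the
active model variant are additionally scaled by `exp(B)` in the
interference condition, and modulated sites scale their excitatory gain by
`exp(I)` there. The control condition never reads `B` — supplying a
modulation for an edge the variant does not declare is an error, not a
silent no-op.

### Parameters, units, and defaults

| Block | Meaning | Count (10 sources) | Default / prior |
|-------|---------|--------------------|-----------------|
| A     | baseline extrinsic log-scalings, forward + backward | 12 + 12 | prior N(0, 1/2) |
| B     | interference-condition extrinsic modulation | 24 (same edges) | prior N(0, 1/2) |
| G     | excitatory/inhibitory synaptic gain scalings per source | 10 + 10 | prior N(0, 1/16) |
| H     | the four intrinsic coupling constants, global | 4 | prior N(0, 1/16) |
| T     | excitatory/inhibitory time-constant scalings per source | 10 + 10 | prior N(0, 1/16) |

All 92 parameters are log-scalings acting through `exp()` on baseline
values `He = 3.25` mV, `Hi = 22` mV, `tau_e = 10` ms, `tau_i = 20` ms,
`gamma = (50, 40, 12, 4)`, forward/backward/lateral baseline strengths
32 / 1 / 2, sigmoid constants `e0 = 2.5` 1/s, `r = 0.56` 1/mV, `v0 = 6`
mV. Two of these deserve comment.

*`rate_scale` (0.006).* The sigmoid returns firing in 1/s while the
kernels run in milliseconds; `rate_scale` converts firing to synaptic
drive and thereby sets every loop gain at the operating point. The
defaults keep each intrinsic loop and each forward–backward loop below
unit gain, so the evoked response is stable and near-linear (halving a
small stimulus halves the response to within 2%, a tested property). The
inhibitory population's sigmoid multiplies backward afferents by
`gamma_4`, which is why the backward baseline strength is numerically
much smaller than the forward one: the pair is chosen so the two
directions have comparable effective loop gains.

*The stimulus.* A Gaussian input bump at the input site (V1), peak 160 ms,
SD 40 ms, amplitude 2. A slow conflict-related input wave propagating
through the four-level hierarchy places the frontal evoked component
inside the 250–350 ms Positive Potential analysis window while keeping
time constants flat; grading time constants up the hierarchy was tried
first and rejected because it scales loop gains with `tau` and destabilises
the deep sources.

## The synthetic cohort

`generate_cohort()` draws, per subject, the 92 log-scalings from
independent Gaussians with per-category SDs (A, B: 0.2; G: 0.1; H: 0.05;
T: 0.1), simulates both task conditions, and projects to 60 channels
through a seeded smooth random gain matrix with white channel noise at
10 dB SNR. Patients (15 of 49, matching the modelled study) receive
additive mean shifts: +0.3 on the excitatory gains of V1 and bilateral
vlPFC/dlPFC shared by all patients, and per-subtype shifts of +0.5 on the
interference modulation of vlPFC→dACC (subtype 1) or V1→ITG (subtype 2) —
the connections the patient-cohort model comparison singles out over and
above the control winner. Effect magnitudes are the package's choice of a
realistic moderate effect (about 1–2 noise SDs on the affected
parameters); `effect_scale` multiplies them and 0 removes them entirely,
which the null-effect distribution test exploits.

What the generator does *not* emulate: real electrode geometry (the gain
matrix is synthetic smooth mixing, labelled as such), trial-level
variability (one trial-averaged epoch per subject and condition, as the
analysis fits), temporally correlated sensor noise, artifacts, or any
demographic covariate structure. Tests passing on these cohorts therefore
validate the *procedure* — inversion, selection, classification,
clustering — under known ground truth; they say nothing about effect sizes
in real recordings.

## Variational inversion

Per subject, channel data reduce to a small number of spatial modes (top
left-singular vectors of the pooled channel data, 4 on the benchmark
networks; a fixed template-derived projector can be supplied instead) and
both conditions are fitted jointly. The free energy

    F = E_q[ log p(y | theta) ] - KL( q || prior )
      = N/2 log(tau / 2 pi) - tau/2 ( r'r + tr(J Sigma J') ) - KL

is maximised over a Gaussian posterior `q = N(mu, Sigma)` by
Gauss–Newton/Levenberg–Marquardt ascent: sensitivities `J` come from
central finite differences (step 1e-3 in log-scaling units), the posterior
covariance is the regularised curvature inverse, and the noise precision
`tau` has a closed-form update each outer iteration. Steps are accepted
only when they increase F, so the accepted-F trace is non-decreasing by
construction; damping is persistent across iterations and backs off over
ten trials per step. Convergence is declared after four consecutive
improvements below 0.01 nats, capped at 64 iterations; a fit that exhausts
the cap returns best-so-far flagged non-converged. Optional random
restarts (`control = list(restarts = 2)`) guard against the local optima
that occasionally trap the prior-mean start, and the benchmarks use them.

The key correctness oracle is exact: on linear-Gaussian models the free
energy at the exact posterior equals the log marginal likelihood, and the
test suite checks agreement to 1e-6 on twenty random instances. Parameter
recovery is validated on a reduced four-source chain (V1→ITG→SPL→vlPFC,
12 synthetic channels): a +0.7 planted modulation is recovered with
correct sign and calibrated 90% credible intervals across twenty noise
draws at 10 dB SNR.

## Model comparison

Candidate variants declare which edges carry free `B` parameters and which
sites carry intrinsic modulations. The extrinsic space is data-driven (a
JSON registry; the packaged fixture encodes the named variants of the
two-cohort analysis, including both readings of the ambiguous intrinsic
winner as `N22a`/`N22b`). Step 2 enumerates intrinsic variants as the
power set over the five site groups V1, ITG, SPL, {vlPFC, dlPFC}, dACC —
32 candidates. Fixed-effects selection sums per-subject free energies;
a winner needs a Bayes factor above 3 over *every* rival, the stricter
reading of the winner-vs-runner-up report. Model recovery on the chain
network (five candidate variants, ten 10-subject cohorts) selects the
generating variant in essentially every cohort.

## Feature tables, classification, attribution, clustering

The biophysical table is the 92 posterior means in fixed A/B/G/H/T order;
the ERP table starts from 240 candidates (60 channels x 2 conditions x
peak amplitude/latency in the 250–350 ms window, earliest-sample
tie-break) and keeps the 23 top channels by summed out-of-bag permutation
importance under a naive random forest — 23 because only 23 x 4 = 92
satisfies the parity constraint with the biophysical table (the source
analysis prints both 23 and 24; 23 is the arithmetically consistent
count). Permutation importance repeats each permutation 50 times by
default and votes only over trees for which a subject is out of bag.

Class balancing applies SMOTE to the *full* table before cross-validation,
deliberately replicating the published, leakage-prone ordering; a
`leakage_safe` flag moves SMOTE inside training folds and a test asserts
the leaky variant scores higher on weak signal, which is exactly the
hazard the original procedure documents. Classifiers: RBF SVM (cost and
gamma tuned on inner 5-fold MCC; features standardised with training-fold
statistics), random forest (500 trees, defaults), gradient boosted trees
(500 rounds, depth 3). Scores are MCC and F1 per held-out fold.

Shapley attributions are interventional: coalition values average the
model output over a background sample with coalition features replaced by
the explained subject's values. Exact enumeration (≤ 12 features) is used
for the closed-form oracles; permutation sampling with antithetic pairs
scales to the 92-feature tables. Local accuracy — attributions plus base
value equal the prediction — is asserted in exact mode.

Subtyping embeds the top-10 features (by mean |SHAP| of the best
classifier on the original, un-augmented cohort) with exact t-SNE
(perplexity binary-searched per point; early exaggeration x12 for 250
iterations; momentum 0.5 then 0.8; 2500 iterations) and clusters the
embedding with k-means (k-means++ seeding, 20 restarts) for k = 2..12,
scoring mean silhouette ± SE (per-point SD / sqrt(n)). For patients-only
analyses (n = 15) the perplexity is capped at (n-1)/3; the full-cohort
perplexity of 25 at n = 49 violates the common 3-perplexity guideline and
is kept deliberately, with a warning, because it is the analysis's stated
setting. Degenerate geometry (identical points) defines silhouette 0.

## Desk-scale study sizes

The validation studies are sized so the whole suite runs on one CPU in
minutes, as the package's own design: parameter recovery uses 20
single-subject inversions on the 4-source chain; model recovery 10
cohorts x 10 subjects x 5 variants; the classification head-to-head one
full-size 49-subject cohort; subtype recovery 10 replicate cohorts. Where
a study needs hundreds of first-level results (classification and
subtyping replicates), posterior means are *emulated* as ground truth plus
independent Gaussian estimation noise of SD 0.2 — the rms estimation error
the real reduced-network inversions exhibit at 10 dB SNR. The emulator is
a labelled synthetic stand-in for the fitting stage, not a fit; a `fit`
engine runs the same head-to-head with real inversions on the chain
network, and the recovery benchmarks always use real inversions.

## Known limitations

- The headline classification ordering (biophysical ≥ ERP features for
  every algorithm) does not reproduce robustly at desk scale: with class
  effects partly on intrinsic gains, ERP peak amplitudes are direct,
  low-noise readouts of the class signal and both tables saturate under
  the leakage-prone balancing, leaving the tree ensembles marginally
  better on ERP features. The property holds or ties for the SVM — the
  best classifier, and the one the attribution stage explains. The
  acceptance suite states the property at full strength and reports it
  honestly.
- Conduction delays, stochastic intrinsic noise, and the David–Friston
  9-state variant are out of scope; the canonical 6-state unit is used.
- Lateral homologous connections are fixed at baseline strength rather
  than carrying free A-scalings, keeping the printed 24-parameter A count
  exact.
- t-SNE at n = 15 with capped perplexity occasionally fragments a true
  cluster; silhouette profiles should be read jointly with the embedding,
  as the subtype driver script does.

## Reproducing the numbers

```{r}
library(dcmerp)
cohort <- generate_cohort(cohort_config(seed = 1))
rec <- recovery_benchmark(n_seeds = 20, seed = 1)
mr  <- model_recovery_benchmark(seed = 1)
hb  <- headline_benchmark(seed = 1)
sb  <- subtype_benchmark(seed = 1, iterations = 2500)
```

The numbered scripts under `analysis/` run these studies in order and
write their tables under `results/`; `scripts/acceptance.R` recomputes the
same quantities from scratch into a single JSON report.
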