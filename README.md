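# dcmerp

Biophysical biomarkers from event-related potentials (ERPs) via
neural-mass model inversion.

## The problem

Scalp EEG features such as ERP peak amplitude and latency are easy to
measure but hard to interpret biologically, and they struggle with the
heterogeneity of psychiatric conditions: very different neural causes can
produce similar scalp waveforms. An alternative is to fit a biophysical
generative model of the cortical network producing the ERP and use its
*parameters* — synaptic gains, time constants, and the task-dependent
modulation of inter-areal connectivity — as interpretable, low-dimensional
features for classification and subtyping.

`dcmerp` implements that pipeline end to end for a two-condition conflict
task on a 10-source cortical network (V1, dACC, bilateral ITG, SPL, vlPFC,
dlPFC), and validates every stage on synthetic cohorts whose ground truth
is known:

1. **Forward model** — a Jansen–Rit neural mass per source: three
   populations coupled by second-order synaptic kernels
   `y'' = (H/τ)·input − (2/τ)·y' − y/τ²` and a centred firing sigmoid
   `S(v) = 2e₀/(1+e^{r(v₀−v)}) − 2e₀/(1+e^{rv₀})`; forward/backward/
   lateral connections between sources; condition-dependent effective
   connectivity `strength = base·e^A` (control) and `base·e^{A+B}`
   (interference, on modulated edges).
2. **Inversion** — per-subject variational Laplace: Gauss–Newton ascent on
   the free energy `F = E_q[log p(y|θ)] − KL(q‖prior)`, Gaussian posterior
   over the 92 log-scaling parameters (24 A + 24 B + 20 G + 4 H + 20 T).
3. **Model comparison** — candidate variants differing in which
   connections are modulated; fixed-effects Bayesian model selection (sum
   of per-subject F; winner requires Bayes factor > 3 over every rival);
   32 intrinsic variants enumerated on the extrinsic winner.
4. **Features & classification** — the 92 posterior means versus 240 ERP
   candidates (60 channels × 2 conditions × peak amplitude/latency,
   250–350 ms window) reduced to 23 channels for 92-feature parity; SMOTE
   balancing (15→34 patients), 10-fold CV of SVM / random forest /
   gradient boosted trees scored by MCC and F1.
5. **Attribution & subtyping** — Shapley values (exact enumeration on
   small models, permutation sampling at scale), rank-paired comparison of
   the two feature sets, and t-SNE + k-means silhouette analysis to
   recover planted patient subtypes.

## Worked example

```r
library(dcmerp)

# a ground-truth cohort: 34 controls, 15 patients in 2 subtypes
cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> cohort: 49 subjects ( 34 controls / 15 patients ), 98 ERP epochs

# recover a planted connectivity modulation on the reduced 4-source chain
rec <- recovery_benchmark(n_seeds = 20, b_true = 0.7, snr_db = 10, seed = 1)
c(coverage = rec$coverage, sign = rec$sign_accuracy)
#> coverage     sign
#>     0.85     1.00

# fixed-effects model selection across 10 replicate cohorts
mr <- model_recovery_benchmark(seed = 1)
mr$winners
#> [1] "gen" "gen" "gen" "gen" "gen" "gen" "gen" "gen" "gen" "gen"
```

The planted +0.7 modulation lies inside its 90% credible interval in 17 of
20 independent fits with the correct sign in all of them, and BMS selects
the generating variant in 10 of 10 cohorts: the inversion recovers both
parameters and structure at 10 dB channel SNR.

The numbered scripts under `analysis/` run the full study in order —
cohort simulation and ERP condition tests, parameter recovery, model
selection, the DCM-vs-ERP classification head-to-head with SHAP
attribution, and subtype clustering — writing their tables under
`results/`.

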