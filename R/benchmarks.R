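#' Desk-scale benchmark suite on the reduced chain network
#'
#' The inversion-heavy validation studies (parameter recovery, model
#' recovery, DCM-vs-ERP classification) run on the 4-source chain network
#' [chain_network()] with a 12-channel synthetic montage: the same code
#' paths as the 10-source analysis at a fraction of the cost.
#'
#' @name benchmarks
NULL

bench_channels <- function() montage_60()[c(1, 5, 12, 21, 26, 30, 34, 40, 48, 53, 55, 59)]

#' @rdname benchmarks
#' @param network the benchmark network.
#' @param seed gain-matrix seed.
#' @export
bench_gain <- function(network = chain_network(), seed = 202L) {
  gain_matrix(network, channels = bench_channels(), seed = seed)
}

#' Spatial modes of the noiseless baseline template
#'
#' A fixed observation projector shared by all subjects of a benchmark:
#' the top left-singular vectors of the baseline (prior-mean) two-condition
#' channel prediction.
#'
#' @param network,const,gain forward-model ingredients.
#' @param n_modes modes kept.
#' @export
template_projection <- function(network, const, gain, n_modes = 4) {
  erps <- lapply(c("control", "interference"), function(cond) {
    st <- simulate_sources(network, const, condition = cond)
    project_to_channels(st, gain, Inf, subject = "template", condition = cond)
  })
  reduce_spatial_modes(erps, n_modes)$projection
}

#' Candidate model space for the reduced network
#'
#' Five variants differing in which connections are condition-modulated:
#' `gen` (the scaled-down analogue of the control-cohort winner: forward
#' modulation beyond V1), `allfwd` (all feedforward, the patient-cohort
#' analogue), `first` (V1->ITG only), `bwd` (backward edges), `last`
#' (SPL->vlPFC only).
#'
#' @param network the [chain_network()].
#' @return named list of [model_variant()].
#' @export
chain_variants <- function(network = chain_network()) {
  v <- list(
    model_variant("gen",    c("ITG->SPL", "SPL->vlPFC"), network = network),
    model_variant("allfwd", c("V1->ITG", "ITG->SPL", "SPL->vlPFC"), network = network),
    model_variant("first",  c("V1->ITG"), network = network),
    model_variant("bwd",    c("SPL->ITG", "vlPFC->SPL"), network = network),
    model_variant("last",   c("SPL->vlPFC"), network = network))
  stats::setNames(v, vapply(v, `[[`, "", "id"))
}

# simulate one subject's two-condition ERP pair from a full theta
bench_erp_pair <- function(theta, network, const, gain, snr_db, subject = "s") {
  lapply(c("control", "interference"), function(cond) {
    st <- simulate_sources(network, const, theta, cond)
    project_to_channels(st, gain, snr_db, subject = subject, condition = cond)
  })
}

#' Parameter-recovery study
#'
#' Plants `b_true` on one forward modulation (ITG->SPL), simulates a
#' subject at the given SNR, inverts with the generating variant's B
#' parameters free, and checks whether the truth lies in the central 90%
#' credible interval and whether the posterior-mean sign is correct,
#' across `n_seeds` independent noise draws.
#'
#' @param n_seeds replicate subjects.
#' @param b_true planted modulation (log-scaling).
#' @param snr_db channel SNR.
#' @param seed base seed.
#' @param n_modes spatial modes used in the inversion.
#' @return list: `coverage`, `sign_accuracy`, `posterior_sd` (mean over
#'   runs), `fits` (per-run mean/sd/inside/sign data.frame).
#' @export
recovery_benchmark <- function(n_seeds = 20, b_true = 0.7, snr_db = 10,
                               seed = 1L, n_modes = 4) {
  network <- chain_network()
  const <- default_constants(network)
  gain <- bench_gain(network)
  variant <- chain_variants(network)$gen
  priors <- prior_spec(network, variant, free = "B")
  target <- "B_f_ITG.SPL"
  theta <- param_template(network)
  theta[target] <- b_true
  rows <- lapply(seq_len(n_seeds), function(i) {
    erps <- withr_seed(seed * 1000 + i,
                       bench_erp_pair(theta, network, const, gain, snr_db,
                                      subject = paste0("r", i)))
    fit <- fit_subject(erps, network, const, variant, gain, priors,
                       n_modes = n_modes, control = list(restarts = 2))
    mu <- fit$mean[target]
    sd_ <- sqrt(diag(fit$cov))[match(target, names(fit$mean))]
    z <- stats::qnorm(0.95)
    data.frame(mean = unname(mu), sd = unname(sd_),
               inside = abs(mu - b_true) <= z * sd_,
               sign_ok = sign(mu) == sign(b_true),
               F = fit$F, converged = fit$converged)
  })
  df <- do.call(rbind, rows)
  list(coverage = mean(df$inside), sign_accuracy = mean(df$sign_ok),
       posterior_sd = mean(df$sd), fits = df)
}

#' Model-recovery study (FFX BMS)
#'
#' Generates replicate cohorts under the `gen` variant (its two forward
#' modulations at `b_true` plus small between-subject jitter), fits all
#' five candidate variants to every subject, and scores each cohort by
#' whether fixed-effects BMS selects the generating variant.
#'
#' @param n_cohorts replicate cohorts. @param n_subjects subjects each.
#' @param b_true planted modulation. @param jitter_sd between-subject SD on
#'   the planted parameters. @param snr_db channel SNR. @param seed base
#'   seed. @param n_modes spatial modes.
#' @return list: `selection_rate`, `winners` (per cohort), `bms` (list of
#'   `bms_result`).
#' @export
model_recovery_benchmark <- function(n_cohorts = 10, n_subjects = 10, b_true = 0.7,
                                     jitter_sd = 0.1, snr_db = 10, seed = 1L,
                                     n_modes = 4) {
  network <- chain_network()
  const <- default_constants(network)
  gain <- bench_gain(network)
  variants <- chain_variants(network)
  gen_edges <- c("B_f_ITG.SPL", "B_f_SPL.vlPFC")
  results <- lapply(seq_len(n_cohorts), function(cidx) {
    Fm <- matrix(NA_real_, n_subjects, length(variants),
                 dimnames = list(NULL, names(variants)))
    for (s in seq_len(n_subjects)) {
      theta <- param_template(network)
      erps <- withr_seed(seed * 10000 + cidx * 100 + s, {
        theta[gen_edges] <- b_true + stats::rnorm(2, 0, jitter_sd)
        bench_erp_pair(theta, network, const, gain, snr_db,
                       subject = sprintf("c%ds%d", cidx, s))
      })
      for (v in names(variants)) {
        fit <- fit_subject(erps, network, const, variants[[v]], gain,
                           prior_spec(network, variants[[v]], free = "B"),
                           n_modes = n_modes, control = list(restarts = 2))
        Fm[s, v] <- fit$F
      }
    }
    ffx_bms(Fm)
  })
  winners <- vapply(results, `[[`, "", "winner")
  list(selection_rate = mean(winners == "gen", na.rm = TRUE),
       winners = winners, bms = results)
}

#' DCM-vs-ERP classification head-to-head at desk scale
#'
#' Builds the two rival feature tables from one synthetic cohort and
#' cross-validates the three classifiers on each (SMOTE applied before CV,
#' as in the published procedure).
#'
#' Two engines are available. `"emulator"` (default) runs the full-scale
#' design -- the 10-source MSIT network, 49 subjects, 60 channels, the 92
#' biophysical features against 240 ERP candidates reduced to 23 channels
#' -- with first-level posterior means emulated as truth plus Gaussian
#' estimation noise of SD `est_sd` (set to the rms estimation error the
#' reduced-network inversion study measures at 10 dB SNR). `"fit"` runs
#' real variational-Laplace inversions on the reduced chain network
#' (all parameter categories free, B restricted to the `allfwd` variant's
#' edges), trading scale for end-to-end fitting.
#'
#' @param seed cohort and pipeline seed.
#' @param effect_scale class-effect multiplier (study condition: 1).
#' @param engine `"emulator"` (full-scale design, emulated first level) or
#'   `"fit"` (reduced network, real inversions).
#' @param est_sd first-level estimation-noise SD for the emulator engine.
#' @param n_control,n_patient class sizes.
#' @param snr_db channel SNR.
#' @param algorithms classifiers to run.
#' @param n_perm permutations in the channel-selection importance.
#' @return list: `cv_dcm`, `cv_erp` (named lists of `cv_result`),
#'   `dcm_table`, `erp_table`, `cohort`, `posteriors`.
#' @export
headline_benchmark <- function(seed = 1L, effect_scale = 1,
                               engine = c("emulator", "fit"), est_sd = 0.2,
                               n_control = 34, n_patient = 15, snr_db = 10,
                               algorithms = c("svm", "random_forest",
                                              "gradient_boosted_trees"),
                               n_perm = 5) {
  engine <- match.arg(engine)
  if (engine == "emulator") {
    network <- msit_network()
    const <- default_constants(network)
    gain <- gain_matrix(network)
  } else {
    network <- chain_network()
    const <- default_constants(network)
    gain <- bench_gain(network)
  }
  cfg <- cohort_config(n_control = n_control, n_patient = n_patient,
                       effect_scale = effect_scale, snr_db = snr_db, seed = seed)
  coh <- generate_cohort(cfg, network, const, gain)
  if (engine == "emulator") {
    posteriors <- simulate_first_level_estimates(coh, est_sd = est_sd, seed = seed)
  } else {
    variant <- chain_variants(network)$allfwd
    priors <- prior_spec(network, variant, free = c("A", "B", "G", "H", "T"))
    posteriors <- lapply(seq_len(nrow(coh$subjects)), function(i) {
      sid <- coh$subjects$subject[i]
      fit_subject(coh$erps[paste(sid, c("control", "interference"), sep = "_")],
                  network, const, variant, gain, priors,
                  control = list(max_iter = 32))
    })
  }
  dcm_ft <- build_dcm_features(posteriors, coh$subjects$label, network)
  pp <- do.call(rbind, lapply(coh$erps, extract_pp_features))
  cand <- build_eeg_candidates(pp, stats::setNames(coh$subjects$label,
                                                   coh$subjects$subject))
  erp_ft <- select_channels(cand, target_feature_count = ncol(dcm_ft$values),
                            n_perm = n_perm, ntree = 200, seed = seed)
  list(cv_dcm = classify_features(dcm_ft, algorithms, seed = seed),
       cv_erp = classify_features(erp_ft, algorithms, seed = seed),
       dcm_table = dcm_ft, erp_table = erp_ft,
       cohort = coh, posteriors = posteriors)
}

#' Subtype-recovery study
#'
#' Replicate full-scale cohorts (10-source network, 34/15 classes, two
#' patient subtypes); per replicate, emulated first-level estimates feed an
#' SVM whose sampling-mode SHAP ranking picks the top-10 features, the
#' patients-only rows embed with t-SNE, and k-means silhouettes over
#' `k_range` are scored for whether k = 2 attains the maximum mean
#' silhouette. First-level estimates use the desk-scale estimate emulator
#' ([simulate_first_level_estimates()]) so that 10 replicates stay cheap;
#' SHAP uses 24 sampling permutations over a seeded 24-row background
#' subsample, enough for a stable top-10 ranking.
#'
#' @param n_replicates replicate cohorts. @param effect_scale class-effect
#'   multiplier. @param est_sd first-level estimation noise SD.
#' @param seed base seed. @param k_range candidate cluster numbers.
#' @param iterations t-SNE iterations.
#' @return list: `k2_rate` (fraction of replicates with argmax silhouette
#'   at k = 2), `argmax_k`, `reports`.
#' @export
subtype_benchmark <- function(n_replicates = 10, effect_scale = 1, est_sd = 0.2,
                              seed = 1L, k_range = 2:8, iterations = 2500) {
  network <- msit_network()
  const <- default_constants(network)
  gain <- gain_matrix(network)
  res <- lapply(seq_len(n_replicates), function(rep) {
    cfg <- cohort_config(effect_scale = effect_scale, seed = seed * 100 + rep)
    coh <- generate_cohort(cfg, network, const, gain)
    posts <- simulate_first_level_estimates(coh, est_sd = est_sd,
                                            seed = seed * 100 + rep)
    ft <- build_dcm_features(posts, coh$subjects$label, network)
    full <- fit_full_model(ft$values, ft$labels, "svm", seed = seed)
    bg <- ft$values[withr_seed(seed, sample(nrow(ft$values), 24)), , drop = FALSE]
    shap <- shap_explain(full$predict_value, ft$values, mode = "sampling",
                         background = bg, n_perm = 24, seed = seed)
    sc <- subtype_clustering(ft, shap, patients_only = TRUE, n_top = 10,
                             iterations = iterations, seed = seed,
                             k_range = k_range)
    sc$report
  })
  argmax <- vapply(res, function(r) r$k[which.max(r$mean_silhouette)], 0)
  list(k2_rate = mean(argmax == 2), argmax_k = argmax, reports = res)
}
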