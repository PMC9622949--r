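#' Synthetic cohort configuration
#'
#' Study-condition defaults mirror the modelled cohort: 34 controls, 15
#' patients in 2 subtypes, channel SNR 10 dB, one trial-averaged epoch per
#' subject and condition.
#'
#' @param n_control,n_patient class sizes (>= 0).
#' @param n_subtypes number of patient subtypes (>= 1).
#' @param effect_scale multiplier on all class/subtype mean shifts (>= 0).
#' @param param_sd per-category SD of the log-scaling parameters; a scalar
#'   is recycled over categories A, B, G, H, T.
#' @param snr_db channel signal-to-noise ratio (dB; may be `Inf`).
#' @param seed integer RNG seed.
#' @param offsets optional class-effect specification (see
#'   [default_offsets()]); NULL means the network's default.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 34, n_patient = 15, n_subtypes = 2,
                          effect_scale = 1,
                          param_sd = c(A = 0.2, B = 0.2, G = 0.1, H = 0.05, T = 0.1),
                          snr_db = 10, seed = 1L, offsets = NULL) {
  if (length(param_sd) == 1 && is.null(names(param_sd)))
    param_sd <- stats::setNames(rep(param_sd, 5), c("A", "B", "G", "H", "T"))
  stopifnot(n_control >= 0, n_patient >= 0, n_control == round(n_control),
            n_patient == round(n_patient), n_subtypes >= 1,
            effect_scale >= 0, all(param_sd >= 0),
            all(c("A", "B", "G", "H", "T") %in% names(param_sd)))
  if (is.na(snr_db) || snr_db == -Inf) stop("snr_db must be finite or +Inf")
  structure(list(n_control = as.integer(n_control), n_patient = as.integer(n_patient),
                 n_subtypes = as.integer(n_subtypes), effect_scale = effect_scale,
                 param_sd = param_sd, snr_db = snr_db, seed = as.integer(seed),
                 offsets = offsets),
            class = "cohort_config")
}

#' Default class/subtype effect placement
#'
#' Patients share a positive shift of the excitatory synaptic gain (G_He)
#' at V1 and bilateral vlPFC/dlPFC; the two subtypes differ in which extra
#' forward connection is condition-modulated — subtype 1 shifts B on
#' vlPFC->dACC (both hemispheres), subtype 2 on V1->ITG. These are exactly
#' the connections the patient-cohort model comparison finds modulated over
#' and above the control winner. All shifts are multiplied by the config's
#' `effect_scale`.
#'
#' @param network a [network_spec()]; networks without those sources (e.g.
#'   the reduced chain) get an analogous placement on their own edges.
#' @return list with `patient` (named shift vector applied to every
#'   patient) and `subtype` (list of per-subtype named shift vectors).
#' @export
default_offsets <- function(network) {
  nm <- names(param_template(network))
  pick <- function(x) x[x %in% nm]
  if ("dACC" %in% network$sources) {
    list(patient = stats::setNames(rep(0.3, 5),
           pick(c("G_He_V1", "G_He_lvlPFC", "G_He_rvlPFC", "G_He_ldlPFC", "G_He_rdlPFC"))),
         subtype = list(
           stats::setNames(rep(0.5, 2), pick(c("B_f_lvlPFC.dACC", "B_f_rvlPFC.dACC"))),
           stats::setNames(rep(0.5, 2), pick(c("B_f_V1.lITG", "B_f_V1.rITG")))))
  } else {
    # reduced chain analogue: shared gain shift at the ends, subtype-specific
    # modulation of the first vs last forward edge
    fwd <- paste0("B_f_", gsub("->", ".", edge_keys(network$forward), fixed = TRUE))
    list(patient = stats::setNames(rep(0.3, 2),
           pick(paste0("G_He_", network$sources[c(1, network$n_sources)]))),
         subtype = list(stats::setNames(0.5, fwd[length(fwd)]),
                        stats::setNames(0.5, fwd[1])))
  }
}

#' Draw one subject's true biophysical parameters
#'
#' Log-scaling parameters are Gaussian around zero with per-category SD;
#' patients get additive mean shifts (`effect_scale` times the configured
#' offsets): the shared patient shift plus the shift of their subtype.
#' Uses the current RNG stream.
#'
#' @param label `"control"` or `"patient"`.
#' @param subtype patient subtype in `1..n_subtypes` (NA for controls).
#' @param config a [cohort_config()].
#' @param network a [network_spec()].
#' @return named vector over [param_template()].
#' @export
sample_subject_parameters <- function(label, subtype, config, network) {
  if (!label %in% c("control", "patient")) stop("unknown label: ", label)
  tmpl <- param_template(network)
  sd_vec <- unname(config$param_sd[param_categories(network)])
  theta <- stats::rnorm(length(tmpl), 0, sd_vec)
  names(theta) <- names(tmpl)
  if (label == "patient") {
    if (is.na(subtype) || subtype < 1 || subtype > config$n_subtypes)
      stop("invalid subtype for patient")
    off <- config$offsets %||% default_offsets(network)
    sub_off <- off$subtype[[((subtype - 1) %% length(off$subtype)) + 1]]
    for (o in list(off$patient, sub_off))
      if (length(o)) theta[names(o)] <- theta[names(o)] + config$effect_scale * o
  }
  theta
}

#' Generate a ground-truth cohort with simulated ERPs
#'
#' Draws true parameters per subject, simulates both task conditions from
#' them through the Jansen-Rit network, and projects to channels with white
#' noise at the configured SNR. Deterministic given the config seed (the
#' gain matrix has its own fixed seed and acts as the shared head model).
#'
#' @param config a [cohort_config()].
#' @param network,const,gain forward-model ingredients; defaults are the
#'   10-source MSIT network with its graded constants and the seeded
#'   60-channel synthetic gain.
#' @param duration,dt epoch length and integration step (ms).
#' @return list of class `cohort`: `subjects` (data.frame subject, label,
#'   subtype), `theta` (subjects x parameters truth), `erps` (named list of
#'   [subject_erp()], one per subject x condition), plus the ingredients.
#' @export
generate_cohort <- function(config, network = msit_network(),
                            const = default_constants(network),
                            gain = gain_matrix(network),
                            duration = 350, dt = 1) {
  n <- config$n_control + config$n_patient
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    label = rep(c("control", "patient"), c(config$n_control, config$n_patient)),
    subtype = NA_integer_, stringsAsFactors = FALSE)
  res <- withr_seed(config$seed, {
    if (config$n_patient > 0)
      subjects$subtype[subjects$label == "patient"] <-
        sample(rep_len(seq_len(config$n_subtypes), config$n_patient))
    theta <- t(vapply(seq_len(n), function(i)
      sample_subject_parameters(subjects$label[i], subjects$subtype[i], config, network),
      param_template(network)))
    rownames(theta) <- subjects$subject
    erps <- list()
    for (i in seq_len(n)) for (cond in c("control", "interference")) {
      st <- simulate_sources(network, const, theta[i, ], cond, duration, dt)
      erps[[paste(subjects$subject[i], cond, sep = "_")]] <-
        project_to_channels(st, gain, config$snr_db,
                            subject = subjects$subject[i], condition = cond)
    }
    list(subjects = subjects, theta = theta, erps = erps)
  })
  structure(c(res, list(config = config, network = network, const = const, gain = gain)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$label == "control"), "controls /",
      sum(x$subjects$label == "patient"), "patients ),",
      length(x$erps), "ERP epochs\n")
  invisible(x)
}

#' Serialise cohort ground truth to JSON
#'
#' Stores labels, subtypes, the true parameter matrix and the config; ERPs
#' go separately through [write_erp_csv()].
#'
#' @param cohort a [generate_cohort()] result. @param path file path.
#' @export
write_cohort_json <- function(cohort, path) {
  jsonlite::write_json(list(
    subjects = cohort$subjects,
    theta = as.data.frame(cohort$theta),
    config = cohort$config[c("n_control", "n_patient", "n_subtypes",
                             "effect_scale", "snr_db", "seed")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Emulate first-level posterior estimates at desk scale
#'
#' Produces stand-in posterior objects whose means are the cohort's true
#' parameters plus independent Gaussian estimation noise of SD `est_sd` —
#' an emulation of the first-level (per-subject) inversion stage used by
#' the replicate-heavy property checks where running hundreds of full
#' variational fits would be prohibitive. `est_sd` defaults to the
#' posterior spread the reduced-network recovery benchmark measures at
#' 10 dB SNR. These are synthetic estimates, not model fits.
#'
#' @param cohort a [generate_cohort()] result.
#' @param est_sd estimation-noise SD on every parameter.
#' @param seed RNG seed.
#' @return list of pseudo-`dcm_posterior` objects (fields `subject`,
#'   `variant_id = "estimate-emulator"`, `full_mean`, `cov`).
#' @export
simulate_first_level_estimates <- function(cohort, est_sd = 0.15, seed = 1L) {
  withr_seed(seed, lapply(seq_len(nrow(cohort$subjects)), function(i) {
    truth <- cohort$theta[i, ]
    structure(list(subject = cohort$subjects$subject[i],
                   variant_id = "estimate-emulator",
                   full_mean = truth + stats::rnorm(length(truth), 0, est_sd),
                   mean = NULL, cov = diag(est_sd^2, length(truth)),
                   F = NA_real_, converged = NA),
              class = "dcm_posterior")
  }))
}
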