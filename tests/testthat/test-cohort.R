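test_that("the default synthetic cohort matches the modelled study design", {
  cfg <- cohort_config(seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$subjects), 49)
  expect_equal(sum(coh$subjects$label == "control"), 34)
  expect_equal(sum(coh$subjects$label == "patient"), 15)
  expect_length(coh$erps, 98)
  expect_true(all(coh$subjects$subtype[coh$subjects$label == "patient"] %in% 1:2))
  expect_true(all(is.na(coh$subjects$subtype[coh$subjects$label == "control"])))
  expect_equal(ncol(coh$theta), 92)
  e <- coh$erps[[1]]
  expect_equal(dim(e$data), c(60, 351))
  expect_true(all(vapply(coh$erps, function(x) all(is.finite(x$data)), TRUE)))
})

test_that("cohort generation is deterministic given the seed", {
  net <- chain_network()
  cfg <- cohort_config(n_control = 3, n_patient = 2, seed = 99)
  g <- bench_gain(net)
  a <- generate_cohort(cfg, net, default_constants(net), g)
  b <- generate_cohort(cfg, net, default_constants(net), g)
  expect_identical(a$theta, b$theta)
  expect_identical(lapply(a$erps, `[[`, "data"), lapply(b$erps, `[[`, "data"))
  c2 <- generate_cohort(cohort_config(n_control = 3, n_patient = 2, seed = 100),
                        net, default_constants(net), g)
  expect_false(identical(a$theta, c2$theta))
})

test_that("configuration validation rejects invalid cohorts", {
  expect_error(cohort_config(n_control = -1), "n_control")
  expect_error(cohort_config(n_subtypes = 0), "n_subtypes")
  expect_error(cohort_config(snr_db = NaN), "snr_db")
  expect_error(cohort_config(effect_scale = -2), "effect_scale")
  cfg <- cohort_config()
  expect_error(sample_subject_parameters("case", 1, cfg, msit_network()),
               "unknown label")
  expect_error(sample_subject_parameters("patient", 99, cfg, msit_network()),
               "subtype")
})

test_that("zero parameter variance gives controls exactly the baseline vector", {
  cfg <- cohort_config(param_sd = 0, seed = 1)
  set.seed(1)
  th <- sample_subject_parameters("control", NA, cfg, msit_network())
  expect_identical(unname(th), rep(0, 92))
})

test_that("patient subtype shifts land on the configured connections at the right size", {
  net <- msit_network()
  cfg <- cohort_config(effect_scale = 1.5, seed = 1)
  off <- default_offsets(net)
  set.seed(31)
  draws <- t(replicate(10000, sample_subject_parameters("patient", 1, cfg, net)))
  target <- names(off$subtype[[1]])[1]
  want <- 1.5 * off$subtype[[1]][1]
  se <- cfg$param_sd["B"] / sqrt(10000)
  expect_lt(abs(mean(draws[, target]) - want), 3 * se)
  # a parameter with no offset stays centred at zero
  expect_lt(abs(mean(draws[, "A_f_V1.lITG"])), 3 * cfg$param_sd["A"] / sqrt(10000))
})

test_that("a null effect size makes patient and control parameters exchangeable", {
  net <- msit_network()
  cfg <- cohort_config(effect_scale = 0, seed = 1)
  set.seed(17)
  n <- 10000
  pat <- t(replicate(n, sample_subject_parameters("patient", 1, cfg, net)))
  ctl <- t(replicate(n, sample_subject_parameters("control", NA, cfg, net)))
  pvals <- vapply(seq_len(92), function(j)
    suppressWarnings(ks.test(pat[, j], ctl[, j])$p.value), 0)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("between-class separation grows with effect scale", {
  net <- msit_network()
  mahal <- vapply(c(0.5, 1, 2), function(es) {
    cfg <- cohort_config(effect_scale = es, seed = 1)
    set.seed(23)
    pat <- t(replicate(1000, sample_subject_parameters("patient", 1, cfg, net)))
    ctl <- t(replicate(1000, sample_subject_parameters("control", NA, cfg, net)))
    d <- colMeans(pat) - colMeans(ctl)
    v <- (apply(pat, 2, var) + apply(ctl, 2, var)) / 2
    sqrt(sum(d^2 / v))
  }, 0)
  expect_true(all(diff(mahal) > 0))
})

test_that("cohort ground truth serialises to JSON", {
  coh <- quick_cohort(n_control = 2, n_patient = 2)
  path <- tempfile(fileext = ".json")
  write_cohort_json(coh, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$subjects$label, coh$subjects$label)
  expect_equal(unname(as.matrix(back$theta)), unname(coh$theta), tolerance = 1e-12)
})

test_that("first-level estimate emulation preserves subjects and adds bounded noise", {
  coh <- quick_cohort(n_control = 4, n_patient = 3)
  est <- simulate_first_level_estimates(coh, est_sd = 0.1, seed = 2)
  expect_length(est, 7)
  devs <- vapply(seq_along(est), function(i)
    sd(est[[i]]$full_mean - coh$theta[i, ]), 0)
  expect_true(all(devs > 0.05 & devs < 0.2))
  est2 <- simulate_first_level_estimates(coh, est_sd = 0.1, seed = 2)
  expect_identical(est[[1]]$full_mean, est2[[1]]$full_mean)
})
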