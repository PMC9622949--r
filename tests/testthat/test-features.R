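make_posteriors <- function(theta_mat, subjects, variant_id = "N22a") {
  lapply(seq_len(nrow(theta_mat)), function(i)
    structure(list(subject = subjects[i], variant_id = variant_id,
                   full_mean = theta_mat[i, ]), class = "dcm_posterior"))
}

test_that("the biophysical feature table has the fixed 92-column layout", {
  net <- msit_network()
  tmpl <- param_template(net)
  theta <- matrix(rnorm(49 * 92), 49, 92, dimnames = list(NULL, names(tmpl)))
  posts <- make_posteriors(theta, sprintf("S%02d", 1:49))
  ft <- build_dcm_features(posts, rep(c("control", "patient"), c(34, 15)), net)
  expect_equal(dim(ft$values), c(49, 92))
  expect_identical(colnames(ft$values), names(tmpl))
  cats <- table(substr(colnames(ft$values), 1, 1))
  expect_equal(as.integer(cats[c("A", "B", "G", "H", "T")]), c(24L, 24L, 20L, 4L, 20L))
  # empty input keeps the full header
  ft0 <- build_dcm_features(list(), character(), net)
  expect_equal(dim(ft0$values), c(0, 92))
  expect_identical(colnames(ft0$values), names(tmpl))
  # column order is a stable snapshot
  expect_identical(colnames(ft$values)[1:3],
                   c("A_f_V1.lITG", "A_f_lITG.lSPL", "A_f_lSPL.lvlPFC"))
  # the common-connection column group is exposed
  expect_true(all(attr(ft, "common_connections") %in% colnames(ft$values)))
  expect_true("B_f_lITG.lSPL" %in% attr(ft, "common_connections"))
})

test_that("mixed model variants are rejected", {
  net <- msit_network()
  theta <- matrix(0, 2, 92, dimnames = list(NULL, names(param_template(net))))
  posts <- make_posteriors(theta, c("a", "b"))
  posts[[2]]$variant_id <- "M8"
  expect_error(build_dcm_features(posts, c("control", "patient"), net), "mixed")
})

test_that("the candidate ERP table enumerates channel x condition x feature", {
  coh <- quick_cohort(n_control = 4, n_patient = 3)
  pp <- do.call(rbind, lapply(coh$erps, extract_pp_features))
  labels <- stats::setNames(coh$subjects$label, coh$subjects$subject)
  cand <- build_eeg_candidates(pp, labels)
  expect_equal(ncol(cand$values), 12 * 4)
  expect_equal(nrow(cand$values), 7)
  # one-channel toy gives 4 columns
  toy <- pp[pp$channel == pp$channel[1], ]
  expect_equal(ncol(build_eeg_candidates(toy, labels)$values), 4)
  # column count is channels x 4 for any subset
  set.seed(9)
  for (k in c(2, 5, 9)) {
    chs <- sample(unique(pp$channel), k)
    sub <- pp[pp$channel %in% chs, ]
    expect_equal(ncol(build_eeg_candidates(sub, labels)$values), 4 * k)
  }
  # missing condition errors
  expect_error(build_eeg_candidates(pp[pp$condition == "control", ], labels),
               "missing")
})

test_that("a 60-channel candidate set reduces to 23 channels for 92-feature parity", {
  set.seed(1)
  n <- 30
  channels <- montage_60()
  labels <- rep(c("control", "patient"), length.out = n)
  vals <- matrix(rnorm(n * 240), n,
                 dimnames = list(NULL, as.vector(t(
                   outer(as.vector(outer(channels, c("control", "interference"),
                                         paste, sep = ".")),
                         c("amplitude", "latency"), paste, sep = ".")))))
  cand <- feature_table(vals, paste0("s", 1:n), labels, "erp")
  sel <- select_channels(cand, 92, n_perm = 2, ntree = 60, seed = 1)
  expect_length(attr(sel, "selected_channels"), 23)
  expect_equal(ncol(sel$values), 92)
  expect_error(select_channels(cand, 90), "divisible")
})

test_that("channel selection finds a planted informative channel", {
  # one channel's features carry the label; the rest are pure noise
  channels <- montage_60()[1:12]
  cols <- as.vector(t(outer(as.vector(outer(channels, c("control", "interference"),
                                            paste, sep = ".")),
                            c("amplitude", "latency"), paste, sep = ".")))
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    labels <- rep(c("control", "patient"), each = n / 2)
    vals <- matrix(rnorm(n * length(cols)), n, dimnames = list(NULL, cols))
    inf_cols <- grepl("^F5\\.", cols)
    vals[, inf_cols] <- (labels == "patient") + rnorm(n * sum(inf_cols), sd = 0.3)
    cand <- feature_table(vals, paste0("s", 1:n), labels, "erp")
    sel <- select_channels(cand, 4, n_perm = 3, ntree = 100, seed = s)
    attr(sel, "selected_channels") == "F5"
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("permuting a label-independent constant feature changes error by about zero", {
  set.seed(4)
  n <- 40
  x <- cbind(signal = rep(c(0, 1), each = n / 2) + rnorm(n, sd = 0.2),
             constant = rep(1, n) + rnorm(n, sd = 1e-6),
             noise = rnorm(n))
  labels <- rep(c("a", "b"), each = n / 2)
  pi <- permutation_importance(x, labels, n_perm = 50, ntree = 150, seed = 2)
  expect_lt(abs(pi$importance["constant"]),
            max(2 * pi$se["constant"], 1e-8) + 1e-12)
  expect_gt(pi$importance["signal"], pi$importance["constant"])
})

test_that("channel selection is invariant to candidate column order", {
  set.seed(2)
  channels <- montage_60()[1:8]
  cols <- as.vector(t(outer(as.vector(outer(channels, c("control", "interference"),
                                            paste, sep = ".")),
                            c("amplitude", "latency"), paste, sep = ".")))
  n <- 30
  labels <- rep(c("control", "patient"), length.out = n)
  vals <- matrix(rnorm(n * length(cols)), n, dimnames = list(NULL, cols))
  vals[, grepl("^AF4\\.", cols)] <- (labels == "patient") + rnorm(n * 4, sd = 0.3)
  cand <- feature_table(vals, paste0("s", 1:n), labels, "erp")
  perm <- sample(ncol(vals))
  cand2 <- feature_table(vals[, perm], paste0("s", 1:n), labels, "erp")
  s1 <- select_channels(cand, 8, n_perm = 3, ntree = 100, seed = 7)
  s2 <- select_channels(cand2, 8, n_perm = 3, ntree = 100, seed = 7)
  expect_identical(attr(s1, "selected_channels"), attr(s2, "selected_channels"))
})

test_that("feature tables write to CSV with subject and label columns", {
  ft <- feature_table(matrix(1:4, 2, dimnames = list(NULL, c("f1", "f2"))),
                      c("a", "b"), c("control", "patient"), "dcm")
  path <- tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("subject_id", "label", "f1", "f2"))
  expect_equal(back$f1, c(1, 2))
})
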