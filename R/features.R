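#' Subjects-by-features table
#'
#' @param values numeric matrix, rows = subjects, named columns.
#' @param subjects subject ids. @param labels class labels aligned with
#'   rows. @param provenance `"dcm"` or `"erp"`.
#' @export
feature_table <- function(values, subjects, labels, provenance) {
  values <- as.matrix(values)
  stopifnot(!anyNA(values), !anyDuplicated(colnames(values)),
            nrow(values) == length(subjects), length(labels) == length(subjects))
  structure(list(values = values, subjects = subjects, labels = labels,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table (", x$provenance, "): ", nrow(x$values), " subjects x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`. @param path CSV path (columns subject_id,
#'   label, then features).
#' @export
write_feature_csv <- function(x, path) {
  df <- data.frame(subject_id = x$subjects, label = x$labels,
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Biophysical (DCM) feature table from first-level posteriors
#'
#' Posterior means arranged in the fixed A/B/G/H/T template order — 92
#' columns for the 10-source MSIT network. All posteriors must come from
#' the same model variant.
#'
#' @param posteriors list of `dcm_posterior` (with `full_mean`), one per
#'   subject.
#' @param labels class labels aligned with `posteriors`.
#' @param network the [network_spec()] defining the template.
#' @return a [feature_table()] with provenance `"dcm"`. The attribute
#'   `common_connections` names the column group of connections shared by
#'   both cohorts' winning models.
#' @export
build_dcm_features <- function(posteriors, labels, network = msit_network()) {
  tmpl <- param_template(network)
  if (length(posteriors)) {
    vids <- unique(vapply(posteriors, function(p) p$variant_id %||% "?", ""))
    if (length(vids) > 1) stop("mixed model variants: ", paste(vids, collapse = ", "))
    vals <- t(vapply(posteriors, function(p) p$full_mean[names(tmpl)], tmpl))
    subj <- vapply(posteriors, function(p) p$subject %||% "?", "")
  } else {
    vals <- matrix(numeric(), 0, length(tmpl), dimnames = list(NULL, names(tmpl)))
    subj <- character()
  }
  ft <- feature_table(vals, subj, labels, "dcm")
  common <- c("B_f_lITG.lSPL", "B_f_lSPL.lvlPFC", "B_f_lSPL.ldlPFC", "B_f_lvlPFC.ldlPFC",
              "B_f_rITG.rSPL", "B_f_rSPL.rvlPFC", "B_f_rSPL.rdlPFC", "B_f_rvlPFC.rdlPFC",
              "G_He_V1", "G_He_lvlPFC", "G_He_rvlPFC", "G_He_ldlPFC", "G_He_rdlPFC",
              "G_Hi_V1", "G_Hi_lvlPFC", "G_Hi_rvlPFC", "G_Hi_ldlPFC", "G_Hi_rdlPFC")
  attr(ft, "common_connections") <- intersect(common, colnames(ft$values))
  ft
}

#' Candidate ERP feature table
#'
#' One column per channel x condition x {amplitude, latency} — 240
#' candidates for 60 channels. Errors if any subject misses a channel or
#' condition.
#'
#' @param pp long Positive-Potential feature table ([extract_pp_features()]
#'   rows for every subject and both conditions).
#' @param labels named or ordered class labels per subject (aligned with
#'   the sorted unique subjects of `pp`).
#' @return a [feature_table()] with provenance `"erp"`.
#' @export
build_eeg_candidates <- function(pp, labels) {
  subjects <- sort(unique(pp$subject))
  channels <- sort(unique(pp$channel))
  conds <- c("control", "interference")
  cols <- as.vector(outer(channels, conds, function(ch, cn)
    paste(ch, cn, sep = ".")))
  cols <- as.vector(t(outer(cols, c("amplitude", "latency"), paste, sep = ".")))
  vals <- matrix(NA_real_, length(subjects), length(cols),
                 dimnames = list(subjects, cols))
  for (cn in conds) {
    d <- pp[pp$condition == cn, ]
    if (!nrow(d)) next
    key <- paste(d$channel, cn, sep = ".")
    vals[cbind(match(d$subject, subjects), match(paste0(key, ".amplitude"), cols))] <- d$amplitude
    vals[cbind(match(d$subject, subjects), match(paste0(key, ".latency"), cols))] <- d$latency
  }
  if (anyNA(vals)) stop("missing channel/condition combinations for some subjects")
  if (!is.null(names(labels))) labels <- labels[subjects]
  feature_table(vals, subjects, unname(labels), "erp")
}

#' Out-of-bag permutation importance of every feature
#'
#' Fits a default-hyperparameter (naive) random forest and scores each
#' feature by the mean increase in out-of-bag prediction error after
#' permuting that feature's column, over `n_perm` independent permutations.
#' Per-tree predictions are restricted to the trees for which a subject is
#' out of bag.
#'
#' @param x feature matrix. @param labels binary class labels.
#' @param n_perm permutations per feature. @param ntree forest size.
#' @param seed RNG seed.
#' @return list: `importance` (named mean error increase), `se` (standard
#'   error over permutations), `baseline_error`.
#' @export
permutation_importance <- function(x, labels, n_perm = 50, ntree = 500, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(labels)
  n <- nrow(x)
  withr_seed(seed, {
    rf <- randomForest::randomForest(x, y, ntree = ntree, keep.inbag = TRUE)
    oob <- rf$inbag == 0
    lev <- levels(y)
    # stack n_perm permuted copies of the data per feature and predict once,
    # then majority-vote within each copy using only the trees for which the
    # subject is out of bag
    base_ind <- predict(rf, x, predict.all = TRUE)$individual
    vote <- function(ind, mask) {
      v1 <- rowSums((ind == lev[1]) & mask)
      v2 <- rowSums((ind == lev[2]) & mask)
      factor(ifelse(v1 >= v2, lev[1], lev[2]), levels = lev)
    }
    err0 <- mean(vote(base_ind, oob) != y)
    p <- ncol(x)
    imp <- se <- numeric(p)
    mask_rep <- oob[rep(seq_len(n), n_perm), , drop = FALSE]
    y_rep <- rep(y, n_perm)
    for (j in seq_len(p)) {
      xp <- x[rep(seq_len(n), n_perm), , drop = FALSE]
      for (r in seq_len(n_perm)) {
        rows <- (r - 1) * n + seq_len(n)
        xp[rows, j] <- x[sample.int(n), j]
      }
      ind <- predict(rf, xp, predict.all = TRUE)$individual
      wrong <- vote(ind, mask_rep) != y_rep
      errs <- vapply(seq_len(n_perm), function(r)
        mean(wrong[(r - 1) * n + seq_len(n)]), 0)
      imp[j] <- mean(errs) - err0
      se[j] <- stats::sd(errs) / sqrt(n_perm)
    }
    list(importance = stats::setNames(imp, colnames(x)),
         se = stats::setNames(se, colnames(x)), baseline_error = err0)
  })
}

#' Reduce ERP candidates to a channel subset matching the DCM feature count
#'
#' Scores each channel by the summed permutation importance of its four
#' features (2 conditions x amplitude/latency) under a naive random forest,
#' and keeps the top `target_feature_count / 4` channels — 23 channels for
#' the 92-feature parity with the DCM table.
#'
#' @param candidates a [build_eeg_candidates()] table.
#' @param target_feature_count total features to keep; must be divisible
#'   by 4.
#' @param n_perm,ntree,seed forwarded to [permutation_importance()].
#' @return the reduced [feature_table()]; attributes `selected_channels`
#'   and `channel_scores`.
#' @export
select_channels <- function(candidates, target_feature_count = 92,
                            n_perm = 50, ntree = 500, seed = 1L) {
  if (target_feature_count %% 4 != 0) stop("target_feature_count must be divisible by 4")
  n_keep <- target_feature_count / 4
  cols <- colnames(candidates$values)
  channels <- unique(sub("\\..*$", "", cols))
  if (n_keep > length(channels)) stop("not enough channels")
  # canonical column order, so selection is invariant to input column order
  ord <- order(cols)
  x <- candidates$values[, ord, drop = FALSE]
  pi <- permutation_importance(x, candidates$labels, n_perm, ntree, seed)
  ch_of <- sub("\\..*$", "", colnames(x))
  scores <- vapply(split(pi$importance, ch_of), sum, 0)
  keep <- names(sort(scores, decreasing = TRUE))[seq_len(n_keep)]
  sel <- cols[sub("\\..*$", "", cols) %in% keep]
  out <- feature_table(candidates$values[, sel, drop = FALSE],
                       candidates$subjects, candidates$labels, "erp")
  attr(out, "selected_channels") <- keep
  attr(out, "channel_scores") <- sort(scores, decreasing = TRUE)
  out
}
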