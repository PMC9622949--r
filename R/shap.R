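#' Shapley-value feature attribution
#'
#' Interventional Shapley values of a model's continuous output: the value
#' of a coalition S is the model output averaged over background rows with
#' the features in S replaced by the explained subject's values. `exact`
#' mode enumerates all 2^p coalitions (allowed for p <= 12) and satisfies
#' local accuracy to numerical precision; `sampling` mode averages marginal
#' contributions over random feature permutations (antithetic pairs).
#'
#' @param predict_fn function: feature matrix -> numeric model output.
#' @param x subjects x features matrix to explain.
#' @param mode `"exact"` or `"sampling"`.
#' @param background background data for the interventional expectation
#'   (default `x`).
#' @param n_perm permutations per subject in sampling mode.
#' @param seed RNG seed (sampling mode).
#' @return list of class `shap_result`: `values` (subjects x features),
#'   `base_value` (mean background prediction), `mean_abs` (named, sorted
#'   order preserved as input order), `rank` (feature names by descending
#'   mean |SHAP|).
#' @export
shap_explain <- function(predict_fn, x, mode = c("exact", "sampling"),
                         background = x, n_perm = 64, seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  background <- as.matrix(background)
  p <- ncol(x)
  preds <- predict_fn(x)
  if (!all(is.finite(preds))) stop("non-finite model predictions")
  base <- mean(predict_fn(background))
  phi <- if (mode == "exact") {
    if (p > 12) stop("exact mode limited to <= 12 features")
    shap_exact(predict_fn, x, background)
  } else {
    withr_seed(seed, shap_sampling(predict_fn, x, background, n_perm))
  }
  dimnames(phi) <- dimnames(x)
  ma <- colMeans(abs(phi))
  structure(list(values = phi, base_value = base, mean_abs = ma,
                 rank = names(sort(ma, decreasing = TRUE)), mode = mode),
            class = "shap_result")
}

shap_exact <- function(predict_fn, x, background) {
  p <- ncol(x)
  nb <- nrow(background)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  s <- 0:(p - 1)                                   # sizes of subsets excluding j
  w <- factorial(s) * factorial(p - 1 - s) / factorial(p)
  phi <- matrix(0, nrow(x), p)
  for (i in seq_len(nrow(x))) {
    # coalition values: mean prediction with S set to subject i's values
    v <- vapply(seq_len(nrow(subsets)), function(s) {
      xb <- background
      on <- subsets[s, ]
      if (any(on)) xb[, on] <- matrix(x[i, on], nb, sum(on), byrow = TRUE)
      mean(predict_fn(xb))
    }, 0)
    sizes <- rowSums(subsets)
    for (j in seq_len(p)) {
      without <- which(!subsets[, j])
      with_j <- without + 2^(j - 1)   # expand.grid order: bit j flips every 2^(j-1)
      phi[i, j] <- sum(w[sizes[without] + 1] * (v[with_j] - v[without]))
    }
  }
  phi
}

shap_sampling <- function(predict_fn, x, background, n_perm) {
  p <- ncol(x)
  nb <- nrow(background)
  phi <- matrix(0, nrow(x), p)
  for (i in seq_len(nrow(x))) {
    acc <- numeric(p)
    for (r in seq_len(ceiling(n_perm / 2))) {
      perm <- sample.int(p)
      for (ord in list(perm, rev(perm))) {
        # build all coalition rows along the permutation path, batched
        xb <- background[rep(seq_len(nb), p + 1), , drop = FALSE]
        on <- logical(p)
        for (k in seq_len(p)) {
          on[ord[k]] <- TRUE
          rows <- k * nb + seq_len(nb)
          xb[rows, on] <- matrix(x[i, on], nb, sum(on), byrow = TRUE)
        }
        vals <- predict_fn(xb)
        vbar <- vapply(seq_len(p + 1), function(k)
          mean(vals[(k - 1) * nb + seq_len(nb)]), 0)
        acc[ord] <- acc[ord] + diff(vbar)
      }
    }
    phi[i, ] <- acc / (2 * ceiling(n_perm / 2))
  }
  phi
}

#' Compare the top-ranked mean |SHAP| values of two feature sets
#'
#' Pairs the i-th ranked mean absolute SHAP value of set A with the i-th of
#' set B and runs a two-sided paired t-test on the differences. Degenerate
#' inputs are handled explicitly: identical ranked values give p = 1;
#' nonzero differences with zero variance give `p = 0` with
#' `degenerate = TRUE` instead of an error.
#'
#' @param shap_a,shap_b `shap_result` objects.
#' @param top_n how many ranks to compare (>= 2).
#' @return list: `t`, `p_value`, `ci` (95% CI of the mean difference),
#'   `mean_diff`, `degenerate`, `ranked_a`, `ranked_b`.
#' @export
compare_top_features <- function(shap_a, shap_b, top_n = 10) {
  if (top_n < 2) stop("top_n must be >= 2")
  if (length(shap_a$mean_abs) < top_n || length(shap_b$mean_abs) < top_n)
    stop("fewer than top_n features available")
  a <- sort(shap_a$mean_abs, decreasing = TRUE)[seq_len(top_n)]
  b <- sort(shap_b$mean_abs, decreasing = TRUE)[seq_len(top_n)]
  d <- unname(a - b)
  if (stats::sd(d) < 1e-14) {
    if (all(abs(d) < 1e-14))
      return(list(t = 0, p_value = 1, ci = c(0, 0), mean_diff = 0,
                  degenerate = TRUE, ranked_a = a, ranked_b = b))
    return(list(t = sign(mean(d)) * Inf, p_value = 0, ci = c(mean(d), mean(d)),
                mean_diff = mean(d), degenerate = TRUE, ranked_a = a, ranked_b = b))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       ci = unname(tt$conf.int), mean_diff = mean(d), degenerate = FALSE,
       ranked_a = a, ranked_b = b)
}
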