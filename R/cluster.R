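#' Exact t-SNE embedding
#'
#' Standard (non-approximate) t-stochastic neighbour embedding: per-point
#' Gaussian bandwidths found by binary search to match the target
#' perplexity, symmetrised input affinities, Student-t output kernel, and
#' gradient descent on the KL divergence with momentum (0.5 then 0.8 after
#' iteration 250) and early exaggeration (x12 for the first 250
#' iterations). Exact affinities are fine at cohort scale (n ~ 49). The
#' common `n > 3 * perplexity` guideline is relaxed to a warning because
#' the analysis runs at perplexity 25 with 49 subjects.
#'
#' @param x subjects x features matrix (class labels are never passed).
#' @param dims output dimensionality (2 or 3).
#' @param perplexity target perplexity; must be `< n`.
#' @param iterations gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @param learning_rate gradient step size.
#' @return list of class `tsne_embedding`: `coords` (n x dims), `kl`
#'   (final KL divergence), `kl_trace` (KL at checkpoints, computed on the
#'   un-exaggerated affinities), `perplexity`, `iterations`, `seed`.
#' @export
tsne_embed <- function(x, dims = 3, perplexity = 25, iterations = 2500,
                       seed = 1L, learning_rate = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!dims %in% 2:3) stop("dims must be 2 or 3")
  if (perplexity >= n) stop("perplexity must be smaller than the number of points")
  if (n <= 3 * perplexity)
    warning("n <= 3 * perplexity; embedding may be under-determined", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite features")

  D2 <- as.matrix(stats::dist(x))^2
  P <- cond_affinities(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  exag_until <- min(250, iterations)
  withr_seed(seed, {
    Y <- matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    dY <- matrix(0, n, dims)
    kl_trace <- numeric()
    for (it in seq_len(iterations)) {
      Pe <- if (it <= exag_until) P * 12 else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      # gradient: 4 * sum_j (p_ij - q_ij) (y_i - y_j) / (1 + d^2)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      momentum <- if (it < 250) 0.5 else 0.8
      dY <- momentum * dY - learning_rate * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
      if (it == exag_until || it == iterations || it %% 500 == 0)
        kl_trace <- c(kl_trace, sum(P * log(P / Q)))
    }
    structure(list(coords = Y, kl = kl_trace[length(kl_trace)],
                   kl_trace = kl_trace, perplexity = perplexity,
                   iterations = iterations, seed = seed),
              class = "tsne_embedding")
  })
}

# conditional affinities: binary search each row's precision so that the
# Shannon entropy matches log(perplexity)
cond_affinities <- function(D2, perplexity, tol = 1e-5, max_iter = 60) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { h <- 0 } else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), 1e-300)
  }
  P
}

#' k-means over a k range with silhouette report
#'
#' k-means++ seeding, best of `restarts` runs by total within-cluster sum
#' of squares, for each k in `k_range`; per-point silhouettes
#' `s(i) = (b - a) / max(a, b)` come from [cluster::silhouette()] on the
#' embedding-space Euclidean distances. Degenerate geometry (all points
#' identical) yields silhouette 0 per point by convention. The SE of the
#' mean silhouette is the per-point SD divided by sqrt(n).
#'
#' @param coords n x d matrix (e.g. a t-SNE embedding).
#' @param k_range candidate cluster counts.
#' @param restarts k-means restarts per k.
#' @param seed RNG seed.
#' @return data.frame of class `clustering_report`: k, mean_silhouette,
#'   se_silhouette, with per-k assignments in `attr(, "assignments")`.
#' @export
kmeans_silhouette <- function(coords, k_range = 2:12, restarts = 20, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= max(k_range)) stop("need more points than max(k_range)")
  D <- stats::dist(coords)
  withr_seed(seed, {
    assignments <- list()
    rows <- lapply(k_range, function(k) {
      best <- NULL
      for (r in seq_len(restarts)) {
        centers <- kmeanspp_init(coords, k)
        km <- suppressWarnings(stats::kmeans(coords, centers, iter.max = 300))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      sil <- silhouette_values(best$cluster, D)
      assignments[[as.character(k)]] <<- best$cluster
      data.frame(k = k, mean_silhouette = mean(sil),
                 se_silhouette = stats::sd(sil) / sqrt(n))
    })
    out <- do.call(rbind, rows)
    attr(out, "assignments") <- assignments
    class(out) <- c("clustering_report", class(out))
    out
  })
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  # nudge exact duplicates so stats::kmeans accepts the centers
  dup <- duplicated(round(centers, 12))
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] +
    matrix(stats::rnorm(sum(dup) * ncol(x), sd = 1e-8), sum(dup))
  centers
}

# per-point silhouette widths; 0 for degenerate geometry
silhouette_values <- function(assign, D) {
  if (length(unique(assign)) < 2) return(rep(0, length(assign)))
  if (max(D) == 0) return(rep(0, length(assign)))
  s <- cluster::silhouette(assign, D)
  v <- s[, "sil_width"]
  v[!is.finite(v)] <- 0
  v
}

#' Subtype-clustering pipeline
#'
#' Embeds the top-`n_top` features (by mean |SHAP|) with t-SNE and reports
#' silhouettes over a k range, optionally restricted to patients. Labels
#' are only used to subset the cohort, never passed to the embedding or
#' clustering.
#'
#' @param ft a [feature_table()].
#' @param shap a `shap_result` providing the feature ranking (NULL: use
#'   all columns).
#' @param patients_only restrict to rows labelled `"patient"`.
#' @param n_top features kept. @param dims,perplexity,iterations,seed
#'   forwarded to [tsne_embed()]; perplexity is capped below n.
#' @param k_range forwarded to [kmeans_silhouette()].
#' @return list: `embedding`, `report`, `features_used`.
#' @export
subtype_clustering <- function(ft, shap = NULL, patients_only = TRUE, n_top = 10,
                               dims = 3, perplexity = 25, iterations = 2500,
                               seed = 1L, k_range = 2:12) {
  feats <- if (is.null(shap)) colnames(ft$values) else shap$rank[seq_len(n_top)]
  rows <- if (patients_only) ft$labels == "patient" else rep(TRUE, length(ft$labels))
  x <- ft$values[rows, feats, drop = FALSE]
  perp <- min(perplexity, (nrow(x) - 1) / 3)
  emb <- suppressWarnings(tsne_embed(x, dims, perp, iterations, seed))
  rep_df <- kmeans_silhouette(emb$coords, k_range[k_range < nrow(x)], seed = seed)
  list(embedding = emb, report = rep_df, features_used = feats)
}
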