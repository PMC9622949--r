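# Shared fixtures: tiny networks and cheap simulation settings.

toy_network <- function() {
  network_spec(c("A", "B"), data.frame(from = "A", to = "B"), input_site = "A")
}

single_source_network <- function() {
  network_spec("A", data.frame(from = character(), to = character()),
               input_site = "A")
}

quick_cohort <- function(n_control = 6, n_patient = 4, seed = 1, ...) {
  net <- chain_network()
  generate_cohort(cohort_config(n_control = n_control, n_patient = n_patient,
                                seed = seed, ...),
                  net, default_constants(net), bench_gain(net))
}

# brute-force silhouette widths from the definition
brute_silhouette <- function(assign, X) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- assign == assign[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(assign), assign[i]), function(cl)
      mean(D[i, assign == cl]), 0))
    if (sum(own) > 1) (b - a) / max(a, b) else 0
  }, 0)
}

# exact log evidence of y = X theta + noise, theta ~ N(0, diag(pv)),
# noise precision tau, via the marginal Gaussian density
exact_log_evidence <- function(y, X, pv, tau) {
  S <- X %*% diag(pv, length(pv)) %*% t(X) + diag(1 / tau, length(y))
  ch <- chol(S)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}
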