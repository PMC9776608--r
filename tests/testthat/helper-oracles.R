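# Independent oracles used across the suite. Deliberately naive: plain loops
# and closed forms, sharing no code with the package internals they check.

# Brute-force running-sum enrichment score: walk the list one gene at a time.
oracle_es <- function(genes, scores, members, weight = 1) {
  N <- length(genes)
  hit <- genes %in% members
  K <- sum(hit)
  w <- abs(scores)^weight
  W <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (W > 0) w[i] / W else 1 / K
    } else {
      -1 / (N - K)
    }
    run[i] <- cur
  }
  # same tie convention as the package: positive excursion wins a tie
  if (max(run) >= -min(run) - 1e-10) max(run) else min(run)
}

# Closed-form solution of a decoupled node dx/dt = J - d x.
decoupled_closed_form <- function(t, J, d, x0) J / d + (x0 - J / d) * exp(-d * t)

# Random stable model: Gershgorin discs of A - diag(d) all in the left half
# plane because each decay rate exceeds its row's interaction mass.
random_stable_model <- function(n = 4) {
  A <- matrix(stats::rnorm(n * n, 0, 0.3), n)
  diag(A) <- 0
  d <- rowSums(abs(A)) + stats::runif(n, 0.5, 1.5)
  network_model(paste0("n", seq_len(n)), J = stats::runif(n, 0.5, 2),
                d = d, A = A)
}

# Random stable model whose fixed point is strictly positive (resampled).
random_feasible_model <- function(n = 4) {
  repeat {
    m <- random_stable_model(n)
    fp <- fixed_point(m)
    if (fp$feasible) return(m)
  }
}
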