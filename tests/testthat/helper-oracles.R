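# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Marginal Gaussian log-likelihood evaluated per subject from the fitted
# parameters: sum_i log N(y_i; X_i beta, Z_i Psi Z_i' + sigma_e^2 I).
mvn_loglik_oracle <- function(fit, design, y) {
  Psi <- fit$Psi
  q <- nrow(Psi)
  ll <- 0
  for (i in seq_len(design$n_subjects)) {
    ix <- (design$starts0[i] + 1):(design$ends0[i] + 1)
    Xi <- design$X[ix, , drop = FALSE]
    Zi <- design$Z[ix, seq_len(q), drop = FALSE]
    Sig <- Zi %*% Psi %*% t(Zi) + diag(fit$sigma2, length(ix))
    r <- y[ix] - drop(Xi %*% fit$beta)
    ch <- chol(Sig)
    ll <- ll - 0.5 * (length(ix) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  ll
}

# Two-sided Fisher exact p by direct enumeration with binomial coefficients
# (no dhyper, no package code).
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || b + d == 0) return(1)
  x <- max(0, n1 - m2):min(n1, m1)
  lp <- lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  probs <- exp(lp)
  p_obs <- probs[x == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Hypergeometric upper-tail by exhaustive enumeration of all n-subsets of a
# universe of size N (feasible for N <= 12).
ora_p_oracle <- function(N, K, n, k) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(matrix(subsets %in% hits, nrow = n))
  mean(overlaps >= k)
}

# Connected components by union-find over a similarity matrix with a strict
# threshold; returns the number of components.
components_oracle <- function(sim, threshold) {
  n <- nrow(sim)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sim[i, j] > threshold) {
        parent[find(i)] <- find(j)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Small longitudinal sheet with standard covariates for direct LMM tests.
make_sheet <- function(n_subjects, waves = c(0, 2.5, 5), seed = 1) {
  set.seed(seed)
  nw <- length(waves)
  base <- runif(n_subjects, 70, 81)
  ids <- sprintf("s%04d", seq_len(n_subjects))
  data.frame(
    sample_id = paste0(rep(ids, each = nw), "_w", rep(seq_len(nw), n_subjects)),
    subject_id = rep(ids, each = nw),
    age = rep(base, each = nw) + rep(waves, n_subjects),
    sex = rep(rbinom(n_subjects, 1, 0.6), each = nw),
    stringsAsFactors = FALSE
  )
}
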