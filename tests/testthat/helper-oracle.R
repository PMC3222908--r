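# Independent brute-force oracle for the latent class likelihood:
# per-record summation over latent assignments with scalar loops, no
# shared code with the estimator.
oracle_loglik <- function(pi, rho, Y, w = rep(1, nrow(Y))) {
  ll <- 0
  for (i in seq_len(nrow(Y))) {
    tot <- 0
    for (c in seq_along(pi)) {
      p <- pi[c]
      for (j in seq_len(ncol(Y))) {
        y <- Y[i, j]
        if (!is.na(y)) p <- p * (if (y == 1) rho[c, j] else 1 - rho[c, j])
      }
      tot <- tot + p
    }
    ll <- ll + w[i] * log(tot)
  }
  ll
}

# Draw an n x J binary matrix from a product-Bernoulli mixture; returns
# values and the true class labels.
sim_mixture <- function(n, pi, rho, seed) {
  withr::with_seed(seed, {
    cls <- sample.int(length(pi), n, replace = TRUE, prob = pi)
    Y <- matrix(rbinom(n * ncol(rho), 1, as.vector(rho[cls, ])),
                nrow = n, ncol = ncol(rho))
    list(Y = Y, class = cls)
  })
}

# Match estimated classes to true classes by the permutation minimizing
# total absolute rho difference; returns the permutation to apply to the
# estimate.
match_classes <- function(rho_est, rho_true) {
  K <- nrow(rho_true)
  perms <- gtools_permutations(K)
  costs <- apply(perms, 1, function(p) sum(abs(rho_est[p, , drop = FALSE] - rho_true)))
  perms[which.min(costs), ]
}

gtools_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(K - 1)
  out <- NULL
  for (k in seq_len(K)) {
    rest <- setdiff(seq_len(K), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), K - 1)))
  }
  unname(out)
}

# Small population spec for fast end-to-end tests.
tiny_spec <- function(n = 400, seed = 42, ...) {
  population_spec(n_respondents = n, seed = seed, ...)
}
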