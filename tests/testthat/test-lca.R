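test_that("log-likelihood matches closed forms", {
  m <- lca_model(pi = 1, rho = matrix(0.5, 1, 1, dimnames = list(NULL, "a")))
  Y <- matrix(c(0L, 1L), 2, 1, dimnames = list(NULL, "a"))
  expect_equal(lca_loglik(m, Y), 2 * log(0.5), tolerance = 1e-12)

  # a fully missing record contributes w * log(sum pi) = 0
  m2 <- lca_model(pi = c(0.3, 0.7), rho = matrix(c(0.2, 0.8), 2, 1))
  Yna <- matrix(NA_integer_, 1, 1)
  expect_equal(lca_loglik(m2, Yna, weights = 5), 0, tolerance = 1e-12)
})

test_that("log-likelihood equals brute-force summation over latent assignments", {
  for (s in 1:12) {
    withr::with_seed(s, {
      J <- sample(1:4, 1)
      K <- sample(1:2, 1)
      n <- sample(3:10, 1)
      pi <- as.numeric(stats::rgamma(K, 2))
      pi <- pi / sum(pi)
      rho <- matrix(runif(K * J, 0.05, 0.95), K, J)
      Y <- matrix(sample(c(0L, 1L, NA), n * J, TRUE, c(0.4, 0.4, 0.2)), n, J)
      w <- runif(n, 0.2, 3)
    })
    m <- lca_model(pi, rho)
    expect_equal(lca_loglik(m, Y, w), oracle_loglik(pi, rho, Y, w),
                 tolerance = 1e-10)
  }
})

test_that("single-class fit has the closed-form weighted-mean solution", {
  sim <- sim_mixture(200, c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.3, 0.6)), seed = 2)
  w <- withr::with_seed(3, runif(200, 0.5, 2))
  Y <- sim$Y
  Y[1, 1] <- NA
  fit <- lca_fit(Y, w, k = 1, n_starts = 1, seed = 1)
  expect_equal(fit$model$pi, 1)
  wn <- w / mean(w)
  for (j in 1:2) {
    obs <- !is.na(Y[, j])
    expect_equal(unname(fit$model$rho[1, j]),
                 sum(wn[obs] * Y[obs, j]) / sum(wn[obs]), tolerance = 1e-8)
  }
  expect_equal(fit$n_params, 2)
  expect_equal(fit$bic, -2 * fit$loglik + 2 * log(200), tolerance = 1e-10)
})

test_that("EM log-likelihood ascends monotonically and the fit is reproducible", {
  sim <- sim_mixture(400, c(0.4, 0.6), rbind(c(0.8, 0.7, 0.2), c(0.2, 0.3, 0.7)),
                     seed = 5)
  f1 <- lca_fit(sim$Y, k = 2, n_starts = 5, seed = 7)
  f2 <- lca_fit(sim$Y, k = 2, n_starts = 5, seed = 7)
  expect_identical(f1$model, f2$model)
  expect_true(all(diff(f1$loglik_trace) >= -1e-9))
  expect_true(f1$converged)
})

test_that("fit is invariant to rescaling weights by a positive constant", {
  sim <- sim_mixture(300, c(0.5, 0.5), rbind(c(0.8, 0.2, 0.7), c(0.2, 0.7, 0.1)),
                     seed = 11)
  w <- withr::with_seed(12, runif(300, 0.5, 4))
  f1 <- lca_fit(sim$Y, w, k = 2, n_starts = 5, seed = 3)
  f2 <- lca_fit(sim$Y, 17.3 * w, k = 2, n_starts = 5, seed = 3)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f1$bic, f2$bic, tolerance = 1e-8)
  expect_equal(f1$model$rho, f2$model$rho, tolerance = 1e-9)
})

test_that("relabeling classes leaves the likelihood and BIC unchanged", {
  sim <- sim_mixture(200, c(0.3, 0.7), rbind(c(0.9, 0.1, 0.8), c(0.2, 0.6, 0.3)),
                     seed = 21)
  m <- lca_model(c(0.3, 0.7), rbind(c(0.9, 0.1, 0.8), c(0.2, 0.6, 0.3)))
  mp <- lca_model(m$pi[2:1], m$rho[2:1, ], m$item_names)
  expect_equal(lca_loglik(m, sim$Y), lca_loglik(mp, sim$Y), tolerance = 1e-10)
})

test_that("parameters of a well-separated 3-class model are recovered", {
  ds <- separated_domain_spec(J = 6)
  sim <- sim_mixture(5000, ds$pi, ds$rho, seed = 31)
  fit <- lca_fit(sim$Y, k = 3, n_starts = 10, seed = 31)
  perm <- match_classes(fit$model$rho, ds$rho)
  expect_lt(max(abs(fit$model$pi[perm] - ds$pi)), 0.03)
  expect_lt(max(abs(fit$model$rho[perm, ] - ds$rho)), 0.05)
})

test_that("posterior rows are proper probabilities with prior fallback and low-index tie-break", {
  m <- lca_model(c(0.25, 0.75), rbind(c(0.9, 0.8), c(0.1, 0.2)))
  post <- lca_posterior(m, matrix(NA_integer_, 1, 2))
  expect_equal(as.numeric(post$values), c(0.25, 0.75), tolerance = 1e-12)

  # symmetric two-class model, record equidistant from both classes
  msym <- lca_model(c(0.5, 0.5), rbind(c(0.8, 0.2), c(0.2, 0.8)))
  post2 <- lca_posterior(msym, matrix(c(1L, 1L), 1, 2))
  expect_equal(as.numeric(post2$values), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(post2$modal, 1L)

  sim <- sim_mixture(300, c(0.4, 0.6), rbind(c(0.8, 0.2, 0.6), c(0.3, 0.7, 0.2)),
                     seed = 6)
  sim$Y[sample(length(sim$Y), 100)] <- NA
  p <- lca_posterior(lca_model(c(0.4, 0.6),
                               rbind(c(0.8, 0.2, 0.6), c(0.3, 0.7, 0.2))),
                     sim$Y)
  expect_equal(rowSums(p$values), rep(1, 300), tolerance = 1e-8)
})

test_that("classes are ordered by mean endorsement with prevalence tie-break", {
  m <- lca_model(c(0.2, 0.8), rbind(c(0.8, 0.8), c(0.1, 0.1)))
  expect_identical(order_classes(m), m)  # already ordered

  tie <- lca_model(c(0.2, 0.8), rbind(c(0.6, 0.4), c(0.4, 0.6)))
  ord <- order_classes(tie)
  expect_equal(ord$pi, c(0.8, 0.2))     # equal risk scores: larger pi first

  withr::with_seed(14, {
    K <- 4
    pi <- as.numeric(stats::rgamma(K, 2)); pi <- pi / sum(pi)
    rho <- matrix(runif(K * 5), K, 5)
  })
  ord <- order_classes(lca_model(pi, rho))
  expect_equal(rowMeans(ord$rho), sort(rowMeans(rho), decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("BIC selection finds the true class count and handles edge cases", {
  ds <- separated_domain_spec(J = 5)
  sim <- sim_mixture(1500, ds$pi, ds$rho, seed = 41)
  sel <- lca_select(sim$Y, k_max = 4, n_starts = 8, seed = 41)
  expect_equal(sel$chosen_k, 3L)
  expect_equal(nrow(sel$bic_table), 4L)
  expect_equal(sel$bic_table$bic,
               -2 * sel$bic_table$loglik + sel$bic_table$n_params * log(1500),
               tolerance = 1e-8)

  sel1 <- lca_select(sim$Y, k_max = 1, n_starts = 2, seed = 1)
  expect_equal(sel1$chosen_k, 1L)
})

test_that("one-class data leads BIC to one class across seeded replicates", {
  hits <- 0L
  for (r in 1:20) {
    sim <- sim_mixture(600, 1, matrix(c(0.3, 0.6, 0.2, 0.5), 1, 4),
                       seed = 500 + r)
    sel <- lca_select(sim$Y, k_max = 3, n_starts = 4, seed = 500 + r)
    hits <- hits + (sel$chosen_k == 1L)
  }
  expect_gte(hits, 19L)
})

test_that("degenerate and contract errors are reported", {
  Y <- matrix(rep(c(0L, 1L), 5), 10, 1)
  expect_warning(lca_fit(Y, k = 3, n_starts = 2, seed = 1),
                 regexp = "distinct observed patterns")
  expect_error(lca_fit(Y, weights = rep(-1, 10), k = 1, seed = 1),
               class = "riskclass_contract_error")
  m <- lca_model(c(0.5, 0.5), matrix(0.5, 2, 3))
  expect_error(lca_loglik(m, matrix(0L, 2, 2)),
               class = "riskclass_contract_error")
})

test_that("tidiers expose profiles and fit summaries", {
  sim <- sim_mixture(300, c(0.4, 0.6), rbind(c(0.8, 0.2), c(0.2, 0.8)), seed = 8)
  colnames(sim$Y) <- c("a", "b")
  fit <- lca_fit(sim$Y, k = 2, n_starts = 4, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4L)
  expect_setequal(as.character(td$item), c("a", "b"))
  expect_equal(td$rho[td$class == 1 & td$item == "a"],
               unname(fit$model$rho[1, "a"]))
  g <- glance(fit)
  expect_equal(g$bic, fit$bic)
  sel <- lca_select(sim$Y, k_max = 2, n_starts = 3, seed = 2)
  expect_equal(nrow(tidy(sel)), 2L)
})
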