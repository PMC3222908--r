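#' Latent class model for binary indicators
#'
#' A K-class model for J binary items: class prevalences `pi` (a simplex)
#' and class-conditional endorsement probabilities `rho` (K x J). Items are
#' conditionally independent given class, so the likelihood of a response
#' pattern is a mixture of products of Bernoulli terms. Missing and
#' structurally missing cells are simply dropped from the product (missing
#' at random).
#'
#' @param pi length-K simplex of class prevalences.
#' @param rho K x J matrix of endorsement probabilities in (0, 1).
#' @param item_names ordered item names (defaults to `rho` column names).
#' @return An `lca_model` object.
#' @export
lca_model <- function(pi, rho, item_names = colnames(rho)) {
  rho <- as.matrix(rho)
  if (abs(sum(pi) - 1) > 1e-10 || any(pi < 0)) {
    abort("`pi` must be a simplex summing to 1.", class = "riskclass_contract_error")
  }
  if (nrow(rho) != length(pi)) {
    abort("`rho` must have one row per class.", class = "riskclass_contract_error")
  }
  if (is.null(item_names)) item_names <- paste0("item_", seq_len(ncol(rho)))
  colnames(rho) <- item_names
  structure(
    list(K = length(pi), pi = as.numeric(pi), rho = rho,
         item_names = item_names),
    class = "lca_model"
  )
}

RHO_CLAMP <- 1e-6

clamp_rho <- function(rho) pmin(pmax(rho, RHO_CLAMP), 1 - RHO_CLAMP)

ind_values <- function(data) {
  if (inherits(data, "indicator_matrix")) data$values else {
    m <- as.matrix(data)
    storage.mode(m) <- "integer"
    m
  }
}

# per-record log component densities: n x K matrix of
# log pi_c + sum_{j observed} [y log rho + (1-y) log(1-rho)]
log_components <- function(model, Y) {
  O <- !is.na(Y)
  Y0 <- Y
  Y0[!O] <- 0L
  storage.mode(Y0) <- "double"
  storage.mode(O) <- "double"
  lrho <- log(clamp_rho(model$rho))
  l1m <- log(1 - clamp_rho(model$rho))
  sweep(Y0 %*% t(lrho) + (O - Y0) %*% t(l1m), 2, log(model$pi), `+`)
}

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Weighted log-likelihood of a latent class model
#'
#' Computes `sum_i w_i log sum_c pi_c prod_{j in obs(i)}
#' rho_cj^y_ij (1 - rho_cj)^(1 - y_ij)`, where `obs(i)` runs over the
#' non-missing cells of record i. A record with no observed items
#' contributes `w_i log(1) = 0`.
#'
#' @param model an `lca_model`.
#' @param data an `indicator_matrix` or binary matrix (`NA` = missing).
#' @param weights positive weights, length n (default all 1).
#' @return The weighted log-likelihood (a scalar).
#' @export
lca_loglik <- function(model, data, weights = NULL) {
  Y <- ind_values(data)
  check_items_match(model, data)
  if (is.null(weights)) weights <- rep(1, nrow(Y))
  if (length(weights) != nrow(Y)) {
    abort("`weights` must have one entry per record.",
          class = "riskclass_contract_error")
  }
  sum(weights * row_log_sum_exp(log_components(model, Y)))
}

check_items_match <- function(model, data) {
  Y <- ind_values(data)
  if (ncol(Y) != ncol(model$rho)) {
    abort("Item count of data does not match the model.",
          class = "riskclass_contract_error")
  }
  nm <- if (inherits(data, "indicator_matrix")) data$item_names else colnames(Y)
  if (!is.null(nm) && !is.null(model$item_names) &&
      !identical(unname(nm), unname(model$item_names))) {
    abort("Item names of data do not match the model.",
          class = "riskclass_contract_error")
  }
  invisible(TRUE)
}

# Collapse records to distinct response patterns (missingness pattern
# included); the likelihood only depends on patterns and their summed
# weights, which makes EM cost independent of n.
collapse_patterns <- function(Y, weights) {
  key <- do.call(paste, c(as.data.frame(Y), sep = "\r"))
  idx <- match(key, unique(key))
  P <- max(idx)
  wp <- as.numeric(rowsum(weights, idx)[, 1])
  list(Y = Y[match(seq_len(P), idx), , drop = FALSE], w = wp, n_patterns = P)
}

#' Fit a weighted latent class model by EM
#'
#' Runs `n_starts` EM runs from random initializations (class prevalences
#' uniform, endorsement probabilities Uniform(0.2, 0.8)) and keeps the run
#' with the highest final weighted log-likelihood. The E-step computes
#' posterior class memberships over observed cells only; the M-step updates
#' prevalences and endorsement probabilities by weighted posterior averages,
#' clamping the latter to `[1e-6, 1 - 1e-6]`. Iteration stops when the
#' relative log-likelihood change falls below `tol`. Weights are normalized
#' to mean 1 before fitting, and the BIC penalty uses the unweighted record
#' count, so the fit is invariant to rescaling all weights. Classes in the
#' returned model are ordered by descending risk (mean endorsement
#' probability), class 1 = highest risk.
#'
#' Estimation works on distinct response patterns rather than raw records:
#' the likelihood depends only on each pattern and its total weight.
#'
#' @param data an `indicator_matrix` or binary matrix (`NA` = missing cell).
#' @param weights positive design weights (default all 1).
#' @param k number of latent classes (>= 1).
#' @param n_starts number of random EM starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param seed master seed; per-start seeds are derived from it.
#' @return An `lca_fit` object: `model` (risk-ordered `lca_model`),
#'   `loglik`, `n_params`, `bic`, `n_basis`, `converged`, `iterations`,
#'   `loglik_trace` (best start), `n_starts`, `best_start_seed`,
#'   `n_patterns`, and a `degenerate` flag when `k` exceeds the number of
#'   distinct observed patterns.
#' @examples
#' svy <- simulate_survey(population_spec(n_respondents = 300, seed = 3))
#' ind <- derive_indicators(svy)
#' fit <- lca_fit(ind$risky_behavior, svy$respondents$design_weight,
#'                k = 2, n_starts = 4, seed = 1)
#' glance(fit)
#' @export
lca_fit <- function(data, weights = NULL, k, n_starts = 20, tol = 1e-6,
                    max_iter = 1000, seed = 1L) {
  Y <- ind_values(data)
  n <- nrow(Y)
  J <- ncol(Y)
  if (k < 1) abort("`k` must be >= 1.", class = "riskclass_contract_error")
  if (n < k) abort("Need at least as many records as classes.",
                   class = "riskclass_contract_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("`weights` must be positive and finite.",
          class = "riskclass_contract_error")
  }
  w <- weights / mean(weights)
  cp <- collapse_patterns(Y, w)
  item_names <- colnames(Y) %||% paste0("item_", seq_len(J))
  degenerate <- k > cp$n_patterns
  if (degenerate) {
    warn(paste0("k = ", k, " exceeds the ", cp$n_patterns,
                " distinct observed patterns; fit is degenerate."))
  }

  start_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_starts))
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- withr::with_seed(start_seeds[s], {
      list(pi = rep(1 / k, k),
           rho = matrix(runif(k * J, 0.2, 0.8), k, J))
    })
    run <- em_run(cp$Y, cp$w, init$pi, init$rho, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) {
      best <- run
      best$seed <- start_seeds[s]
    }
  }

  model <- lca_model(best$pi, best$rho, item_names)
  model <- order_classes(model)
  n_params <- (k - 1) + k * J
  structure(
    list(
      model = model,
      loglik = best$loglik,
      n_params = n_params,
      bic = -2 * best$loglik + n_params * log(n),
      n_basis = n,
      converged = best$converged,
      iterations = best$iterations,
      loglik_trace = best$trace,
      n_starts = n_starts,
      best_start_seed = best$seed,
      n_patterns = cp$n_patterns,
      degenerate = degenerate,
      domain = if (inherits(data, "indicator_matrix")) data$domain else NA_character_
    ),
    class = "lca_fit"
  )
}

em_run <- function(Y, w, pi, rho, tol, max_iter) {
  O <- !is.na(Y)
  Y0 <- Y
  Y0[!O] <- 0L
  storage.mode(Y0) <- "double"
  storage.mode(O) <- "double"
  sw <- sum(w)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lrho <- log(rho)
    l1m <- log1p(-rho)
    lc <- sweep(Y0 %*% t(lrho) + (O - Y0) %*% t(l1m), 2, log(pi), `+`)
    ll_i <- row_log_sum_exp(lc)
    ll <- sum(w * ll_i)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    tau <- exp(lc - ll_i)           # n x K posteriors
    wt <- tau * w
    pi <- colSums(wt) / sw
    pi <- pmax(pi, 1e-12)
    pi <- pi / sum(pi)
    num <- t(wt) %*% Y0
    den <- t(wt) %*% O
    rho <- ifelse(den > 0, num / den, 0.5)
    rho <- clamp_rho(rho)
  }
  list(pi = pi, rho = rho, loglik = ll, converged = converged,
       iterations = iter, trace = trace)
}

#' Fit 1..K_max classes and select by BIC
#'
#' Sequentially fits latent class models with 1 up to `k_max` classes and
#' chooses the class count minimizing the Bayesian information criterion
#' `BIC = -2 loglik + n_params log(n)`.
#'
#' @inheritParams lca_fit
#' @param k_max largest class count to try.
#' @return An `lca_selection` object: `fits` (list of `lca_fit`),
#'   `chosen_k`, `bic_table` (tibble), `domain`.
#' @export
lca_select <- function(data, weights = NULL, k_max = 4, n_starts = 20,
                       tol = 1e-6, max_iter = 1000, seed = 1L) {
  if (k_max < 1) abort("`k_max` must be >= 1.", class = "riskclass_contract_error")
  fits <- lapply(seq_len(k_max), function(k) {
    lca_fit(data, weights, k = k, n_starts = n_starts, tol = tol,
            max_iter = max_iter, seed = derive_seed(seed, 31L * k))
  })
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  chosen <- which.min(bics)
  tbl <- tibble(
    n_classes = seq_len(k_max),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    n_params = vapply(fits, function(f) f$n_params, numeric(1)),
    bic = bics,
    chosen = seq_len(k_max) == chosen
  )
  structure(
    list(fits = fits, chosen_k = chosen, bic_table = tbl,
         domain = fits[[1]]$domain),
    class = "lca_selection"
  )
}

#' Posterior class membership probabilities
#'
#' Bayes-rule posteriors for each record given a fitted model, using
#' observed cells only; a record with no observed items gets the prior
#' prevalences. Modal assignment breaks ties toward the lowest class index
#' (i.e. the higher-risk class after ordering).
#'
#' @param fit an `lca_fit` or `lca_model`.
#' @param data an `indicator_matrix` or binary matrix.
#' @return An `lca_posterior`: `values` (n x K matrix, rows sum to 1) and
#'   `modal` (integer class labels).
#' @export
lca_posterior <- function(fit, data) {
  model <- if (inherits(fit, "lca_fit")) fit$model else fit
  check_items_match(model, data)
  Y <- ind_values(data)
  lc <- log_components(model, Y)
  ll_i <- row_log_sum_exp(lc)
  values <- exp(lc - ll_i)
  colnames(values) <- paste0("class_", seq_len(model$K))
  structure(
    list(values = values, modal = max.col(values, ties.method = "first")),
    class = "lca_posterior"
  )
}

#' @export
print.lca_posterior <- function(x, ...) {
  cat("<lca_posterior>", nrow(x$values), "records x", ncol(x$values),
      "classes; modal distribution:\n")
  print(table(x$modal))
  invisible(x)
}

#' @method as_tibble lca_posterior
#' @export
as_tibble.lca_posterior <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$values))
  out$modal <- x$modal
  out
}

#' Order classes by descending risk
#'
#' Permutes the classes of a model so that the risk score (the mean
#' endorsement probability across items) is non-increasing; class 1 is the
#' highest-risk class. Ties are broken by larger prevalence first. Because
#' all 24 indicators are coded with 1 = adverse state, this ordering
#' reproduces the low/intermediate/high-risk reading of the classes.
#'
#' @param model an `lca_model`.
#' @return The model with permuted `pi` and `rho` (likelihood unchanged).
#' @export
order_classes <- function(model) {
  s <- rowMeans(model$rho)
  perm <- order(-s, -model$pi)
  lca_model(model$pi[perm], model$rho[perm, , drop = FALSE],
            model$item_names)
}

#' @export
print.lca_model <- function(x, ...) {
  cat("<lca_model>", x$K, "classes x", length(x$item_names), "items\n")
  cat("  pi:", paste(format(x$pi, digits = 3), collapse = ", "), "\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("<lca_fit>", if (!is.na(x$domain)) x$domain else "", x$model$K,
      "classes,", length(x$model$item_names), "items\n")
  cat(sprintf("  loglik = %.2f  BIC = %.2f  (n = %d, %d params)\n",
              x$loglik, x$bic, x$n_basis, x$n_params))
  cat(sprintf("  converged: %s after %d iterations (%d starts, %d patterns)\n",
              x$converged, x$iterations, x$n_starts, x$n_patterns))
  cat("  pi:", paste(format(x$model$pi, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lca_selection <- function(x, ...) {
  cat("<lca_selection>", if (!is.na(x$domain)) x$domain else "",
      "chosen k =", x$chosen_k, "\n")
  print(x$bic_table)
  invisible(x)
}

#' Tidiers for latent class fits
#'
#' `tidy()` returns the class-conditional endorsement probabilities in long
#' form (one row per class x item) plus the class prevalences; `glance()`
#' returns a one-row model summary. For an `lca_selection`, `tidy()` returns
#' the BIC table.
#'
#' @param x an `lca_fit` or `lca_selection`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy lca_fit
#' @export
tidy.lca_fit <- function(x, ...) {
  m <- x$model
  tidyr::expand_grid(class = seq_len(m$K), item = m$item_names) %>%
    mutate(item = factor(.data$item, levels = m$item_names),
           rho = as.vector(t(m$rho)),
           pi = m$pi[.data$class])
}

#' @rdname tidy.lca_fit
#' @method glance lca_fit
#' @export
glance.lca_fit <- function(x, ...) {
  tibble(n_classes = x$model$K, loglik = x$loglik, n_params = x$n_params,
         bic = x$bic, n_basis = x$n_basis, converged = x$converged,
         iterations = x$iterations, n_patterns = x$n_patterns)
}

#' @rdname tidy.lca_fit
#' @method tidy lca_selection
#' @export
tidy.lca_selection <- function(x, ...) x$bic_table

#' @rdname tidy.lca_fit
#' @method glance lca_selection
#' @export
glance.lca_selection <- function(x, ...) {
  glance(x$fits[[x$chosen_k]])
}
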