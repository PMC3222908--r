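#' Convert risk-ordered class assignments to a factor
#'
#' Modal class labels from [lca_posterior()] are risk-descending integers
#' (1 = highest risk). For regression the classes enter as a categorical
#' covariate whose reference level is the *lowest*-risk class, so odds
#' ratios read "relative to the low-risk class". With three classes the
#' levels are low/intermediate/high; with more, intermediates are numbered.
#'
#' @param modal integer class labels, 1 = highest risk.
#' @param k total number of classes (default `max(modal)`).
#' @return A factor with the low-risk class as the first (reference) level.
#' @examples
#' risk_factor(c(1, 2, 3, 3), k = 3)
#' @export
risk_factor <- function(modal, k = max(modal)) {
  labs <- risk_labels(k)
  factor(labs[modal], levels = rev(labs))
}

risk_labels <- function(k) {
  if (k == 1) return("low")
  if (k == 2) return(c("high", "low"))
  if (k == 3) return(c("high", "intermediate", "low"))
  c("high", paste0("intermediate_", seq_len(k - 2)), "low")
}

#' Weighted logistic regression with robust variance
#'
#' Fits a design-weighted logistic regression by iteratively reweighted
#' least squares (via [stats::glm()] with a quasibinomial family) and pairs
#' the point estimates with a heteroskedasticity-robust sandwich covariance,
#' the with-replacement first-stage approximation commonly used for survey
#' data without full design information. Wald 95% confidence intervals and
#' two-sided p-values are reported on the odds-ratio scale in the
#' `or_table` element.
#'
#' Records with a missing outcome or missing covariates are dropped
#' listwise and counted (`n_dropped`). Factor covariates that are constant
#' in the analysis sample are dropped with a warning. Exact collinearity
#' among the remaining columns is an error naming the aliased columns;
#' quasi-separation is flagged with a warning on the fit.
#'
#' @param data a data frame containing the outcome, predictors and weights.
#' @param formula model formula, e.g. `outcome ~ classes + age_group + sex`.
#' @param weights design weights: a column name (string) or numeric vector.
#'   Defaults to the `design_weight` column when present, else equal
#'   weights.
#' @param cluster optional primary-sampling-unit labels (column name or
#'   vector): score contributions are summed within PSU before the meat of
#'   the sandwich, the usual with-replacement approximation.
#' @param strata optional stratum labels; PSU score totals are centered
#'   within stratum with an `n_h / (n_h - 1)` finite-cluster factor. With
#'   neither argument each respondent is their own PSU in one stratum.
#' @param max_iter,tol IRLS control passed to [stats::glm()].
#' @return A `wlogit` object: `fit` (the glm), `vcov` (robust), `or_table`
#'   tibble, `n_used`, `n_dropped`, `separation` flag.
#' @examples
#' d <- tibble::tibble(y = rbinom(200, 1, 0.3), x = rnorm(200),
#'                     design_weight = runif(200, 0.5, 2))
#' fit <- fit_weighted_logistic(d, y ~ x)
#' tidy(fit)
#' @export
fit_weighted_logistic <- function(data, formula, weights = NULL,
                                  cluster = NULL, strata = NULL,
                                  max_iter = 100, tol = 1e-10) {
  stopifnot(is.data.frame(data))
  w <- resolve_weights(data, weights)
  cluster <- resolve_labels(data, cluster)
  strata <- resolve_labels(data, strata)
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("Weights must be positive and finite.",
          class = "riskclass_contract_error")
  }
  vars <- all.vars(formula)
  missing_row <- !complete.cases(data[intersect(vars, names(data))])
  n_dropped <- sum(missing_row)
  d <- data[!missing_row, , drop = FALSE]
  w <- w[!missing_row] / mean(w[!missing_row])
  d$.w <- w

  # drop constant factor covariates (e.g. a single-class domain)
  rhs <- attr(stats::terms(formula, data = d), "term.labels")
  keep <- vapply(rhs, function(v) {
    if (!v %in% names(d)) return(TRUE)
    x <- d[[v]]
    if (is.factor(x) || is.character(x)) length(unique(x)) > 1 else TRUE
  }, logical(1))
  if (any(!keep)) {
    warn(paste0("Dropping constant predictor(s): ",
                paste(rhs[!keep], collapse = ", ")))
    rhs <- rhs[keep]
    formula <- stats::reformulate(if (length(rhs)) rhs else "1",
                                  response = all.vars(formula)[1])
  }

  mm <- model.matrix(formula, data = d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)),
                                qr_mm$pivot[seq_len(qr_mm$rank)])]
    abort(paste0("Collinear design columns: ", paste(bad, collapse = ", ")),
          class = "riskclass_contract_error")
  }

  fit <- glm(formula, family = quasibinomial(), data = d, weights = .w,
             control = list(maxit = max_iter, epsilon = tol))
  V <- if (is.null(cluster) && is.null(strata)) {
    sandwich::sandwich(fit)
  } else {
    survey_sandwich(fit,
                    cluster = if (is.null(cluster)) seq_len(nrow(d))
                              else cluster[!missing_row],
                    strata = if (is.null(strata)) rep(1L, nrow(d))
                             else strata[!missing_row])
  }

  mu <- stats::fitted(fit)
  separation <- (any(mu > 1 - 1e-8) || any(mu < 1e-8)) &&
    max(abs(coef(fit))) > 10
  if (separation) {
    warn("Possible separation: fitted probabilities at the boundary with large coefficients.")
  }

  est <- coef(fit)
  se <- sqrt(diag(V))
  z <- est / se
  tab <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    or = exp(unname(est)),
    conf.low = exp(unname(est - qnorm(0.975) * se)),
    conf.high = exp(unname(est + qnorm(0.975) * se))
  )

  structure(
    list(fit = fit, vcov = V, or_table = tab, formula = formula,
         n_used = nrow(d), n_dropped = n_dropped, separation = separation),
    class = "wlogit"
  )
}

# Stratified with-replacement linearization: PSU score totals centered
# within stratum, n_h/(n_h - 1) finite-cluster factor.
survey_sandwich <- function(fit, cluster, strata) {
  S <- sandwich::estfun(fit)
  p <- ncol(S)
  M <- matrix(0, p, p)
  for (h in unique(strata)) {
    Sh <- S[strata == h, , drop = FALSE]
    tot <- rowsum(Sh, group = cluster[strata == h])
    nh <- nrow(tot)
    if (nh < 2) next
    ctr <- sweep(tot, 2, colMeans(tot))
    M <- M + nh / (nh - 1) * crossprod(ctr)
  }
  n <- nrow(S)
  B <- sandwich::bread(fit)
  B %*% (M / n) %*% B / n
}

resolve_labels <- function(data, x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1 && x %in% names(data)) {
    return(data[[x]])
  }
  x
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) {
    if ("design_weight" %in% names(data)) return(data$design_weight)
    return(rep(1, nrow(data)))
  }
  if (is.character(weights) && length(weights) == 1) {
    if (!weights %in% names(data)) {
      abort(paste0("Weight column `", weights, "` not found."),
            class = "riskclass_contract_error")
    }
    return(data[[weights]])
  }
  as.numeric(weights)
}

#' @export
print.wlogit <- function(x, ...) {
  cat("<wlogit> weighted logistic fit:",
      deparse(x$formula), "\n")
  cat("  n used:", x$n_used, " dropped (missing):", x$n_dropped, "\n")
  print(x$or_table, n = Inf)
  invisible(x)
}

#' Tidiers for weighted logistic fits
#'
#' `tidy()` follows the broom convention: coefficient-scale estimates with
#' robust standard errors, or odds ratios with `exponentiate = TRUE`.
#' `glance()` gives a one-row fit summary.
#'
#' @param x a `wlogit`.
#' @param exponentiate report odds ratios and OR-scale confidence bounds.
#' @param ... unused.
#' @return A tibble.
#' @method tidy wlogit
#' @export
tidy.wlogit <- function(x, exponentiate = FALSE, ...) {
  tab <- x$or_table
  if (exponentiate) {
    tab %>% select("term", estimate = "or", "std.error", "statistic",
                   "p.value", "conf.low", "conf.high")
  } else {
    tab %>%
      mutate(conf.low = log(.data$conf.low),
             conf.high = log(.data$conf.high)) %>%
      select("term", "estimate", "std.error", "statistic", "p.value",
             "conf.low", "conf.high")
  }
}

#' @rdname tidy.wlogit
#' @method glance wlogit
#' @export
glance.wlogit <- function(x, ...) {
  tibble(n_used = x$n_used, n_dropped = x$n_dropped,
         separation = x$separation,
         df = length(coef(x$fit)),
         deviance = as.numeric(stats::deviance(x$fit)))
}

#' Odds-ratio report for class variables across outcomes
#'
#' Assembles a report table in the layout of a by-domain odds-ratio table:
#' one row per class level per domain, with the low-risk reference level
#' marked `1 [Reference]`, and OR (95% CI) and p-value columns for each
#' fitted outcome.
#'
#' @param fits named list of `wlogit` fits (e.g. physical and mental
#'   distress), sharing predictor coding.
#' @param class_vars character vector of the class-factor column names in
#'   the model (default the four domain names).
#' @return A tibble with columns `domain`, `level`, and per-outcome
#'   `or_ci_<name>` and `p_<name>` columns.
#' @export
build_or_table <- function(fits, class_vars = domain_names()) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  rows <- list()
  f1 <- fits[[1]]$fit
  xl <- f1$xlevels
  for (v in class_vars) {
    lv <- xl[[v]]
    if (is.null(lv)) next
    for (l in lv) {
      term <- paste0(v, l)
      is_ref <- l == lv[1]
      row <- tibble(domain = v, level = l)
      for (nm in names(fits)) {
        tab <- fits[[nm]]$or_table
        if (is_ref) {
          row[[paste0("or_ci_", nm)]] <- "1 [Reference]"
          row[[paste0("p_", nm)]] <- NA_real_
        } else {
          hit <- tab[tab$term == term, ]
          if (nrow(hit) != 1) {
            abort(paste0("Term `", term, "` not found in fit `", nm, "`."),
                  class = "riskclass_contract_error")
          }
          row[[paste0("or_ci_", nm)]] <-
            sprintf("%.2f (%.2f-%.2f)", hit$or, hit$conf.low, hit$conf.high)
          row[[paste0("p_", nm)]] <- hit$p.value
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  bind_rows(rows)
}

#' Weighted prevalence of outcomes by demographic level
#'
#' For each level of each demographic characteristic, reports the
#' unweighted respondent count, the weighted share of the sample, and the
#' weighted prevalence of each outcome with a normal-approximation 95%
#' confidence interval based on the sandwich variance of the weighted
#' proportion. Records missing the characteristic are excluded from its
#' rows; records missing an outcome are excluded from that outcome's
#' prevalence.
#'
#' @param data respondent tibble.
#' @param outcomes character vector of binary outcome columns.
#' @param demographics character vector of categorical columns.
#' @param weights weight column name or numeric vector (default
#'   `design_weight`).
#' @return A tibble, one row per characteristic level per outcome:
#'   `characteristic`, `level`, `n`, `pct_weighted`, `outcome`,
#'   `prevalence`, `conf.low`, `conf.high` (percent scale).
#' @export
prevalence_table <- function(data, outcomes, demographics = names(demographic_levels()),
                             weights = NULL) {
  w_all <- resolve_weights(data, weights)
  rows <- list()
  for (v in demographics) {
    ok_v <- !is.na(data[[v]])
    x_v <- data[[v]]
    lv <- if (is.factor(x_v)) levels(x_v) else sort(unique(x_v[ok_v]))
    tot_w <- sum(w_all[ok_v])
    for (l in lv) {
      in_lvl <- ok_v & data[[v]] == l
      for (y in outcomes) {
        ok <- in_lvl & !is.na(data[[y]])
        n_lvl <- sum(in_lvl)
        if (sum(ok) == 0) {
          rows[[length(rows) + 1]] <- tibble(
            characteristic = v, level = l, n = n_lvl,
            pct_weighted = 100 * sum(w_all[in_lvl]) / tot_w,
            outcome = y, prevalence = NA_real_,
            conf.low = NA_real_, conf.high = NA_real_)
          next
        }
        wy <- w_all[ok]
        yy <- data[[y]][ok]
        p <- sum(wy * yy) / sum(wy)
        v_p <- sum(wy^2 * (yy - p)^2) / sum(wy)^2
        half <- qnorm(0.975) * sqrt(v_p)
        rows[[length(rows) + 1]] <- tibble(
          characteristic = v, level = l, n = n_lvl,
          pct_weighted = 100 * sum(w_all[in_lvl]) / tot_w,
          outcome = y, prevalence = 100 * p,
          conf.low = 100 * (p - half), conf.high = 100 * (p + half))
      }
    }
  }
  bind_rows(rows)
}
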