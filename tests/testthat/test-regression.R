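test_that("null model intercept equals the logit of the weighted prevalence", {
  withr::with_seed(1, {
    d <- tibble::tibble(y = rbinom(500, 1, 0.3),
                        design_weight = runif(500, 0.5, 3))
  })
  fit <- fit_weighted_logistic(d, y ~ 1)
  p <- weighted.mean(d$y, d$design_weight)
  expect_equal(unname(coef(fit$fit)[1]), qlogis(p), tolerance = 1e-8)
})

test_that("single binary predictor with equal weights reproduces the cross-product ratio", {
  # contingency table: a=30 exposed cases, b=70, c=20, d=180
  d <- tibble::tibble(
    y = rep(c(1, 0, 1, 0), c(30, 70, 20, 180)),
    x = rep(c(1, 1, 0, 0), c(30, 70, 20, 180))
  )
  fit <- fit_weighted_logistic(d, y ~ x)
  expect_equal(fit$or_table$or[fit$or_table$term == "x"],
               (30 * 180) / (70 * 20), tolerance = 1e-8)
})

test_that("equal weights match unweighted maximum likelihood to 1e-6", {
  withr::with_seed(7, {
    d <- tibble::tibble(
      x1 = rnorm(800), x2 = factor(sample(letters[1:3], 800, TRUE)))
    d$y <- rbinom(800, 1, plogis(-1 + 0.8 * d$x1 + 0.5 * (d$x2 == "b")))
  })
  fw <- fit_weighted_logistic(d, y ~ x1 + x2, weights = rep(2.5, 800))
  fu <- glm(y ~ x1 + x2, family = binomial(), data = d)
  expect_equal(coef(fw$fit), coef(fu), tolerance = 1e-6)
})

test_that("the OR table is invariant to rescaling all weights", {
  withr::with_seed(8, {
    d <- tibble::tibble(x = rnorm(400), w = runif(400, 0.5, 2))
    d$y <- rbinom(400, 1, plogis(-0.5 + d$x))
  })
  f1 <- fit_weighted_logistic(d, y ~ x, weights = d$w)
  f2 <- fit_weighted_logistic(d, y ~ x, weights = 42 * d$w)
  expect_equal(f1$or_table, f2$or_table, tolerance = 1e-9)
})

test_that("or table values are exp(coefficients) and tidy respects the broom convention", {
  withr::with_seed(9, {
    d <- tibble::tibble(x = rnorm(300))
    d$y <- rbinom(300, 1, plogis(d$x))
  })
  fit <- fit_weighted_logistic(d, y ~ x)
  expect_equal(fit$or_table$or, exp(fit$or_table$estimate), tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$or_table$estimate)
  to <- tidy(fit, exponentiate = TRUE)
  expect_equal(to$estimate, exp(td$estimate), tolerance = 1e-12)
  expect_true(all(fit$or_table$conf.low <= fit$or_table$conf.high))
})

test_that("constant factors are dropped with a warning and collinearity errors name columns", {
  withr::with_seed(10, {
    d <- tibble::tibble(x = rnorm(200), z = factor("only"),
                        y = rbinom(200, 1, 0.4))
  })
  expect_warning(fit <- fit_weighted_logistic(d, y ~ x + z),
                 regexp = "constant predictor")
  expect_true("x" %in% fit$or_table$term)

  d$x2 <- 2 * d$x
  expect_error(fit_weighted_logistic(d, y ~ x + x2),
               regexp = "x2", class = "riskclass_contract_error")
})

test_that("rows with missing outcome or covariates are dropped and counted", {
  withr::with_seed(11, {
    d <- tibble::tibble(x = rnorm(100), y = rbinom(100, 1, 0.5))
  })
  d$y[1:5] <- NA
  d$x[6:8] <- NA
  fit <- fit_weighted_logistic(d, y ~ x)
  expect_equal(fit$n_dropped, 8L)
  expect_equal(fit$n_used, 92L)
})

test_that("separation is flagged with a warning", {
  d <- tibble::tibble(x = c(rep(0, 30), rep(1, 30)),
                      y = c(rep(0, 30), rep(1, 30)))
  w <- capture_warnings(fit <- fit_weighted_logistic(d, y ~ x))
  expect_match(w, "separation", all = FALSE)
  expect_true(fit$separation)
})

test_that("the by-domain report marks reference rows and formats ORs", {
  withr::with_seed(12, {
    n <- 600
    d <- tibble::tibble(
      risky_behavior = risk_factor(sample(1:3, n, TRUE), 3),
      health_condition = risk_factor(sample(1:3, n, TRUE), 3),
      health_care_access = risk_factor(sample(1:2, n, TRUE), 2),
      preventive_service = risk_factor(sample(1:3, n, TRUE), 3)
    )
    d$y1 <- rbinom(n, 1, plogis(-1 + 0.8 * (d$health_condition == "high")))
    d$y2 <- rbinom(n, 1, 0.3)
  })
  rhs <- paste(domain_names(), collapse = " + ")
  fits <- list(
    physical = fit_weighted_logistic(d, as.formula(paste("y1 ~", rhs))),
    mental = fit_weighted_logistic(d, as.formula(paste("y2 ~", rhs)))
  )
  tab <- build_or_table(fits)
  expect_equal(nrow(tab), 3 + 3 + 2 + 3)
  refs <- tab[tab$level == "low", ]
  expect_true(all(refs$or_ci_physical == "1 [Reference]"))
  expect_true(all(is.na(refs$p_physical)))
  hc_high <- fits$physical$or_table[
    fits$physical$or_table$term == "health_conditionhigh", ]
  expect_equal(tab$or_ci_physical[tab$domain == "health_condition" &
                                    tab$level == "high"],
               sprintf("%.2f (%.2f-%.2f)", hc_high$or, hc_high$conf.low,
                       hc_high$conf.high))
})

test_that("risk_factor puts the low-risk class as reference", {
  f <- risk_factor(c(1L, 2L, 3L), 3)
  expect_equal(levels(f), c("low", "intermediate", "high"))
  expect_equal(as.character(f), c("high", "intermediate", "low"))
  expect_equal(levels(risk_factor(1L, 1)), "low")
})

test_that("weighted prevalence table matches direct computation", {
  withr::with_seed(13, {
    d <- tibble::tibble(
      grp = sample(c("a", "b"), 400, TRUE),
      design_weight = runif(400, 0.5, 2),
      y = rbinom(400, 1, 0.25)
    )
  })
  tab <- prevalence_table(d, outcomes = "y", demographics = "grp")
  for (g in c("a", "b")) {
    sel <- d$grp == g
    p_direct <- 100 * weighted.mean(d$y[sel], d$design_weight[sel])
    row <- tab[tab$level == g, ]
    expect_equal(row$prevalence, p_direct, tolerance = 1e-10)
    expect_equal(row$n, sum(sel))
    expect_true(row$conf.low < p_direct && row$conf.high > p_direct)
  }

  # equal weights reduce to the simple proportion; all-ones outcome is 100%
  d$design_weight <- 1
  d$one <- 1L
  tab2 <- prevalence_table(d, outcomes = c("y", "one"), demographics = "grp")
  expect_equal(tab2$prevalence[tab2$outcome == "y" & tab2$level == "a"],
               100 * mean(d$y[d$grp == "a"]), tolerance = 1e-12)
  expect_true(all(tab2$prevalence[tab2$outcome == "one"] == 100))

  # empty category: zero count, undefined CI
  d2 <- d
  d2$grp <- factor(d2$grp, levels = c("a", "b", "c"))
  tab3 <- prevalence_table(d2, outcomes = "y", demographics = "grp")
  crow <- tab3[tab3$level == "c", ]
  expect_equal(crow$n, 0L)
  expect_true(is.na(crow$prevalence))
})

test_that("cluster/stratum labels enter the sandwich variance correctly", {
  withr::with_seed(21, {
    d <- tibble::tibble(x = rnorm(600))
    d$y <- rbinom(600, 1, plogis(-0.3 + 0.6 * d$x))
  })
  base <- fit_weighted_logistic(d, y ~ x)
  # one record per PSU, one stratum: equals HC0 times n/(n-1)
  solo <- fit_weighted_logistic(d, y ~ x, cluster = seq_len(600))
  expect_equal(solo$vcov, base$vcov * 600 / 599, tolerance = 1e-6)

  # strongly cluster-correlated design: clustered SEs exceed naive ones
  withr::with_seed(22, {
    g <- rep(1:30, each = 40)
    u <- rnorm(30, 0, 1.5)[g]
    dc <- tibble::tibble(g = g, x = rnorm(1200),
                         strat = rep(1:2, each = 600))
    dc$y <- rbinom(1200, 1, plogis(u + 0.4 * dc$x))
  })
  cl <- fit_weighted_logistic(dc, y ~ x, cluster = "g", strata = "strat")
  naive <- fit_weighted_logistic(dc, y ~ x)
  expect_gt(sqrt(cl$vcov[1, 1]), sqrt(naive$vcov[1, 1]))
  expect_equal(coef(cl$fit), coef(naive$fit))
})
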