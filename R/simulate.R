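#' Simulate a survey dataset with known latent structure
#'
#' Draws a full respondent-level survey from a [population_spec()]:
#' demographics, design weights, a true latent class per domain, raw survey
#' responses consistent with the class-conditional indicator probabilities,
#' and the two unhealthy-days outcomes generated from the spec's logistic
#' link. Sex- and age-gated screening questions are not asked of ineligible
#' respondents (structural missingness); independent item nonresponse is
#' then injected at the spec's `item_missing_rate`.
#'
#' True class labels are kept in a sidecar tibble (`$truth`), never in the
#' emitted respondent table, so estimation code cannot see them.
#'
#' The raw responses are generated by inverting the recoding rules: for each
#' respondent a binary indicator value is drawn from the class-conditional
#' probability, then a raw answer is drawn that recodes back to exactly that
#' value (e.g. binge drinking = 1 for a man becomes a maximum-drinks answer
#' of at least 5). This guarantees the generator and the recoder agree.
#'
#' @param spec a [population_spec()].
#' @return An object of class `survey_dataset`: a list with `respondents`
#'   (tibble, one row per respondent), `truth` (tibble of true class labels,
#'   class 1 = highest risk), and `spec`.
#' @examples
#' svy <- simulate_survey(population_spec(n_respondents = 200, seed = 7))
#' svy
#' @export
simulate_survey <- function(spec) {
  validate_population_spec(spec)
  withr::with_seed(spec$seed, simulate_survey_impl(spec))
}

simulate_survey_impl <- function(spec) {
  n <- spec$n_respondents
  lv <- demographic_levels()

  sex <- ifelse(rbinom(n, 1, spec$sex_fraction_female) == 1, "female", "male")
  age_group <- sample(lv$age_group, n, replace = TRUE,
                      prob = spec$demographic_dists$age_group)
  age_years <- draw_age_within_group(age_group)
  race_ethnicity <- sample(lv$race_ethnicity, n, replace = TRUE,
                           prob = spec$demographic_dists$race_ethnicity)
  education <- sample(lv$education, n, replace = TRUE,
                      prob = spec$demographic_dists$education)
  employment <- sample(lv$employment, n, replace = TRUE,
                       prob = spec$demographic_dists$employment)
  intact_cervix <- ifelse(sex == "female",
                          ifelse(rbinom(n, 1, spec$prop_intact_cervix) == 1,
                                 "yes", "no"),
                          NA_character_)

  # post-stratification-style base factor x lognormal noise; weights are
  # independent of the indicators given demographics
  age_fac <- c(`18-44` = 1.40, `45-64` = 0.85, `65+` = 0.70)[age_group]
  sex_fac <- c(male = 1.25, female = 0.85)[sex]
  design_weight <- as.numeric(age_fac * sex_fac *
                                rlnorm(n, meanlog = 0, sdlog = spec$weight_sdlog))

  truth <- tibble(id = seq_len(n))
  for (d in domain_names()) {
    pi_d <- spec$domain_specs[[d]]$pi
    truth[[d]] <- sample.int(length(pi_d), n, replace = TRUE, prob = pi_d)
  }

  reg <- indicator_registry()
  ind <- matrix(NA_integer_, n, nrow(reg), dimnames = list(NULL, reg$item))
  for (k in seq_len(nrow(reg))) {
    item <- reg$item[k]
    rho_d <- spec$domain_specs[[reg$domain[k]]]$rho
    j <- match(item, domain_items(reg$domain[k]))
    p <- rho_d[cbind(truth[[reg$domain[k]]], j)]
    applies <- item_applies(item, sex, age_years, intact_cervix)
    draw <- rbinom(n, 1, p)
    ind[, k] <- ifelse(applies, draw, NA_integer_)
  }

  raw <- raw_from_indicators(ind, sex)

  eta <- outcome_linear_predictor(spec$outcome_model, truth,
                                  age_group, sex, race_ethnicity,
                                  education, employment)
  phys <- rbinom(n, 1, plogis(eta$physical))
  ment <- rbinom(n, 1, plogis(eta$mental))
  phys_days <- ifelse(phys == 1, sample(14:30, n, replace = TRUE),
                      sample(0:13, n, replace = TRUE))
  ment_days <- ifelse(ment == 1, sample(14:30, n, replace = TRUE),
                      sample(0:13, n, replace = TRUE))

  respondents <- bind_cols(
    tibble(id = seq_len(n), sex = sex, age_years = age_years,
           age_group = age_group, race_ethnicity = race_ethnicity,
           education = education, employment = employment,
           intact_cervix = intact_cervix, design_weight = design_weight),
    as_tibble(raw),
    tibble(phys_days = phys_days, ment_days = ment_days)
  )

  out <- structure(
    list(respondents = respondents, truth = truth, spec = spec),
    class = "survey_dataset"
  )
  if (spec$item_missing_rate > 0) {
    out <- inject_missingness(out, spec$item_missing_rate,
                              seed = derive_seed(spec$seed, 104729L))
  }
  out
}

draw_age_within_group <- function(age_group) {
  n <- length(age_group)
  lo <- c(`18-44` = 18L, `45-64` = 45L, `65+` = 65L)[age_group]
  hi <- c(`18-44` = 44L, `45-64` = 64L, `65+` = 90L)[age_group]
  as.integer(lo + floor(runif(n) * (hi - lo + 1L)))
}

# Invert the recoding rules: a raw answer consistent with each drawn
# indicator value. NA indicator (structural) => NA raw answer.
raw_from_indicators <- function(ind, sex) {
  n <- nrow(ind)
  yn <- function(v, adverse = "yes") {
    other <- if (adverse == "yes") "no" else "yes"
    ifelse(is.na(v), NA_character_, ifelse(v == 1, adverse, other))
  }
  binge_thr <- ifelse(sex == "male", 5L, 4L)
  heavy_thr <- ifelse(sex == "male", 3, 2)
  list(
    smoke_status = ifelse(ind[, "smoking"] == 1,
                          sample(c("daily", "some days"), n, TRUE, c(0.8, 0.2)),
                          "not at all"),
    max_drinks_occasion = ifelse(ind[, "binge_drinking"] == 1,
                                 binge_thr + rpois(n, 1.2),
                                 as.integer(floor(runif(n) * binge_thr))),
    avg_drinks_per_day = round(ifelse(ind[, "heavy_drinking"] == 1,
                                      heavy_thr + rexp(n, 1),
                                      runif(n, 0, heavy_thr - 0.1)), 1),
    drink_drive_days = ifelse(ind[, "drink_drive"] == 1,
                              1L + as.integer(floor(runif(n) * 5)), 0L),
    seatbelt = ifelse(ind[, "seatbelt_nonuse"] == 1,
                      sample(c("nearly always", "sometimes", "seldom", "never"),
                             n, TRUE, c(0.5, 0.25, 0.1, 0.15)),
                      "always"),
    asthma_now = yn(ind[, "asthma"]),
    diabetes = yn(ind[, "diabetes"]),
    bmi = round(ifelse(ind[, "obesity"] == 1, runif(n, 30, 45),
                       runif(n, 18.5, 29.8)), 1),
    disability = yn(ind[, "disability"]),
    teeth_lost_count = ifelse(ind[, "teeth_lost"] == 1,
                              6L + as.integer(floor(runif(n) * 20)),
                              as.integer(floor(runif(n) * 6))),
    angina_chd = yn(ind[, "angina_chd"]),
    heart_attack = yn(ind[, "heart_attack"]),
    stroke = yn(ind[, "stroke"]),
    has_coverage = yn(ind[, "no_coverage"], adverse = "no"),
    cost_barrier = yn(ind[, "cost_barrier"]),
    has_provider = yn(ind[, "no_provider"], adverse = "no"),
    checkup_past_year = yn(ind[, "no_checkup"], adverse = "no"),
    dental_past_year = yn(ind[, "no_dental_visit"], adverse = "no"),
    pneumonia_vax_ever = yn(ind[, "no_pneumonia_vax"], adverse = "no"),
    flu_vax_past_year = yn(ind[, "no_flu_vax"], adverse = "no"),
    psa_test_2y = yn(ind[, "no_psa_test"], adverse = "no"),
    sigmoid_colonoscopy_ever = yn(ind[, "no_sigmoid_colonoscopy"], adverse = "no"),
    mammogram_2y = yn(ind[, "no_mammogram"], adverse = "no"),
    pap_test_3y = yn(ind[, "no_pap_test"], adverse = "no")
  )
}

outcome_linear_predictor <- function(outcome_model, truth, age_group, sex,
                                     race_ethnicity, education, employment) {
  terms <- class_term_names(truth)
  demo <- tibble(age_group = age_group, sex = sex,
                 race_ethnicity = race_ethnicity, education = education,
                 employment = employment)
  lapply(outcome_model, function(om) {
    eta <- rep(om$intercept, nrow(truth))
    cf <- om$coefficients
    class_coef <- grepl(paste0("^(", paste(domain_names(), collapse = "|"),
                               ")_"), names(cf))
    for (k in seq_along(cf)) {
      nm <- names(cf)[k]
      if (nm %in% names(terms)) {
        eta <- eta + cf[[nm]] * terms[[nm]]
      } else if (class_coef[k]) {
        # class term absent (e.g. a single-class domain): contributes 0
        next
      } else {
        hit <- FALSE
        for (v in names(demo)) {
          pre <- paste0(v, "_")
          if (startsWith(nm, pre)) {
            eta <- eta + cf[[nm] ] * (demo[[v]] == sub(pre, "", nm))
            hit <- TRUE
            break
          }
        }
        if (!hit) {
          abort(paste0("Unknown outcome-model coefficient `", nm, "`."),
                class = "riskclass_config_error")
        }
      }
    }
    eta
  })
}

# Dummy variables for true class membership: class 1 (highest risk) is the
# "high" term, the last class is the low-risk reference, anything between is
# "intermediate".
class_term_names <- function(truth) {
  out <- list()
  for (d in domain_names()) {
    cls <- truth[[d]]
    K <- max(cls)
    if (K >= 2) {
      out[[paste0(d, "_high")]] <- as.numeric(cls == 1)
      if (K >= 3) {
        out[[paste0(d, "_intermediate")]] <- as.numeric(cls > 1 & cls < K)
      }
    }
  }
  out
}

#' Inject independent item nonresponse
#'
#' Sets each non-structurally-missing indicator response to missing
#' independently with probability `rate`. Structural missingness (questions
#' not asked because of sex, age, or cervix eligibility gates) is untouched.
#' The operation acts on the raw survey columns that the 24 indicators are
#' derived from, one column per indicator.
#'
#' @param data a `survey_dataset`.
#' @param rate missingness probability in `[0, 0.5)`.
#' @param seed integer seed; the result is deterministic given it.
#' @return The modified `survey_dataset`.
#' @export
inject_missingness <- function(data, rate, seed = 1L) {
  stopifnot(inherits(data, "survey_dataset"))
  if (rate < 0 || rate >= 0.5) {
    abort("`rate` must lie in [0, 0.5).", class = "riskclass_config_error")
  }
  if (rate == 0) return(data)
  resp <- data$respondents
  reg <- indicator_registry()
  withr::with_seed(seed, {
    for (k in seq_len(nrow(reg))) {
      applies <- item_applies(reg$item[k], resp$sex, resp$age_years,
                              resp$intact_cervix)
      hit <- applies & (runif(nrow(resp)) < rate)
      col <- reg$raw_field[k]
      resp[[col]][hit] <- if (is.character(resp[[col]])) NA_character_ else NA
    }
  })
  data$respondents <- resp
  data
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + salt) %% 2147483647)
}

#' @export
print.survey_dataset <- function(x, ...) {
  n <- nrow(x$respondents)
  cat("<survey_dataset>", n, "respondents,",
      sum(x$respondents$sex == "male"), "men /",
      sum(x$respondents$sex == "female"), "women\n")
  cat("  raw columns:", ncol(x$respondents), " truth sidecar for",
      ncol(x$truth) - 1L, "domains\n")
  invisible(x)
}
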