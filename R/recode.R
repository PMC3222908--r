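#' Derive the 24 binary indicators from raw survey responses
#'
#' Applies the indicator definitions to a respondent table: current smoking
#' (daily or some days); binge drinking (>= 5 drinks for men, >= 4 for women
#' on one occasion in the past 30 days); heavy drinking (>= 3 drinks/day for
#' men, >= 2 for women); any drinking and driving in the past 30 days; not
#' always wearing a seatbelt; current asthma; diabetes; obesity (BMI >= 30
#' kg/m2); disability; six or more teeth lost; angina/CHD; heart attack;
#' stroke; the five access items; and the six preventive items with their
#' eligibility gates (PSA men >= 40, sigmoidoscopy/colonoscopy >= 50,
#' mammogram women >= 40, Pap women with intact cervix; boundary ages are
#' eligible).
#'
#' Every indicator is coded 1 = adverse/risk state. An item a respondent was
#' not asked by design is *structurally* missing; an unanswered item is
#' ordinary item nonresponse. Both appear as `NA` in the value matrices but
#' are distinguished by the structural mask.
#'
#' @param data a `survey_dataset` or a respondent tibble with the raw
#'   columns listed in [indicator_registry()] plus `sex`, `age_years`, and
#'   `intact_cervix`.
#' @return A named list of four `indicator_matrix` objects, one per domain.
#' @examples
#' svy <- simulate_survey(population_spec(n_respondents = 100, seed = 2))
#' ind <- derive_indicators(svy)
#' ind$risky_behavior
#' @export
derive_indicators <- function(data) {
  resp <- if (inherits(data, "survey_dataset")) data$respondents else data
  stopifnot(is.data.frame(resp))
  validate_raw_responses(resp)
  n <- nrow(resp)

  yes1 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x == "yes"))
  no1 <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x == "no"))

  male <- resp$sex == "male"
  vals <- list(
    smoking = ifelse(is.na(resp$smoke_status), NA_integer_,
                     as.integer(resp$smoke_status %in% c("daily", "some days"))),
    binge_drinking = as.integer(resp$max_drinks_occasion >=
                                  ifelse(male, 5L, 4L)),
    heavy_drinking = as.integer(resp$avg_drinks_per_day >=
                                  ifelse(male, 3, 2)),
    drink_drive = as.integer(resp$drink_drive_days >= 1),
    seatbelt_nonuse = ifelse(is.na(resp$seatbelt), NA_integer_,
                             as.integer(resp$seatbelt != "always")),
    asthma = yes1(resp$asthma_now),
    diabetes = yes1(resp$diabetes),
    obesity = as.integer(resp$bmi >= 30),
    disability = yes1(resp$disability),
    teeth_lost = as.integer(resp$teeth_lost_count >= 6),
    angina_chd = yes1(resp$angina_chd),
    heart_attack = yes1(resp$heart_attack),
    stroke = yes1(resp$stroke),
    no_coverage = no1(resp$has_coverage),
    cost_barrier = yes1(resp$cost_barrier),
    no_provider = no1(resp$has_provider),
    no_checkup = no1(resp$checkup_past_year),
    no_dental_visit = no1(resp$dental_past_year),
    no_pneumonia_vax = no1(resp$pneumonia_vax_ever),
    no_flu_vax = no1(resp$flu_vax_past_year),
    no_psa_test = no1(resp$psa_test_2y),
    no_sigmoid_colonoscopy = no1(resp$sigmoid_colonoscopy_ever),
    no_mammogram = no1(resp$mammogram_2y),
    no_pap_test = no1(resp$pap_test_3y)
  )

  reg <- indicator_registry()
  out <- list()
  for (d in domain_names()) {
    items <- domain_items(d)
    values <- do.call(cbind, vals[items])
    structural <- matrix(FALSE, n, length(items),
                         dimnames = list(NULL, items))
    for (item in items) {
      applies <- item_applies(item, resp$sex, resp$age_years,
                              resp$intact_cervix)
      structural[, item] <- !applies
      values[!applies, item] <- NA_integer_
    }
    out[[d]] <- indicator_matrix(d, values, structural)
  }
  out
}

validate_raw_responses <- function(resp) {
  bad <- character()
  chk <- function(cond, field) if (any(cond, na.rm = TRUE)) bad <<- c(bad, field)
  if ("bmi" %in% names(resp)) chk(resp$bmi <= 0, "bmi")
  if ("drink_drive_days" %in% names(resp)) {
    chk(resp$drink_drive_days < 0 | resp$drink_drive_days > 30,
        "drink_drive_days")
  }
  if ("phys_days" %in% names(resp)) chk(resp$phys_days < 0 | resp$phys_days > 30, "phys_days")
  if ("ment_days" %in% names(resp)) chk(resp$ment_days < 0 | resp$ment_days > 30, "ment_days")
  if ("teeth_lost_count" %in% names(resp)) chk(resp$teeth_lost_count < 0, "teeth_lost_count")
  if ("max_drinks_occasion" %in% names(resp)) chk(resp$max_drinks_occasion < 0, "max_drinks_occasion")
  if ("age_years" %in% names(resp)) chk(resp$age_years < 18, "age_years")
  if (length(bad)) {
    abort(paste0("Impossible raw values in field(s): ",
                 paste(unique(bad), collapse = ", ")),
          class = "riskclass_validation_error")
  }
  invisible(resp)
}

#' Indicator matrix container
#'
#' A per-domain n x J matrix of binary indicator values with an aligned
#' logical mask flagging *structural* missingness (items not asked of a
#' respondent by design). Ordinary item nonresponse and structural
#' missingness are both `NA` in `values`; only the former is `NA` with
#' `structural = FALSE`.
#'
#' @param domain domain name.
#' @param values integer n x J matrix in \{0, 1, NA\} with item-name columns.
#' @param structural logical n x J matrix, `TRUE` where missingness is
#'   structural; defaults to all `FALSE`.
#' @return An `indicator_matrix` object.
#' @export
indicator_matrix <- function(domain, values,
                             structural = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(structural)) {
    structural <- matrix(FALSE, nrow(values), ncol(values))
  }
  stopifnot(all(dim(structural) == dim(values)),
            all(values %in% c(0L, 1L) | is.na(values)),
            all(is.na(values[structural])))
  structure(
    list(domain = domain, values = values, structural = structural,
         item_names = colnames(values)),
    class = "indicator_matrix"
  )
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("<indicator_matrix>", x$domain, ":", nrow(x$values), "x",
      ncol(x$values), "\n")
  cat("  items:", paste(x$item_names, collapse = ", "), "\n")
  miss <- is.na(x$values)
  cat(sprintf("  missing cells: %d structural, %d nonresponse\n",
              sum(x$structural), sum(miss & !x$structural)))
  invisible(x)
}

#' @method as_tibble indicator_matrix
#' @export
as_tibble.indicator_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$values))
  out$.row <- seq_len(nrow(out))
  tidyr::pivot_longer(out, -".row", names_to = "item",
                      values_to = "value") %>%
    mutate(structural = as.vector(t(x$structural)),
           domain = x$domain) %>%
    select("domain", ".row", "item", "value", "structural")
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

#' Dichotomize an unhealthy-days count
#'
#' The two health-related quality-of-life outcomes count physically and
#' mentally unhealthy days in the past 30; each is dichotomized at 14 or
#' more days ("frequent distress") versus 0-13 days.
#'
#' @param days integer vector in `[0, 30]`; `NA` propagates.
#' @return Integer vector in \{0, 1, NA\}.
#' @examples
#' dichotomize_hrqol(c(0, 13, 14, 30, NA))
#' @export
dichotomize_hrqol <- function(days) {
  if (any(days < 0 | days > 30, na.rm = TRUE)) {
    abort("`days` must lie in [0, 30].", class = "riskclass_validation_error")
  }
  ifelse(is.na(days), NA_integer_, as.integer(days >= 14))
}

#' Enumerate complete response patterns for a domain
#'
#' The latent class likelihood can be expressed over distinct complete
#' response patterns; a domain with J applicable binary items has 2^J of
#' them. For the preventive-services domain the applicable item count
#' depends on sex (the PSA question is asked only of men, mammogram and Pap
#' only of women), so the pattern count is sex-specific.
#'
#' @param domain domain name.
#' @param sex for `preventive_service`, `"male"` or `"female"`; ignored
#'   otherwise. For gated items the most-inclusive eligible profile is used
#'   (age above all gates, intact cervix).
#' @return A tibble with one row per pattern and one column per applicable
#'   item.
#' @examples
#' nrow(enumerate_patterns("risky_behavior"))        # 32
#' nrow(enumerate_patterns("preventive_service", "male"))   # 16
#' nrow(enumerate_patterns("preventive_service", "female")) # 32
#' @export
enumerate_patterns <- function(domain, sex = "male") {
  items <- domain_items(domain)
  applicable <- vapply(items, function(it) {
    item_applies(it, sex, age_years = 80L, intact_cervix = "yes")
  }, logical(1))
  items <- items[applicable]
  grid <- do.call(expand.grid, setNames(rep(list(0:1), length(items)), items))
  as_tibble(grid)
}

#' Dichotomized distress outcomes for a survey
#'
#' @param data a `survey_dataset` or respondent tibble with `phys_days` and
#'   `ment_days`.
#' @return The respondent tibble with `frequent_phys_distress` and
#'   `frequent_ment_distress` columns appended.
#' @export
derive_outcomes <- function(data) {
  resp <- if (inherits(data, "survey_dataset")) data$respondents else data
  resp %>%
    mutate(frequent_phys_distress = dichotomize_hrqol(.data$phys_days),
           frequent_ment_distress = dichotomize_hrqol(.data$ment_days))
}
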