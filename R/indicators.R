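#' The 24 binary health indicators and their four domains
#'
#' Every analysis in this package runs over 24 dichotomous indicators grouped
#' into four health domains: 5 risky behaviors, 8 health conditions, 5 health
#' care access items, and 6 preventive service items. Each indicator is coded
#' so that 1 is the adverse (risk) state; this polarity makes the risk
#' ordering of latent classes monotone in endorsement probability.
#'
#' Four preventive items are eligibility-gated: the PSA test applies only to
#' men aged 40 or older, sigmoidoscopy/colonoscopy to adults 50 or older,
#' mammography to women 40 or older, and the Pap test to women with an intact
#' cervix. Ineligible respondents are structurally missing on those items.
#'
#' @return A tibble with one row per indicator: `item` (indicator name),
#'   `domain`, `raw_field` (the survey column it is derived from), and
#'   `label` (a human-readable description).
#' @examples
#' indicator_registry()
#' dplyr::count(indicator_registry(), domain)
#' @export
indicator_registry <- function() {
  tibble::tribble(
    ~item,                    ~domain,              ~raw_field,                ~label,
    "smoking",                "risky_behavior",     "smoke_status",            "Currently smokes cigarettes (daily or some days)",
    "binge_drinking",         "risky_behavior",     "max_drinks_occasion",     "Binge drinking (>=5 drinks men / >=4 women, one occasion, past 30 d)",
    "heavy_drinking",         "risky_behavior",     "avg_drinks_per_day",      "Heavy drinking (>=3 drinks/d men / >=2 women)",
    "drink_drive",            "risky_behavior",     "drink_drive_days",        "Drinking and driving in past 30 days",
    "seatbelt_nonuse",        "risky_behavior",     "seatbelt",                "Not always wearing a seatbelt",
    "asthma",                 "health_condition",   "asthma_now",              "Current asthma",
    "diabetes",               "health_condition",   "diabetes",                "Diabetes",
    "obesity",                "health_condition",   "bmi",                     "Obesity (BMI >= 30 kg/m2)",
    "disability",             "health_condition",   "disability",              "Activity limitation or special equipment",
    "teeth_lost",             "health_condition",   "teeth_lost_count",        "Six or more teeth lost to decay or gum disease",
    "angina_chd",             "health_condition",   "angina_chd",              "Angina or coronary heart disease",
    "heart_attack",           "health_condition",   "heart_attack",            "Heart attack (myocardial infarction)",
    "stroke",                 "health_condition",   "stroke",                  "Stroke",
    "no_coverage",            "health_care_access", "has_coverage",            "No health care coverage",
    "cost_barrier",           "health_care_access", "cost_barrier",            "Could not see doctor because of cost, past year",
    "no_provider",            "health_care_access", "has_provider",            "No regular health care provider",
    "no_checkup",             "health_care_access", "checkup_past_year",       "No routine checkup in past year",
    "no_dental_visit",        "health_care_access", "dental_past_year",        "No dental visit in past year",
    "no_pneumonia_vax",       "preventive_service", "pneumonia_vax_ever",      "Never had pneumonia vaccination",
    "no_flu_vax",             "preventive_service", "flu_vax_past_year",       "No influenza vaccination in past 12 months",
    "no_psa_test",            "preventive_service", "psa_test_2y",             "No PSA test in past 2 years (men >= 40 y)",
    "no_sigmoid_colonoscopy", "preventive_service", "sigmoid_colonoscopy_ever","Never had sigmoidoscopy or colonoscopy (>= 50 y)",
    "no_mammogram",           "preventive_service", "mammogram_2y",            "No mammogram in past 2 years (women >= 40 y)",
    "no_pap_test",            "preventive_service", "pap_test_3y",             "No Pap test in past 3 years (women, intact cervix)"
  )
}

#' @rdname indicator_registry
#' @export
domain_names <- function() {
  c("risky_behavior", "health_condition", "health_care_access",
    "preventive_service")
}

domain_items <- function(domain) {
  reg <- indicator_registry()
  reg$item[reg$domain == domain]
}

#' Which indicators apply to a respondent
#'
#' Applies the eligibility gates: PSA only for men aged 40 or older,
#' sigmoidoscopy/colonoscopy only at age 50 or older, mammogram only for
#' women 40 or older, Pap test only for women with an intact cervix.
#' Boundary ages (exactly 40 or 50) are eligible. All other indicators
#' apply to everyone.
#'
#' @param item indicator name (see [indicator_registry()]).
#' @param sex `"male"` or `"female"`.
#' @param age_years age in whole years at interview.
#' @param intact_cervix `"yes"`/`"no"` (only consulted for the Pap item).
#' @return Logical vector: is the item asked of this respondent?
#' @export
item_applies <- function(item, sex, age_years, intact_cervix = "yes") {
  switch(item,
    no_psa_test            = sex == "male" & age_years >= 40,
    no_sigmoid_colonoscopy = age_years >= 50,
    no_mammogram           = sex == "female" & age_years >= 40,
    no_pap_test            = sex == "female" & !is.na(intact_cervix) &
                               intact_cervix == "yes",
    rep_len(TRUE, length(sex))
  )
}

demographic_levels <- function() {
  list(
    age_group      = c("18-44", "45-64", "65+"),
    sex            = c("male", "female"),
    race_ethnicity = c("nh_white", "hispanic", "nh_other"),
    education      = c("hs_or_less", "some_college", "college_grad"),
    employment     = c("employed", "homemaker_student", "retired",
                       "unemployed", "unable_to_work")
  )
}
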