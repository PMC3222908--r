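#' Write / read a survey as CSV plus a codebook
#'
#' `write_survey()` emits the respondent table as a CSV (one row per
#' respondent, missing cells empty) together with a YAML codebook that maps
#' each raw column to its indicator, domain and adverse polarity, and
#' documents the weight, demographic and outcome columns. The truth sidecar
#' is deliberately *not* written: downstream estimation must never see it.
#' `read_survey()` reads the pair back into a `survey_dataset` (with no
#' truth).
#'
#' @param data a `survey_dataset` or respondent tibble.
#' @param dir output directory (created if needed).
#' @return `write_survey()` returns the paths invisibly; `read_survey()`
#'   returns a `survey_dataset`.
#' @export
write_survey <- function(data, dir) {
  resp <- if (inherits(data, "survey_dataset")) data$respondents else data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "respondents.csv")
  cb <- file.path(dir, "codebook.yaml")
  readr::write_csv(resp, csv, na = "")
  reg <- indicator_registry()
  codebook <- list(
    missing_sentinel = "empty cell",
    weight_column = "design_weight",
    demographics = names(demographic_levels()),
    outcomes = list(
      phys_days = "physically unhealthy days, past 30 (dichotomized at >= 14)",
      ment_days = "mentally unhealthy days, past 30 (dichotomized at >= 14)"
    ),
    indicators = purrr::pmap(reg, function(item, domain, raw_field, label) {
      list(item = item, domain = domain, raw_field = raw_field,
           label = label, adverse_value = 1L)
    })
  )
  yaml::write_yaml(codebook, cb)
  invisible(c(respondents = csv, codebook = cb))
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  csv <- file.path(dir, "respondents.csv")
  if (!file.exists(csv)) {
    abort(paste0("No respondents.csv under ", dir),
          class = "riskclass_config_error")
  }
  resp <- readr::read_csv(csv, na = "", show_col_types = FALSE,
                          col_types = survey_col_types())
  structure(list(respondents = resp, truth = NULL, spec = NULL),
            class = "survey_dataset")
}

survey_col_types <- function() {
  readr::cols(
    id = readr::col_integer(),
    sex = readr::col_character(),
    age_years = readr::col_integer(),
    age_group = readr::col_character(),
    race_ethnicity = readr::col_character(),
    education = readr::col_character(),
    employment = readr::col_character(),
    intact_cervix = readr::col_character(),
    design_weight = readr::col_double(),
    smoke_status = readr::col_character(),
    max_drinks_occasion = readr::col_integer(),
    avg_drinks_per_day = readr::col_double(),
    drink_drive_days = readr::col_integer(),
    seatbelt = readr::col_character(),
    bmi = readr::col_double(),
    teeth_lost_count = readr::col_integer(),
    phys_days = readr::col_integer(),
    ment_days = readr::col_integer(),
    .default = readr::col_character()
  )
}
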