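## Tabular input/output and run configuration.
##
## All interchange is comma-delimited UTF-8 with a header row; missing values
## are empty fields. Downstream stages consume only the validated data.tables
## produced here and never re-parse raw text.

default_physical_conditions <- function() {
  c("asthma", "cancer", "cardiovascular_disease", "chronic_kidney_disease",
    "chronic_liver_disease", "copd", "dementia", "diabetes", "epilepsy",
    "gastroenterological", "neurological", "rheumatological",
    "physical_disability")
}

default_mental_conditions <- function() {
  c("anxiety", "depression", "severe_mental_illness", "neurodevelopmental",
    "learning_disability")
}

default_tariffs <- function() {
  ## abstract currency units per contact; site-configurable
  c(primary_care = 39, ae = 180, inpatient = 1500, outpatient = 120,
    mental_health = 220, community = 90, adult_social_care = 250,
    children_social_care = 1500)
}

default_thresholds <- function() {
  list(
    ae_visits_per_year   = 5L,    # flag is strictly greater than this
    distinct_services_min = 3L,
    spend_quantile       = 0.75,
    deprivation_quantile = 0.20,
    child_age_max        = 16L,
    max_household_size   = 10L
  )
}

#' Default run configuration
#'
#' Builds a fully resolved configuration: the condition taxonomy (physical,
#' mental, child-problem code sets), vulnerability code lists, a sector
#' tariff table and the segmentation thresholds. The shipped taxonomy names
#' the long-term conditions the segmentation reads (asthma through physical
#' disability on the physical side; anxiety, depression, severe mental
#' illness, neurodevelopmental conditions and learning disabilities on the
#' mental side); real deployments replace it with local clinical code lists.
#'
#' Thresholds and their defaults: `ae_visits_per_year` 5 (a person is a
#' frequent A&E attender with strictly more than this many attendances in
#' the year), `distinct_services_min` 3, `spend_quantile` 0.75 (top quarter
#' of per-capita spend), `deprivation_quantile` 0.20 (most deprived fifth),
#' `child_age_max` 16 (children are aged 0-16 inclusive),
#' `max_household_size` 10 (larger address groups are treated as
#' institutional and dropped).
#'
#' @param ... Named overrides for any top-level field.
#' @return A `hhseg_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    physical_conditions = default_physical_conditions(),
    mental_conditions = default_mental_conditions(),
    ## children qualify through any condition listed for adults, plus
    ## disabilities; NULL means "physical + mental union", resolved below
    child_problem_conditions = NULL,
    vulnerability_codes = list(
      homelessness    = "homelessness",
      substance_abuse = "substance_abuse",
      child_in_care   = "child_in_care"
    ),
    tariffs = as.list(default_tariffs()),
    thresholds = default_thresholds(),
    ## reason classes counted as mental-health presentations
    mh_reason_classes = c("mental_health", "anxiety", "crisis", "self_harm",
                          "eating_disorder", "neurodevelopmental"),
    random_seed = 1L
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_config(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' Absent fields fall back to [default_config()] values; absent thresholds
#' fall back individually, so a config may set only what it changes.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `hhseg_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_config()
  for (nm in setdiff(names(raw), c("thresholds", "vulnerability_codes", "tariffs"))) {
    cfg[[nm]] <- raw[[nm]]
  }
  for (nm in names(raw$thresholds)) cfg$thresholds[[nm]] <- raw$thresholds[[nm]]
  for (nm in names(raw$vulnerability_codes)) {
    cfg$vulnerability_codes[[nm]] <- raw$vulnerability_codes[[nm]]
  }
  for (nm in names(raw$tariffs)) cfg$tariffs[[nm]] <- raw$tariffs[[nm]]
  validate_config(cfg)
}

#' Write a run configuration to YAML or JSON
#' @param cfg A `hhseg_config`.
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

validate_config <- function(cfg) {
  overlap <- intersect(cfg$physical_conditions, cfg$mental_conditions)
  if (length(overlap)) {
    stop("config error: codes listed as both physical and mental: ",
         paste(overlap, collapse = ", "))
  }
  if (is.null(cfg$child_problem_conditions)) {
    cfg$child_problem_conditions <-
      union(cfg$physical_conditions, cfg$mental_conditions)
  }
  th <- cfg$thresholds
  stopifnot(
    th$spend_quantile > 0, th$spend_quantile < 1,
    th$deprivation_quantile > 0, th$deprivation_quantile < 1,
    th$ae_visits_per_year >= 0, th$distinct_services_min >= 1,
    th$child_age_max >= 0, th$max_household_size >= 1
  )
  bad <- setdiff(names(cfg$tariffs), hh_sectors())
  if (length(bad)) stop("config error: unknown tariff sector(s): ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "hhseg_config")
}

#' All condition and vulnerability codes a config resolves
#' @param cfg A `hhseg_config`.
#' @return Character vector of resolvable codes.
#' @export
all_codes <- function(cfg) {
  unique(c(cfg$physical_conditions, cfg$mental_conditions,
           cfg$child_problem_conditions,
           unlist(cfg$vulnerability_codes, use.names = FALSE)))
}

## ---- readers / writers -----------------------------------------------------

require_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stop("schema error in ", what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

row_fail <- function(what, bad_rows, why) {
  stop("validation error in ", what, ": ", why, " at row(s) ",
       paste(utils::head(bad_rows, 20L), collapse = ", "),
       if (length(bad_rows) > 20L) sprintf(" (and %d more)", length(bad_rows) - 20L) else "")
}

#' Read and validate a person table
#'
#' Expected columns: `person_id`, `household_id` (may be empty),
#' `age`, `sex` (M/F/unknown), `ethnicity`, `imd_score` (in `[0,1]`, may be
#' empty), `registered` (logical). Any row failing a type or range check
#' aborts the load with the offending row numbers.
#'
#' @param path CSV path.
#' @return Validated `data.table` of persons.
#' @export
read_persons <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  validate_persons(dt)
}

validate_persons <- function(dt) {
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("person_id", "household_id", "age", "sex",
                        "ethnicity", "imd_score", "registered"), "persons")
  for (col in c("person_id", "household_id", "sex", "ethnicity")) {
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  }
  dt[, age := as.integer(age)]
  dt[, imd_score := as.numeric(imd_score)]
  dt[, registered := as.logical(registered)]
  if (anyDuplicated(dt$person_id)) {
    row_fail("persons", which(duplicated(dt$person_id)), "duplicate person_id")
  }
  bad <- which(is.na(dt$age) | dt$age < 0L)
  if (length(bad)) row_fail("persons", bad, "age missing or negative")
  bad <- which(!is.na(dt$imd_score) & (dt$imd_score < 0 | dt$imd_score > 1))
  if (length(bad)) row_fail("persons", bad, "imd_score outside [0,1]")
  bad <- which(!dt$sex %in% sex_levels())
  if (length(bad)) row_fail("persons", bad, "sex not one of M/F/unknown")
  dt[]
}

#' Read and validate a condition-flag table
#'
#' Expected columns: `person_id`, `condition_code`. Every code must resolve
#' in the loaded taxonomy (condition sets plus vulnerability code lists).
#'
#' @param path CSV path.
#' @param cfg A `hhseg_config` supplying the taxonomy.
#' @return Validated `data.table` of condition flags.
#' @export
read_conditions <- function(path, cfg) {
  dt <- data.table::fread(path, na.strings = "")
  validate_conditions(dt, cfg)
}

validate_conditions <- function(dt, cfg) {
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("person_id", "condition_code"), "conditions")
  for (col in c("person_id", "condition_code")) {
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  }
  bad <- which(!dt$condition_code %in% all_codes(cfg))
  if (length(bad)) {
    row_fail("conditions", bad, paste0(
      "condition_code not in taxonomy (e.g. '",
      dt$condition_code[bad[1L]], "')"))
  }
  dt[]
}

#' Read and validate a care-contact table
#'
#' Expected columns: `person_id`, `sector` (one of [hh_sectors()]),
#' `reason_class`, `emergency` (logical; only A&E and inpatient contacts may
#' be emergencies), `n_contacts` (positive integer), `unit_cost_override`
#' (non-negative, may be empty).
#'
#' @param path CSV path.
#' @return Validated `data.table` of contacts.
#' @export
read_contacts <- function(path) {
  dt <- data.table::fread(path, na.strings = "")
  validate_contacts(dt)
}

validate_contacts <- function(dt) {
  dt <- data.table::as.data.table(dt)
  require_columns(dt, c("person_id", "sector", "reason_class", "emergency",
                        "n_contacts", "unit_cost_override"), "contacts")
  for (col in c("person_id", "sector", "reason_class")) {
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  }
  dt[, emergency := as.logical(emergency)]
  dt[, n_contacts := as.integer(n_contacts)]
  dt[, unit_cost_override := as.numeric(unit_cost_override)]
  bad <- which(!dt$sector %in% hh_sectors())
  if (length(bad)) {
    row_fail("contacts", bad, paste0("unknown sector label (e.g. '",
                                     dt$sector[bad[1L]], "')"))
  }
  bad <- which(is.na(dt$n_contacts) | dt$n_contacts < 1L)
  if (length(bad)) row_fail("contacts", bad, "n_contacts missing or < 1")
  bad <- which(dt$emergency & !dt$sector %in% emergency_sectors())
  if (length(bad)) {
    row_fail("contacts", bad, "emergency flag outside ae/inpatient sectors")
  }
  bad <- which(!is.na(dt$unit_cost_override) & dt$unit_cost_override < 0)
  if (length(bad)) row_fail("contacts", bad, "negative unit_cost_override")
  dt[]
}

#' Load the three input tables of a run
#' @param persons,conditions,contacts CSV paths.
#' @param cfg A `hhseg_config`.
#' @return Named list of validated `data.table`s.
#' @export
load_tables <- function(persons, conditions, contacts, cfg) {
  list(persons = read_persons(persons),
       conditions = read_conditions(conditions, cfg),
       contacts = read_contacts(contacts))
}

#' Write a table as CSV (empty fields for missing values)
#' @param dt A data.frame/data.table.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(dt, path) {
  data.table::fwrite(dt, path, na = "", quote = "auto")
  invisible(path)
}
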