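## Descriptive profiling of the segment: criteria table, prevalence table,
## household-size and age/sex summaries, service co-use intersections and
## mental-health service-use breakdowns.

## round half away from zero (print-style), not banker's rounding
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage in print style
#'
#' `100 * numerator / denominator`, rounded half-up with print-style
#' precision: two decimals below 0.1%, one decimal below 2%, whole numbers
#' otherwise.
#'
#' @param numerator,denominator Counts.
#' @return Numeric percentage.
#' @export
pct_print <- function(numerator, denominator) {
  p <- 100 * numerator / denominator
  digits <- data.table::fifelse(p < 0.1, 2L, data.table::fifelse(p < 2, 1L, 0L))
  round_half_up(p, digits)
}

age_band_breaks <- function() c(0, 5, 12, 17, 25, 45, 65, Inf)
age_band_labels <- function() c("0-4", "5-11", "12-16", "17-24", "25-44",
                                "45-64", "65+")

cut_age_band <- function(age) {
  cut(age, breaks = age_band_breaks(), labels = age_band_labels(),
      right = FALSE)
}

## cohort persons with group label; complex = member of an in-segment
## household, other = member of any other household with children
cohort_persons <- function(persons, segments) {
  members <- attr(segments, "members")
  if (is.null(members)) stop("segments lack the 'members' attribute")
  x <- merge(members,
             data.table::as.data.table(persons)[, !"household_id"],
             by = "person_id")
  complex_hh <- segments[in_segment == TRUE, household_id]
  x[, group := data.table::fifelse(household_id %in% complex_hh,
                                   "complex", "other")]
  x[]
}

#' Criteria table: counts and percentages per criterion and sub-flag
#'
#' One row per criterion and Criterion-3 sub-flag; counts and print-style
#' percentages within the three column populations: all households with
#' children, other households, complex households. Within the complex
#' column, criteria 1, 2 and 4 are 100% by construction of the conjunction.
#'
#' @param segments Output of [segment_households()].
#' @return `data.table` with columns `criterion`, `total_n`, `total_pct`,
#'   `other_n`, `other_pct`, `complex_n`, `complex_pct`.
#' @export
criteria_table <- function(segments) {
  flags <- c(c1_adult_phys_and_mental = "c1_adult_phys_and_mental",
             c2_child_problem = "c2_child_problem",
             c3_vulnerability = "c3_vulnerability",
             homelessness = "homelessness", high_ae = "high_ae",
             substance_abuse = "substance_abuse", lone_parent = "lone_parent",
             child_in_care = "child_in_care", deprived = "deprived",
             multi_service = "multi_service", c4_top_spend = "c4_top_spend")
  n_tot <- nrow(segments)
  n_cx <- sum(segments$in_segment)
  n_ot <- n_tot - n_cx
  out <- data.table::rbindlist(lapply(names(flags), function(f) {
    v <- segments[[flags[[f]]]]
    cx <- sum(v & segments$in_segment)
    tot <- sum(v)
    data.table::data.table(
      criterion = f, total_n = tot, total_pct = pct_print(tot, n_tot),
      other_n = tot - cx, other_pct = pct_print(tot - cx, n_ot),
      complex_n = cx, complex_pct = pct_print(cx, n_cx))
  }))
  data.table::setattr(out, "populations",
                      c(total = n_tot, other = n_ot, complex = n_cx))
  out[]
}

#' Prevalence table: condition prevalence by age group and segment
#'
#' For every taxonomy condition, the percentage of children and of adults
#' in complex vs other households carrying the flag, with group
#' demographics (counts, mean/sd age, % male, mean/sd deprivation score).
#'
#' @param persons,conditions Validated input tables.
#' @param segments Output of [segment_households()].
#' @param cfg A `hhseg_config`.
#' @return List with `prevalence` (`condition`, `age_group`, `other_pct`,
#'   `complex_pct`) and `demographics` (per age group x segment group).
#' @export
prevalence_table <- function(persons, conditions, segments, cfg) {
  x <- cohort_persons(persons, segments)
  cm <- cfg$thresholds$child_age_max
  x[, age_group := data.table::fifelse(age <= cm, "children", "adults")]
  codes <- union(cfg$physical_conditions, cfg$mental_conditions)
  denom <- x[, .(n = .N), by = .(age_group, group)]
  flagged <- merge(conditions[condition_code %in% codes],
                   x[, .(person_id, age_group, group)], by = "person_id")
  num <- flagged[, .(k = data.table::uniqueN(person_id)),
                 by = .(condition_code, age_group, group)]
  grid <- data.table::CJ(condition_code = codes,
                         age_group = c("children", "adults"),
                         group = c("other", "complex"))
  num <- merge(grid, num, by = c("condition_code", "age_group", "group"),
               all.x = TRUE)
  data.table::set(num, which(is.na(num$k)), "k", 0L)
  num <- merge(num, denom, by = c("age_group", "group"))
  num[, pct := pct_print(num$k, num$n)]
  prev <- data.table::dcast(num, condition_code + age_group ~ group,
                            value.var = "pct")
  data.table::setnames(prev, c("other", "complex"),
                       c("other_pct", "complex_pct"))
  demo <- x[, .(n = .N, mean_age = mean(age), sd_age = stats::sd(age),
                pct_male = pct_print(sum(sex == "M"), .N),
                mean_imd = mean(imd_score, na.rm = TRUE),
                sd_imd = stats::sd(imd_score, na.rm = TRUE)),
            by = .(age_group, group)]
  data.table::setorder(demo, age_group, group)
  list(prevalence = prev[], demographics = demo[])
}

#' Household size and age/sex summaries
#'
#' @param persons Validated person table.
#' @param segments Output of [segment_households()].
#' @return List: `size_summary` (mean household size per group) and
#'   `age_sex_density` (member counts by age band x sex x group).
#' @export
size_age_sex_summary <- function(persons, segments) {
  grp <- data.table::fifelse(segments$in_segment, "complex", "other")
  size_summary <- data.table::data.table(
    group = c("complex", "other"),
    n_households = c(sum(grp == "complex"), sum(grp == "other")),
    mean_size = c(mean(segments$n_members[grp == "complex"]),
                  mean(segments$n_members[grp == "other"])))
  x <- cohort_persons(persons, segments)
  x[, age_band := cut_age_band(age)]
  density <- x[, .(n = .N), by = .(group, age_band, sex)]
  data.table::setorder(density, group, age_band, sex)
  list(size_summary = size_summary, age_sex_density = density[])
}

#' Service co-use intersections among complex households
#'
#' Partitions complex households by the exact set of care sectors their
#' members used in the year (households with no contacts form the empty
#' set), with marginal per-sector counts.
#'
#' @param segments Output of [segment_households()].
#' @param contacts Validated contact table.
#' @return `data.table` (`sectors_key`, `n_households`), sector names
#'   joined by `+`; attribute `marginals` holds per-sector counts.
#' @export
service_intersections <- function(segments, contacts) {
  members <- attr(segments, "members")
  complex_hh <- segments[in_segment == TRUE, household_id]
  m <- members[household_id %in% complex_hh]
  used <- merge(contacts[, .(person_id, sector)], m, by = "person_id")
  sets <- used[, .(sectors_key = paste(sort(unique(sector)), collapse = "+")),
               by = household_id]
  none <- setdiff(complex_hh, sets$household_id)
  if (length(none)) {
    sets <- data.table::rbindlist(list(
      sets, data.table::data.table(household_id = none, sectors_key = "")))
  }
  out <- sets[, .(n_households = .N), by = sectors_key]
  data.table::setorder(out, -n_households, sectors_key)
  marg <- unique(used[, .(household_id, sector)])[
    , .(n_households = .N), by = sector]
  data.table::setorder(marg, -n_households)
  data.table::setattr(out, "marginals", marg[])
  out[]
}

#' Mental-health service-use breakdowns
#'
#' Reason-class contact volumes for mental-health sector services by
#' segment group, and emergency mental-health attendance counts by age band
#' and sex within complex households.
#'
#' @param contacts,persons Validated input tables.
#' @param segments Output of [segment_households()].
#' @param cfg A `hhseg_config` (supplies `mh_reason_classes`).
#' @return List: `mh_reason_breakdown` (`reason_class`, `group`,
#'   `n_contacts`) and `ae_mh_by_age_sex` (`age_band`, `sex`,
#'   `n_attendances`).
#' @export
mh_breakdowns <- function(contacts, segments, persons, cfg) {
  x <- cohort_persons(persons, segments)
  mh <- merge(contacts[sector == "mental_health"],
              x[, .(person_id, group)], by = "person_id")
  reason <- mh[, .(n_contacts = sum(n_contacts)), by = .(reason_class, group)]
  data.table::setorder(reason, group, -n_contacts)
  em <- merge(contacts[emergency == TRUE &
                         reason_class %in% cfg$mh_reason_classes],
              x[group == "complex", .(person_id, age, sex)], by = "person_id")
  em[, age_band := cut_age_band(age)]
  aemh <- em[, .(n_attendances = sum(n_contacts)), by = .(age_band, sex)]
  data.table::setorder(aemh, age_band, sex)
  list(mh_reason_breakdown = reason[], ae_mh_by_age_sex = aemh[])
}

#' Full profile report
#'
#' Convenience wrapper assembling every profiling output plus segment cost
#' shares.
#'
#' @param persons,conditions,contacts Validated input tables.
#' @param segments Output of [segment_households()].
#' @param cfg A `hhseg_config`.
#' @return Named list of profiling tables.
#' @export
profile_report <- function(persons, conditions, contacts, segments, cfg) {
  person_costs <- cost_contacts(contacts, cfg)
  hcosts <- household_costs(segments, person_costs)
  sas <- size_age_sex_summary(persons, segments)
  mh <- mh_breakdowns(contacts, segments, persons, cfg)
  prev <- prevalence_table(persons, conditions, segments, cfg)
  list(
    criteria_table = criteria_table(segments),
    prevalence_table = prev$prevalence,
    demographics = prev$demographics,
    size_summary = sas$size_summary,
    age_sex_density = sas$age_sex_density,
    cost_shares = cost_share_by_sector(
      segments[in_segment == TRUE, household_id], hcosts),
    service_intersections = service_intersections(segments, contacts),
    mh_reason_breakdown = mh$mh_reason_breakdown,
    ae_mh_by_age_sex = mh$ae_mh_by_age_sex
  )
}

## ---- published worked examples --------------------------------------------

#' Published regional aggregate counts
#'
#' The criteria-table counts and cohort totals published for the 2021
#' regional deployment of this segmentation (an English region of 2.7
#' million registered people). These are printed aggregates shipped as
#' worked-example inputs: the regional record-level data are not
#' distributable, so percentage and total cells are recomputed from these
#' counts rather than from raw records.
#'
#' @return List of two `data.table`s: `table1` (criterion counts by column
#'   population) and `cohort` (named totals).
#' @export
published_region_counts <- function() {
  dir <- system.file("extdata", package = "householdseg")
  t1 <- data.table::fread(file.path(dir, "region_criteria_counts.csv"))
  coh <- data.table::fread(file.path(dir, "region_cohort_counts.csv"))
  list(table1 = t1, cohort = coh)
}

#' Worked-example arithmetic on the published counts
#'
#' Recomputes, from the published numerator/denominator pairs: the segment
#' share of households with children (t1), the number of people living in
#' complex households (t2), and the complex-column percentages for
#' multi-service use (t3), lone parenthood (t4) and frequent A&E use (t5).
#'
#' @return Named list; each element has `value` (on the published scale)
#'   and `n` (the problem size used).
#' @export
worked_example_targets <- function() {
  counts <- published_region_counts()
  coh <- stats::setNames(counts$cohort$value, counts$cohort$quantity)
  t1d <- counts$table1
  cx <- function(crit) t1d[criterion == crit, complex_n]
  n_complex <- coh[["complex_households"]]
  list(
    t1 = list(value = pct_print(n_complex, coh[["households_with_children"]]),
              n = unname(coh[["households_with_children"]])),
    t2 = list(value = unname(coh[["complex_children"]] + coh[["complex_adults"]]),
              n = 2),
    t3 = list(value = pct_print(cx("multi_service"), n_complex),
              n = unname(n_complex)),
    t4 = list(value = pct_print(cx("lone_parent"), n_complex),
              n = unname(n_complex)),
    t5 = list(value = pct_print(cx("high_ae"), n_complex),
              n = unname(n_complex))
  )
}
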