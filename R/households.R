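## Household derivation from pseudonymised address identifiers.
##
## People sharing an address identifier constitute one household. Address
## groups larger than the configured maximum (default 10) are dropped
## wholesale as likely institutions (care homes, houses of multiple
## occupation); persons with no address identifier cannot be household-linked
## and are dropped. Both exclusions are counted in the run log attached to
## the result, never raised as errors.

#' Derive households from person records
#'
#' Groups persons by `household_id`. The result carries an `exclusions`
#' attribute with the counts of persons dropped for a missing household id
#' and of households (and their members) dropped for exceeding
#' `max_household_size`. Household deprivation is the mean of member
#' `imd_score`s; members of one address share an area score, so differing
#' member scores are counted in the log as discrepancies.
#'
#' @param persons Validated person `data.table`.
#' @param cfg A `hhseg_config`.
#' @return `data.table` with one row per retained household: `household_id`,
#'   `n_members`, `n_children`, `n_adults`, `imd_score`; attribute
#'   `exclusions` (named list of counts) and `members` (person to household
#'   map for retained persons).
#' @export
build_households <- function(persons, cfg) {
  persons <- data.table::as.data.table(persons)
  child_max <- cfg$thresholds$child_age_max
  no_hh <- is.na(persons$household_id) | persons$household_id == ""
  kept <- persons[!no_hh]
  sizes <- kept[, .N, by = household_id]
  oversize <- sizes[N > cfg$thresholds$max_household_size, household_id]
  kept <- kept[!household_id %in% oversize]
  hh <- kept[, .(
    n_members  = .N,
    n_children = sum(age <= child_max),
    n_adults   = sum(age > child_max),
    imd_score  = if (all(is.na(imd_score))) NA_real_ else
      mean(imd_score, na.rm = TRUE),
    imd_discrepant = data.table::uniqueN(imd_score[!is.na(imd_score)]) > 1L
  ), by = household_id]
  data.table::setorder(hh, household_id)
  exclusions <- list(
    n_missing_household_id = sum(no_hh),
    n_oversize_households  = length(oversize),
    n_oversize_persons     = nrow(persons) - sum(no_hh) - nrow(kept),
    n_imd_discrepant_households = sum(hh$imd_discrepant)
  )
  hh[, imd_discrepant := NULL]
  data.table::setattr(hh, "exclusions", exclusions)
  data.table::setattr(hh, "members",
                      kept[, .(person_id, household_id)][order(person_id)])
  hh[]
}

#' Restrict to households containing at least one child
#'
#' A child is any member aged `child_age_max` or younger (default 0-16
#' inclusive); the quantile population for the top-spend criterion and all
#' profiling outputs are defined over this cohort.
#'
#' @param households Output of [build_households()].
#' @param cfg A `hhseg_config`.
#' @return Subset of `households` with `n_children >= 1` (attributes
#'   preserved; `members` restricted to the cohort).
#' @export
households_with_children <- function(households, cfg) {
  out <- households[n_children >= 1L]
  members <- attr(households, "members")
  if (!is.null(members)) {
    data.table::setattr(out, "members",
                        members[household_id %in% out$household_id])
  }
  data.table::setattr(out, "exclusions", attr(households, "exclusions"))
  out[]
}
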