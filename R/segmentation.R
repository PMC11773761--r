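## The four-criterion complex-household classification.
##
## A household with children is in the complex segment iff all four hold at
## once:
##   C1  at least one adult with a physical long-term condition AND at least
##       one adult (possibly a different one) with a mental health condition;
##   C2  at least one child with a health or social problem (any condition
##       listed for adults, or a child-in-care marker);
##   C3  any indicator of social vulnerability: homelessness, frequent A&E
##       use (> threshold attendances by any member), substance abuse, lone
##       parenthood, a child in care, residence in the most deprived share
##       of the region, or use of >= 3 distinct care sectors;
##   C4  per-capita cost-weighted utilisation in the top quarter of all
##       households with children.

## person ids scoped to one role within the cohort
role_ids <- function(persons, cfg, role = c("adult", "child")) {
  role <- match.arg(role)
  cm <- cfg$thresholds$child_age_max
  if (role == "child") persons[age <= cm, person_id] else persons[age > cm, person_id]
}

## household_id -> has any member of `ids` carrying a code in `codes`
hh_any_code <- function(members, flags, ids, codes) {
  carriers <- unique(flags[condition_code %in% codes & person_id %in% ids,
                           person_id])
  unique(members[person_id %in% carriers, household_id])
}

#' Criterion 1: adult physical and mental comorbidity in the household
#'
#' True when some adult member carries a physical-set code and some adult
#' member (not necessarily the same person) carries a mental-set code.
#'
#' @param households Household table carrying a `members` attribute.
#' @param persons,flags Validated person and condition tables.
#' @param cfg A `hhseg_config`.
#' @return Logical vector aligned with `households` rows.
#' @export
eval_condition1 <- function(households, persons, flags, cfg) {
  members <- attr(households, "members")
  adults <- role_ids(persons, cfg, "adult")
  phys <- hh_any_code(members, flags, adults, cfg$physical_conditions)
  ment <- hh_any_code(members, flags, adults, cfg$mental_conditions)
  households$household_id %in% phys & households$household_id %in% ment
}

#' Criterion 2: a child with a health or social problem
#'
#' True when some child member carries a child-problem code (by default the
#' union of the adult physical and mental sets) or a child-in-care marker.
#'
#' @inheritParams eval_condition1
#' @return Logical vector aligned with `households` rows.
#' @export
eval_condition2 <- function(households, persons, flags, cfg) {
  members <- attr(households, "members")
  children <- role_ids(persons, cfg, "child")
  codes <- union(cfg$child_problem_conditions,
                 cfg$vulnerability_codes$child_in_care)
  hit <- hh_any_code(members, flags, children, codes)
  households$household_id %in% hit
}

#' Deprivation cutoff for the most-deprived share of the region
#'
#' Empirical threshold over the supplied households' deprivation scores
#' (higher = more deprived): the smallest score among the top
#' `deprivation_quantile` fraction by rank. Households at or above the
#' cutoff are flagged deprived. With too few scored households to isolate a
#' top fraction the cutoff is `Inf` (nobody flagged).
#'
#' @param households Household table (normally all built households, the
#'   "region").
#' @param cfg A `hhseg_config`.
#' @return Scalar cutoff.
#' @export
deprivation_cutoff <- function(households, cfg) {
  x <- households$imd_score
  x <- x[!is.na(x)]
  m <- floor(cfg$thresholds$deprivation_quantile * length(x))
  if (m < 1L) return(Inf)
  sort(x, decreasing = TRUE)[m]
}

#' Criterion 3: social vulnerability sub-flags
#'
#' Evaluates the seven vulnerability sub-flags per household; the criterion
#' is their disjunction. Households with a missing deprivation score take
#' `deprived = FALSE` (counted upstream in the run log).
#'
#' @inheritParams eval_condition1
#' @param contacts Validated contact table.
#' @param region_deprivation_cutoff Scalar from [deprivation_cutoff()].
#' @return `data.table` aligned with `households` rows: the seven sub-flags
#'   and `c3_vulnerability`.
#' @export
eval_condition3 <- function(households, persons, flags, contacts, cfg,
                            region_deprivation_cutoff) {
  members <- attr(households, "members")
  th <- cfg$thresholds
  all_ids <- members$person_id
  children <- role_ids(persons, cfg, "child")
  vc <- cfg$vulnerability_codes

  hid <- households$household_id
  homeless_hh <- hh_any_code(members, flags, all_ids, vc$homelessness)
  substance_hh <- hh_any_code(members, flags, all_ids, vc$substance_abuse)
  in_care_hh <- hh_any_code(members, flags, children, vc$child_in_care)

  ## frequent A&E: any member with strictly more than the threshold
  ae <- contacts[sector == "ae" & person_id %in% all_ids,
                 .(ae_visits = sum(n_contacts)), by = person_id]
  frequent <- ae[ae_visits > th$ae_visits_per_year, person_id]
  high_ae_hh <- unique(members[person_id %in% frequent, household_id])

  ## distinct-sector count over all members' contacts
  svc <- merge(contacts[person_id %in% all_ids, .(person_id, sector)],
               members, by = "person_id")
  nsvc <- svc[, .(n_sectors = data.table::uniqueN(sector)), by = household_id]
  multi_hh <- nsvc[n_sectors >= th$distinct_services_min, household_id]

  out <- data.table::data.table(
    homelessness    = hid %in% homeless_hh,
    high_ae         = hid %in% high_ae_hh,
    substance_abuse = hid %in% substance_hh,
    lone_parent     = households$n_adults == 1L & households$n_children >= 1L,
    child_in_care   = hid %in% in_care_hh,
    deprived        = !is.na(households$imd_score) &
      households$imd_score >= region_deprivation_cutoff,
    multi_service   = hid %in% multi_hh
  )
  out[, c3_vulnerability := homelessness | high_ae | substance_abuse |
        lone_parent | child_in_care | deprived | multi_service]
  out[]
}

## threshold for the top `frac` share of x by rank: the m-th largest value,
## m = floor(frac * n); ties at the threshold are included by the >= rule,
## so the flagged share is at most frac plus the tie mass at the threshold
top_share_threshold <- function(x, frac) {
  m <- floor(frac * length(x))
  if (m < 1L) {
    stop("quantile undefined: too few observations (n = ", length(x),
         ") to isolate a top ", format(frac), " share")
  }
  sort(x, decreasing = TRUE)[m]
}

#' Criterion 4: top share of per-capita spend
#'
#' True for households whose per-capita cost is at or above the empirical
#' threshold isolating the top `1 - spend_quantile` share of per-capita
#' costs over all households with children (nearest-rank, ties included).
#'
#' @param household_costs Output of [household_costs()] over the
#'   children-cohort households (the quantile population).
#' @param cfg A `hhseg_config`.
#' @return Logical vector aligned with `household_costs` rows; attribute
#'   `threshold` carries the cutoff.
#' @export
eval_condition4 <- function(household_costs, cfg) {
  thr <- top_share_threshold(household_costs$per_capita,
                             1 - cfg$thresholds$spend_quantile)
  structure(household_costs$per_capita >= thr, threshold = thr)
}

#' Classify households with children against the four criteria
#'
#' End-to-end segmentation: derives households, restricts to those with
#' children, evaluates criteria 1-4 and their conjunction. The deprivation
#' cutoff is computed over all retained households (the region); the spend
#' threshold over households with children only.
#'
#' @param persons,conditions,contacts Validated input tables.
#' @param cfg A `hhseg_config`.
#' @return `data.table`, one row per household with children: sizes,
#'   `per_capita`, `c1_adult_phys_and_mental`, `c2_child_problem`, the seven
#'   Criterion-3 sub-flags, `c3_vulnerability`, `c4_top_spend`,
#'   `in_segment`. Attributes: `members`, `exclusions`,
#'   `deprivation_cutoff`, `spend_threshold`, `spend_tie_mass` (share of
#'   cohort households tied exactly at the spend threshold).
#' @export
segment_households <- function(persons, conditions, contacts, cfg) {
  hh <- build_households(persons, cfg)
  hwc <- households_with_children(hh, cfg)
  dep_cut <- deprivation_cutoff(hh, cfg)
  person_costs <- cost_contacts(contacts, cfg)
  hcosts <- household_costs(hwc, person_costs)
  stopifnot(identical(hcosts$household_id, hwc$household_id))

  c1 <- eval_condition1(hwc, persons, conditions, cfg)
  c2 <- eval_condition2(hwc, persons, conditions, cfg)
  c3 <- eval_condition3(hwc, persons, conditions, contacts, cfg, dep_cut)
  c4 <- eval_condition4(hcosts, cfg)

  out <- data.table::data.table(
    household_id = hwc$household_id,
    n_members = hwc$n_members, n_children = hwc$n_children,
    n_adults = hwc$n_adults, imd_score = hwc$imd_score,
    per_capita = hcosts$per_capita,
    c1_adult_phys_and_mental = c1, c2_child_problem = c2)
  out <- cbind(out, c3)
  out[, c4_top_spend := as.logical(c4)]
  out[, in_segment := c1_adult_phys_and_mental & c2_child_problem &
        c3_vulnerability & c4_top_spend]
  thr <- attr(c4, "threshold")
  data.table::setattr(out, "members", attr(hwc, "members"))
  data.table::setattr(out, "exclusions", attr(hh, "exclusions"))
  data.table::setattr(out, "deprivation_cutoff", dep_cut)
  data.table::setattr(out, "spend_threshold", thr)
  data.table::setattr(out, "spend_tie_mass", mean(out$per_capita == thr))
  out[]
}
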