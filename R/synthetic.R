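## Synthetic linked-data generator.
##
## Emulates the joint structure the segmentation reads: household clustering
## of individuals, age-structured condition prevalence, mental-physical
## comorbidity within persons, sector-specific contact rates and costs, and
## a planted complex-household subpopulation for ground-truth recovery.
## Sampling order: household size -> member ages -> condition flags
## (bivariate Bernoulli with configured comorbidity log-odds) -> Poisson
## contacts per sector. Planted households satisfy Criteria 1-3 by
## construction (forced adult physical + mental flags, a forced child
## problem, and guaranteed contacts in three sectors) and receive a sector
## rate multiplier so that Criterion 4 emerges from the computed quantile
## rather than being planted directly.

#' Configuration for the synthetic generator
#'
#' Defaults describe a deliberately well-separated world: an 8% planted
#' complex fraction mirrors the published regional segment share; planted
#' households are larger (size conditioned on >= 3, mean about 4.2 vs 3.3),
#' have teen-skewed children, higher condition prevalence, and a six-fold
#' contact-rate multiplier.
#'
#' @param n_households Number of households to generate.
#' @param planted_complex_fraction Fraction of households planted as
#'   complex; a warning is issued when it exceeds the top-spend share
#'   `1 - spend_quantile`, since full recovery is then impossible by
#'   construction.
#' @param household_size_dist Probability vector over sizes 1..10.
#' @param child_fraction Probability a non-anchor member is a child.
#' @param adult_physical_prev,adult_mental_prev,child_problem_prev Named
#'   numeric `c(other=, planted=)` prevalence pairs.
#' @param comorbidity_log_odds Log odds ratio linking a person's physical
#'   and mental flags.
#' @param sector_rate_multiplier_complex Contact-rate multiplier (>= 1) for
#'   members of planted households.
#' @param planted_unmet_need_or Odds ratio of emergency mental-health
#'   attendance, planted vs other households, in the no-prior-contact
#'   stratum (used by [plant_unmet_need()]).
#' @param known_stratum_or Same contrast in the known-to-services stratum.
#' @param emergency_mh_p_no_prior,emergency_mh_p_known Baseline (other
#'   household) event probabilities per stratum.
#' @param spend_quantile Spend quantile the downstream segmentation will
#'   use; only read for the recovery warning.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A `hhseg_syncfg` list.
#' @export
synthetic_config <- function(n_households = 1000L,
                             planted_complex_fraction = 0.08,
                             household_size_dist = c(0.10, 0.18, 0.24, 0.26,
                                                     0.13, 0.05, 0.02, 0.01,
                                                     0.006, 0.004),
                             child_fraction = 0.45,
                             adult_physical_prev = c(other = 0.20, planted = 0.45),
                             adult_mental_prev   = c(other = 0.08, planted = 0.30),
                             child_problem_prev  = c(other = 0.08, planted = 0.35),
                             comorbidity_log_odds = 1.0,
                             sector_rate_multiplier_complex = 6,
                             planted_unmet_need_or = 6.8,
                             known_stratum_or = 2.0,
                             emergency_mh_p_no_prior = 0.02,
                             emergency_mh_p_known = 0.05,
                             spend_quantile = 0.75,
                             seed = 1L) {
  stopifnot(n_households >= 1,
            planted_complex_fraction >= 0, planted_complex_fraction <= 1,
            length(household_size_dist) == 10L,
            all(household_size_dist >= 0), sum(household_size_dist) > 0,
            all(adult_physical_prev >= 0 & adult_physical_prev <= 1),
            all(adult_mental_prev >= 0 & adult_mental_prev <= 1),
            all(child_problem_prev >= 0 & child_problem_prev <= 1),
            sector_rate_multiplier_complex >= 1,
            planted_unmet_need_or > 0)
  if (planted_complex_fraction > 1 - spend_quantile) {
    warning("planted_complex_fraction (", planted_complex_fraction,
            ") exceeds the top-spend share ", 1 - spend_quantile,
            ": full recovery is impossible by construction")
  }
  structure(list(
    n_households = as.integer(n_households),
    planted_complex_fraction = planted_complex_fraction,
    household_size_dist = household_size_dist / sum(household_size_dist),
    child_fraction = child_fraction,
    adult_physical_prev = adult_physical_prev,
    adult_mental_prev = adult_mental_prev,
    child_problem_prev = child_problem_prev,
    comorbidity_log_odds = comorbidity_log_odds,
    sector_rate_multiplier_complex = sector_rate_multiplier_complex,
    planted_unmet_need_or = planted_unmet_need_or,
    known_stratum_or = known_stratum_or,
    emergency_mh_p_no_prior = emergency_mh_p_no_prior,
    emergency_mh_p_known = emergency_mh_p_known,
    spend_quantile = spend_quantile,
    seed = as.integer(seed)
  ), class = "hhseg_syncfg")
}

## joint (physical, mental) Bernoulli cell probability P(1,1) with marginals
## p1, p2 and odds ratio psi (Plackett construction)
joint_p11 <- function(p1, p2, psi) {
  if (abs(psi - 1) < 1e-12) return(p1 * p2)
  s <- 1 + (p1 + p2) * (psi - 1)
  (s - sqrt(s^2 - 4 * psi * (psi - 1) * p1 * p2)) / (2 * (psi - 1))
}

## per-sector annual base contact rates (multiplied for planted households)
base_rates <- function() {
  c(primary_care = 2.5, ae = 0.25, inpatient = 0.08, outpatient = 0.6,
    mental_health = 0.15, community = 0.35, adult_social_care = 0.03,
    children_social_care = 0.02)
}

physical_code_weights <- function() c(
  asthma = 0.40, diabetes = 0.08, cardiovascular_disease = 0.08,
  epilepsy = 0.07, copd = 0.05, cancer = 0.05, chronic_kidney_disease = 0.05,
  chronic_liver_disease = 0.05, gastroenterological = 0.06,
  neurological = 0.04, rheumatological = 0.04, dementia = 0.01,
  physical_disability = 0.02)

mental_code_weights <- function() c(
  anxiety = 0.35, depression = 0.35, severe_mental_illness = 0.08,
  neurodevelopmental = 0.12, learning_disability = 0.10)

child_code_weights <- function() c(
  asthma = 0.45, epilepsy = 0.08, neurodevelopmental = 0.20,
  learning_disability = 0.07, anxiety = 0.10, depression = 0.10)

mh_reason_weights <- function() c(
  anxiety = 0.30, mental_health = 0.20, crisis = 0.15, self_harm = 0.10,
  neurodevelopmental = 0.15, eating_disorder = 0.10)

#' Generate a synthetic linked population
#'
#' @param cfg A [synthetic_config()].
#' @return Named list: `persons`, `conditions`, `contacts` (schema-valid
#'   `data.table`s accepted by the validators), and `truth`
#'   (`household_id`, `planted`, `n_members`, `n_children`).
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "hhseg_syncfg"))
  set.seed(cfg$seed)
  nh <- cfg$n_households
  hid <- sprintf("h%06d", seq_len(nh))
  n_planted <- round(cfg$planted_complex_fraction * nh)
  planted <- seq_len(nh) %in% sample.int(nh, n_planted)

  ## sizes: planted households drawn conditionally on size >= 3
  sizes <- sample(1:10, nh, replace = TRUE, prob = cfg$household_size_dist)
  if (n_planted) {
    pd <- cfg$household_size_dist
    pd[1:2] <- 0
    if (sum(pd) > 0) {
      sizes[planted] <- sample(1:10, n_planted, replace = TRUE, prob = pd)
    } else {
      sizes[planted] <- 3L
    }
  }

  ## composition: every household keeps >= 1 adult; planted keep >= 1 child
  n_children <- stats::rbinom(nh, pmax(sizes - 1L, 0L), cfg$child_fraction)
  if (n_planted) {
    n_children[planted] <- 1L +
      stats::rbinom(n_planted, pmax(sizes[planted] - 2L, 0L), cfg$child_fraction)
  }
  n_adults <- sizes - n_children

  ## household-level deprivation: Beta tuned to mean 0.20, sd 0.16 for
  ## ordinary households and mean 0.25 for planted ones
  imd <- stats::rbeta(nh, 1.05, 4.20)
  if (n_planted) imd[planted] <- stats::rbeta(n_planted, 1.58, 4.74)
  imd <- round(imd, 4)

  ## --- person rows -----------------------------------------------------
  hh_idx <- rep(seq_len(nh), sizes)
  np <- length(hh_idx)
  is_child <- sequence(sizes) <= n_children[hh_idx]
  age <- integer(np)
  kid <- which(is_child)
  kid_planted <- kid[planted[hh_idx[kid]]]
  kid_other <- setdiff(kid, kid_planted)
  age[kid_other] <- sample(0:16, length(kid_other), replace = TRUE)
  age[kid_planted] <- sample(0:16, length(kid_planted), replace = TRUE,
                             prob = (0:16) + 4)  # teen-skewed
  ad <- which(!is_child)
  age[ad] <- sample(17:90, length(ad), replace = TRUE,
                    prob = exp(-(0:73) / 25))
  sex <- sample(c("M", "F"), np, replace = TRUE, prob = c(0.51, 0.49))
  ethnicity <- sample(c("white", "asian", "black", "mixed", "other"), np,
                      replace = TRUE, prob = c(0.90, 0.04, 0.03, 0.02, 0.01))
  persons <- data.table::data.table(
    person_id = sprintf("p%07d", seq_len(np)),
    household_id = hid[hh_idx], age = age, sex = sex, ethnicity = ethnicity,
    imd_score = imd[hh_idx], registered = TRUE)
  p_planted <- planted[hh_idx]

  ## --- condition flags --------------------------------------------------
  cond_person <- character(0)
  cond_code <- character(0)
  add_flags <- function(ids, codes) {
    cond_person <<- c(cond_person, ids)
    cond_code <<- c(cond_code, codes)
  }

  ## adults: bivariate Bernoulli (physical, mental)
  for (grp in c("other", "planted")) {
    sel <- ad[p_planted[ad] == (grp == "planted")]
    if (!length(sel)) next
    p1 <- cfg$adult_physical_prev[[grp]]
    p2 <- cfg$adult_mental_prev[[grp]]
    p11 <- joint_p11(p1, p2, exp(cfg$comorbidity_log_odds))
    cell <- sample(c("both", "phys", "ment", "none"), length(sel),
                   replace = TRUE,
                   prob = c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11))
    phys_ids <- persons$person_id[sel[cell %in% c("both", "phys")]]
    ment_ids <- persons$person_id[sel[cell %in% c("both", "ment")]]
    pw <- physical_code_weights(); mw <- mental_code_weights()
    add_flags(phys_ids, sample(names(pw), length(phys_ids), TRUE, prob = pw))
    add_flags(ment_ids, sample(names(mw), length(ment_ids), TRUE, prob = mw))
  }

  ## children: problem flag
  for (grp in c("other", "planted")) {
    sel <- kid[p_planted[kid] == (grp == "planted")]
    if (!length(sel)) next
    hit <- sel[stats::runif(length(sel)) < cfg$child_problem_prev[[grp]]]
    cw <- child_code_weights()
    add_flags(persons$person_id[hit],
              sample(names(cw), length(hit), TRUE, prob = cw))
  }

  ## vulnerability markers
  sa <- ad[stats::runif(length(ad)) <
             data.table::fifelse(p_planted[ad], 0.12, 0.02)]
  add_flags(persons$person_id[sa], rep("substance_abuse", length(sa)))
  hl <- which(stats::runif(np) < data.table::fifelse(p_planted, 0.001, 0.0002))
  add_flags(persons$person_id[hl], rep("homelessness", length(hl)))
  cc <- kid[stats::runif(length(kid)) <
              data.table::fifelse(p_planted[kid], 0.04, 0.002)]
  add_flags(persons$person_id[cc], rep("child_in_care", length(cc)))

  ## planted forcing: guarantee Criteria 1 and 2 hold (planted households
  ## always contain >= 1 adult and >= 1 child by construction)
  if (n_planted) {
    planted_hid <- hid[planted]
    ## households among planted already holding a code of `codeset` carried
    ## by a member drawn from `pool` (person row indices)
    covered <- function(codeset, pool) {
      carriers <- cond_person[cond_code %in% codeset]
      idx <- intersect(match(unique(carriers), persons$person_id), pool)
      intersect(unique(persons$household_id[idx]), planted_hid)
    }
    ## first pool member of each household in `want`
    pick_one <- function(want, pool) {
      f <- pool[!duplicated(persons$household_id[pool])]
      f[match(want, persons$household_id[f])]
    }
    ad_planted <- ad[p_planted[ad]]
    kid_planted_pool <- kid[p_planted[kid]]
    force_one <- function(codeset, pool, code) {
      lack <- setdiff(planted_hid, covered(codeset, pool))
      sel <- pick_one(lack, pool)
      add_flags(persons$person_id[sel], rep(code, length(sel)))
    }
    force_one(default_physical_conditions(), ad_planted, "asthma")
    force_one(default_mental_conditions(), ad_planted, "depression")
    force_one(c(default_physical_conditions(), default_mental_conditions(),
                "child_in_care"), kid_planted_pool, "asthma")
  }

  conditions <- data.table::data.table(person_id = cond_person,
                                       condition_code = cond_code)
  conditions <- unique(conditions)
  data.table::setorder(conditions, person_id, condition_code)

  ## --- contacts ---------------------------------------------------------
  has_mental <- persons$person_id %in%
    conditions[condition_code %in% default_mental_conditions(), person_id]
  in_care <- persons$person_id %in%
    conditions[condition_code == "child_in_care", person_id]
  mult <- data.table::fifelse(p_planted,
                              cfg$sector_rate_multiplier_complex, 1)
  rates <- base_rates()
  rows <- vector("list", 16L)
  k <- 0L
  add_rows <- function(pid, sec, reason, emerg, n) {
    keep <- n > 0L
    if (!any(keep)) return(invisible())
    k <<- k + 1L
    rows[[k]] <<- data.table::data.table(
      person_id = pid[keep], sector = sec, reason_class = reason[keep],
      emergency = emerg, n_contacts = n[keep],
      unit_cost_override = NA_real_)
  }
  for (sec in hh_sectors()) {
    lam <- rates[[sec]] * mult
    if (sec == "adult_social_care") lam[is_child] <- 0
    if (sec == "children_social_care") {
      lam[!is_child] <- 0
      lam[in_care] <- 6 * mult[in_care]   # state-care funding dominates
    }
    if (sec == "mental_health") lam <- lam + 1.2 * has_mental * mult
    n <- stats::rpois(np, lam)
    if (sec == "ae") {
      ## mental-health A&E presentations, concentrated in teenage girls
      ## of planted households
      p_mh <- data.table::fifelse(
        p_planted & persons$sex == "F" & persons$age >= 12 &
          persons$age <= 16, 0.45, 0.08)
      n_mh <- stats::rbinom(np, n, p_mh)
      add_rows(persons$person_id, sec, rep("mental_health", np), TRUE, n_mh)
      add_rows(persons$person_id, sec, rep("physical", np), TRUE, n - n_mh)
    } else if (sec == "inpatient") {
      n_em <- stats::rbinom(np, n, 0.5)
      add_rows(persons$person_id, sec, rep("physical", np), TRUE, n_em)
      add_rows(persons$person_id, sec, rep("physical", np), FALSE, n - n_em)
    } else if (sec == "mental_health") {
      w <- mh_reason_weights()
      reason <- sample(names(w), np, replace = TRUE, prob = w)
      add_rows(persons$person_id, sec, reason, FALSE, n)
    } else {
      reason <- rep(if (sec %in% c("community", "adult_social_care",
                                   "children_social_care")) "other"
                    else "physical", np)
      add_rows(persons$person_id, sec, reason, FALSE, n)
    }
  }
  ## deterministic Criterion-3 guarantee: every planted household uses at
  ## least three distinct sectors
  if (n_planted) {
    anchor <- persons$person_id[!duplicated(persons$household_id) & p_planted]
    for (sec in c("primary_care", "community", "mental_health")) {
      reason <- rep(if (sec == "mental_health") "mental_health" else "other",
                    length(anchor))
      add_rows(anchor, sec, reason, FALSE, rep(1L, length(anchor)))
    }
  }
  contacts <- data.table::rbindlist(rows[seq_len(k)])
  contacts <- contacts[, .(n_contacts = sum(n_contacts)),
                       by = .(person_id, sector, reason_class, emergency)]
  contacts[, unit_cost_override := NA_real_]
  data.table::setorder(contacts, person_id, sector, reason_class, emergency)
  data.table::setcolorder(contacts, c("person_id", "sector", "reason_class",
                                      "emergency", "n_contacts",
                                      "unit_cost_override"))

  truth <- data.table::data.table(household_id = hid, planted = planted,
                                  n_members = sizes, n_children = n_children)
  list(persons = persons, conditions = conditions, contacts = contacts,
       truth = truth)
}

#' Plant a two-stratum unmet-need contrast
#'
#' Replaces the population's emergency mental-health attendance structure
#' with a two-stratum Bernoulli model. A person's stratum is derived from
#' the generated data itself (known to services = any mental-condition flag
#' or any non-emergency mental-health sector contact); within the
#' no-prior-contact stratum the odds of an emergency mental-health
#' attendance are `planted_unmet_need_or` times higher for members of
#' planted households than for others, and `known_stratum_or` times higher
#' in the known stratum. Pre-existing emergency rows with mental-health
#' reasons are relabelled `physical` so the planted odds ratio is exact.
#'
#' @param pop Output of [generate_population()].
#' @param cfg The [synthetic_config()] used to generate `pop`.
#' @return Named list: `contacts` (augmented table) and `person_strata`
#'   (truth per cohort person: `person_id`, `complex`, `prior`, `event`).
#' @export
plant_unmet_need <- function(pop, cfg) {
  stopifnot(inherits(cfg, "hhseg_syncfg"))
  set.seed(cfg$seed + 1L)   # own stream: planting is reproducible whatever
                            # ran between generation and planting
  contacts <- data.table::copy(pop$contacts)
  mh_reasons <- c("mental_health", "anxiety", "crisis", "self_harm",
                  "eating_disorder", "neurodevelopmental")
  contacts[emergency & reason_class %in% mh_reasons,
           reason_class := "physical"]
  ## cohort: members of households with at least one child (0-16)
  child_hh <- unique(pop$persons[age <= 16, household_id])
  cohort <- pop$persons[household_id %in% child_hh,
                        .(person_id, household_id)]
  cohort[, complex := household_id %in% pop$truth[planted == TRUE, household_id]]
  prior_ids <- union(
    pop$conditions[condition_code %in% default_mental_conditions(), person_id],
    pop$contacts[sector == "mental_health" & !emergency, person_id])
  cohort[, prior := person_id %in% prior_ids]

  p_event <- function(base, or, exposed) {
    odds <- base / (1 - base) * ifelse(exposed, or, 1)
    odds / (1 + odds)
  }
  p <- ifelse(cohort$prior,
              p_event(cfg$emergency_mh_p_known, cfg$known_stratum_or,
                      cohort$complex),
              p_event(cfg$emergency_mh_p_no_prior, cfg$planted_unmet_need_or,
                      cohort$complex))
  cohort[, event := stats::runif(.N) < p]
  ev <- cohort[event == TRUE]
  if (nrow(ev)) {
    contacts <- data.table::rbindlist(list(contacts, data.table::data.table(
      person_id = ev$person_id, sector = "ae", reason_class = "mental_health",
      emergency = TRUE, n_contacts = 1L, unit_cost_override = NA_real_)))
  }
  data.table::setorder(contacts, person_id, sector, reason_class, emergency)
  list(contacts = contacts,
       person_strata = cohort[, .(person_id, complex, prior, event)])
}

#' Write a generated population to a directory
#' @param pop Output of [generate_population()].
#' @param dir Output directory (created if absent).
#' @return Paths of the four CSVs, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("persons.csv", "conditions.csv", "contacts.csv",
                            "truth.csv"))
  write_table(pop$persons, paths[1]); write_table(pop$conditions, paths[2])
  write_table(pop$contacts, paths[3]); write_table(pop$truth, paths[4])
  invisible(paths)
}
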