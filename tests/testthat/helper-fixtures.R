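# Hand-rolled fixture builders. Deliberately plain (no generator reuse) so
# oracle-equivalence fixtures are not tied to the synthetic module's
# structure.

fx_persons <- function(person_id, household_id, age,
                       sex = rep("F", length(person_id)),
                       ethnicity = rep("white", length(person_id)),
                       imd_score = rep(0.3, length(person_id)),
                       registered = TRUE) {
  data.table::data.table(person_id = person_id, household_id = household_id,
                         age = as.integer(age), sex = sex,
                         ethnicity = ethnicity, imd_score = imd_score,
                         registered = registered)
}

fx_conditions <- function(person_id = character(), condition_code = character()) {
  data.table::data.table(person_id = person_id,
                         condition_code = condition_code)
}

fx_contacts <- function(person_id = character(), sector = character(),
                        reason_class = rep("physical", length(person_id)),
                        emergency = rep(FALSE, length(person_id)),
                        n_contacts = rep(1L, length(person_id)),
                        unit_cost_override = rep(NA_real_, length(person_id))) {
  data.table::data.table(person_id = person_id, sector = sector,
                         reason_class = reason_class, emergency = emergency,
                         n_contacts = as.integer(n_contacts),
                         unit_cost_override = unit_cost_override)
}

# a deliberately rich hand-built population: 6 households covering the
# criteria combinations, used by several suites
fx_small_population <- function() {
  persons <- fx_persons(
    person_id    = sprintf("p%02d", 1:19),
    household_id = c("h1","h1","h1","h1",      # 2 adults, 2 children
                     "h2","h2",                # lone parent + child
                     "h3","h3","h3",           # 2 adults, 1 child
                     "h4","h4",                # 2 adults, no children
                     "h5","h5","h5",           # 1 adult, 2 children
                     "h6","h6","h6","h6","h6"),# 2 adults, 3 children
    age = c(40, 38, 10, 14,
            29, 3,
            45, 44, 16,
            30, 34,
            52, 8, 12,
            41, 39, 2, 6, 15),
    sex = c("M","F","M","F", "F","M", "M","F","F", "M","F",
            "F","M","F", "M","F","F","M","F"),
    imd_score = c(rep(0.80, 4), rep(0.10, 2), rep(0.40, 3), rep(0.20, 2),
                  rep(0.55, 3), rep(0.05, 5)))
  conditions <- fx_conditions(
    person_id = c("p01", "p02", "p03",           # h1: phys+mental adults, child problem
                  "p05",                          # h2 adult mental only
                  "p07", "p07", "p09",            # h3: one adult both, child in care
                  "p10",                          # h4 adult phys (no children)
                  "p12",                          # h5 adult phys only
                  "p15", "p16", "p17"),           # h6 adults phys+mental, child asthma
    condition_code = c("asthma", "depression", "epilepsy",
                       "anxiety",
                       "diabetes", "severe_mental_illness", "child_in_care",
                       "copd",
                       "cancer",
                       "rheumatological", "depression", "asthma"))
  contacts <- fx_contacts(
    person_id = c("p01", "p01", "p02", "p03",    # h1 heavy multi-sector use
                  "p05",
                  "p07", "p09", "p09",
                  "p10",
                  "p12",
                  "p15", "p16"),
    sector = c("primary_care", "mental_health", "community", "ae",
               "primary_care",
               "primary_care", "children_social_care", "ae",
               "outpatient",
               "primary_care",
               "primary_care", "ae"),
    reason_class = c("physical", "anxiety", "other", "mental_health",
                     "physical",
                     "physical", "other", "physical",
                     "physical",
                     "physical",
                     "physical", "physical"),
    emergency = c(FALSE, FALSE, FALSE, TRUE,
                  FALSE,
                  FALSE, FALSE, TRUE,
                  FALSE,
                  FALSE,
                  FALSE, TRUE),
    n_contacts = c(4L, 6L, 2L, 7L,
                   1L,
                   2L, 12L, 2L,
                   3L,
                   1L,
                   2L, 1L))
  list(persons = persons, conditions = conditions, contacts = contacts)
}

# fully random schema-valid population for oracle-equivalence sweeps
fx_random_population <- function(n_households, seed) {
  set.seed(seed)
  cfg <- default_config()
  hid <- sprintf("rh%03d", seq_len(n_households))
  sizes <- sample(1:12, n_households, replace = TRUE,
                  prob = c(0.1, 0.2, 0.2, 0.2, 0.1, 0.08, 0.05, 0.03,
                           0.02, 0.01, 0.005, 0.005))
  hh <- rep(hid, sizes)
  # a few persons lack a household id entirely
  hh[sample(length(hh), max(1, length(hh) %/% 20))] <- NA_character_
  np <- length(hh)
  persons <- fx_persons(
    person_id = sprintf("rp%04d", seq_len(np)),
    household_id = hh,
    age = sample(0:90, np, replace = TRUE),
    sex = sample(c("M", "F", "unknown"), np, TRUE, prob = c(.48, .48, .04)),
    imd_score = ifelse(stats::runif(np) < 0.1, NA_real_,
                       round(stats::runif(np), 3)))
  # household-level imd consistency not enforced: the builder averages
  codes <- all_codes(cfg)
  nflag <- stats::rpois(1, np * 0.8)
  conditions <- fx_conditions(
    person_id = sample(persons$person_id, nflag, replace = TRUE),
    condition_code = sample(codes, nflag, replace = TRUE))
  ncon <- stats::rpois(1, np * 1.5)
  sector <- sample(hh_sectors(), ncon, replace = TRUE)
  contacts <- fx_contacts(
    person_id = sample(persons$person_id, ncon, replace = TRUE),
    sector = sector,
    reason_class = sample(c("physical", "mental_health", "anxiety", "crisis",
                            "other"), ncon, replace = TRUE),
    emergency = sector %in% c("ae", "inpatient") & stats::runif(ncon) < 0.5,
    n_contacts = 1L + stats::rpois(ncon, 1.2),
    unit_cost_override = ifelse(stats::runif(ncon) < 0.05,
                                round(stats::runif(ncon, 0, 500), 2),
                                NA_real_))
  list(persons = persons, conditions = unique(conditions),
       contacts = contacts)
}
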