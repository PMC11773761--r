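cfg <- default_config()

seg_of <- function(pop, cfg2 = cfg) {
  segment_households(pop$persons, pop$conditions, pop$contacts, cfg2)
}

test_that("criterion 1 accepts physical and mental flags on different adults", {
  pop <- fx_small_population()
  seg <- seg_of(pop)
  # h1: adult p01 asthma, adult p02 depression
  expect_true(seg[household_id == "h1", c1_adult_phys_and_mental])
  # h3: one adult carries both
  expect_true(seg[household_id == "h3", c1_adult_phys_and_mental])
  # h5: adult physical only
  expect_false(seg[household_id == "h5", c1_adult_phys_and_mental])
  # h2: adult mental only
  expect_false(seg[household_id == "h2", c1_adult_phys_and_mental])
})

test_that("criterion 1 ignores flagged children", {
  persons <- fx_persons(c("a", "k"), c("h1", "h1"), c(40, 10))
  conditions <- fx_conditions(c("k", "k"), c("asthma", "depression"))
  hh <- build_households(persons, cfg)
  expect_false(eval_condition1(hh, persons, conditions, cfg))
  expect_true(eval_condition2(hh, persons, conditions, cfg))
})

test_that("criterion 1 equals exhaustive enumeration on a toy taxonomy", {
  # two adults, each independently carrying any subset of 4 codes
  toy <- default_config(physical_conditions = c("px1", "px2"),
                        mental_conditions = c("mx1", "mx2"))
  codes <- c("px1", "px2", "mx1", "mx2")
  subsets <- lapply(0:15, function(m) codes[bitwAnd(m, 2^(0:3)) > 0])
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      persons <- fx_persons(c("a1", "a2", "k"), rep("hh", 3), c(40, 41, 5))
      conditions <- fx_conditions(
        c(rep("a1", length(subsets[[i]])), rep("a2", length(subsets[[j]]))),
        c(subsets[[i]], subsets[[j]]))
      got <- eval_condition1(
        build_households(persons, toy), persons, conditions, toy)
      want <- any(c(subsets[[i]], subsets[[j]]) %in% c("px1", "px2")) &&
              any(c(subsets[[i]], subsets[[j]]) %in% c("mx1", "mx2"))
      expect_identical(got, want)
    }
  }
})

test_that("criterion 2: child problem flag or in-care marker", {
  pop <- fx_small_population()
  seg <- seg_of(pop)
  expect_true(seg[household_id == "h1", c2_child_problem])   # child epilepsy
  expect_true(seg[household_id == "h3", c2_child_problem])   # child in care
  expect_false(seg[household_id == "h5", c2_child_problem])  # healthy children
  expect_true(seg[household_id == "h6", c2_child_problem])   # child asthma
})

test_that("criterion 3 sub-flags follow their definitions", {
  pop <- fx_small_population()
  seg <- seg_of(pop)
  # h2 and h5: exactly one adult living with children
  expect_true(seg[household_id == "h2", lone_parent])
  expect_true(seg[household_id == "h5", lone_parent])
  expect_false(seg[household_id == "h1", lone_parent])
  # h1 child p03 has 7 A&E attendances (> 5); h3 member has 2
  expect_true(seg[household_id == "h1", high_ae])
  expect_false(seg[household_id == "h3", high_ae])
  # h1 uses 4 sectors; h2 only primary care
  expect_true(seg[household_id == "h1", multi_service])
  expect_false(seg[household_id == "h2", multi_service])
  expect_true(seg[household_id == "h3", child_in_care])
  expect_true(seg[household_id == "h2", c3_vulnerability])   # via lone parent
})

test_that("frequent-A&E threshold is strictly greater-than", {
  persons <- fx_persons(sprintf("a%d", 1:8),
                        rep(sprintf("h%d", 1:4), each = 2),
                        rep(c(40, 5), 4))
  mk <- function(n) rbind(
    fx_contacts("a1", "ae", emergency = TRUE, n_contacts = n),
    fx_contacts("a3", "primary_care"))
  seg5 <- segment_households(persons, fx_conditions(), mk(5L), cfg)
  seg6 <- segment_households(persons, fx_conditions(), mk(6L), cfg)
  expect_false(seg5[household_id == "h1", high_ae])
  expect_true(seg6[household_id == "h1", high_ae])
})

test_that("multi-service needs three distinct sectors, not three contacts", {
  persons <- fx_persons(sprintf("a%d", 1:8),
                        rep(sprintf("h%d", 1:4), each = 2),
                        rep(c(40, 5), 4))
  c1 <- rbind(
    fx_contacts(rep("a1", 3), c("primary_care", "community", "mental_health"),
                reason_class = c("physical", "other", "anxiety")),
    fx_contacts("a3", "primary_care", n_contacts = 9L))
  seg <- segment_households(persons, fx_conditions(), c1, cfg)
  expect_true(seg[household_id == "h1", multi_service])
  expect_false(seg[household_id == "h2", multi_service])
})

test_that("deprivation flag uses the empirical top-quintile cutoff", {
  # 10 single-adult-plus-child households with distinct scores
  persons <- fx_persons(
    sprintf("a%02d", 1:20),
    rep(sprintf("h%02d", 1:10), each = 2),
    rep(c(30, 5), 10),
    imd_score = rep(seq(0.05, 0.95, by = 0.1), each = 2))
  seg <- segment_households(persons, fx_conditions(),
                            fx_contacts("a01", "primary_care"), cfg)
  # top 20% of 10 households = 2 most deprived (scores 0.85, 0.95)
  expect_equal(sum(seg$deprived), 2L)
  expect_setequal(seg[deprived == TRUE, household_id], c("h09", "h10"))
})

test_that("top-spend rule: nearest rank, ties included, small-n error", {
  # four lone-parent households with per-capita costs 1,2,3,4
  persons <- fx_persons(sprintf("a%d", 1:8),
                        rep(sprintf("h%d", 1:4), each = 2),
                        rep(c(30, 5), 4))
  contacts <- fx_contacts(sprintf("a%d", c(1, 3, 5, 7)), rep("ae", 4),
                          emergency = TRUE,
                          unit_cost_override = c(2, 4, 6, 8))  # pc 1,2,3,4
  seg <- segment_households(persons, fx_conditions(), contacts, cfg)
  expect_identical(seg[c4_top_spend == TRUE, household_id], "h4")
  # all identical costs: everyone ties at the threshold
  contacts2 <- fx_contacts(sprintf("a%d", c(1, 3, 5, 7)), rep("ae", 4),
                           emergency = TRUE, unit_cost_override = rep(6, 4))
  seg2 <- segment_households(persons, fx_conditions(), contacts2, cfg)
  expect_true(all(seg2$c4_top_spend))
  expect_equal(attr(seg2, "spend_tie_mass"), 1)
  # fewer than four cohort households: quantile undefined
  expect_error(
    segment_households(persons[1:6], fx_conditions(), contacts[1:3], cfg),
    "quantile undefined")
})

test_that("in_segment is the conjunction and dropping criteria only enlarges", {
  pop <- fx_random_population(60, seed = 51)
  seg <- seg_of(pop)
  expect_identical(seg$in_segment,
                   seg$c1_adult_phys_and_mental & seg$c2_child_problem &
                     seg$c3_vulnerability & seg$c4_top_spend)
  for (drop in list(c("c1_adult_phys_and_mental"), c("c2_child_problem"),
                    c("c3_vulnerability"), c("c4_top_spend"))) {
    kept <- setdiff(c("c1_adult_phys_and_mental", "c2_child_problem",
                      "c3_vulnerability", "c4_top_spend"), drop)
    relaxed <- Reduce(`&`, lapply(kept, function(cn) seg[[cn]]))
    expect_true(all(seg$in_segment <= relaxed))
  }
})

test_that("segment share is bounded by the top-spend share plus tie mass", {
  for (s in c(61, 62, 63)) {
    pop <- fx_random_population(50, seed = s)
    seg <- seg_of(pop)
    bound <- (1 - cfg$thresholds$spend_quantile) + attr(seg, "spend_tie_mass")
    expect_lte(mean(seg$in_segment), bound + 1e-12)
    expect_lte(mean(seg$c4_top_spend), bound + 1e-12)
  }
})

test_that("segmentation is invariant to input row order", {
  pop <- fx_random_population(40, seed = 71)
  seg1 <- seg_of(pop)
  set.seed(2)
  pop2 <- list(persons = pop$persons[sample(nrow(pop$persons))],
               conditions = pop$conditions[sample(nrow(pop$conditions))],
               contacts = pop$contacts[sample(nrow(pop$contacts))])
  seg2 <- seg_of(pop2)
  expect_equal(as.data.frame(seg1), as.data.frame(seg2))
})

test_that("vectorised segmentation equals the brute-force oracle", {
  for (s in c(101, 102, 103, 104)) {
    pop <- fx_random_population(8L + (s %% 13L), seed = s)
    seg <- tryCatch(seg_of(pop), error = function(e) e)
    orc <- tryCatch(oracle_segment(pop$persons, pop$conditions,
                                   pop$contacts, cfg),
                    error = function(e) e)
    if (inherits(seg, "error") || inherits(orc, "error")) {
      # both paths must refuse identically (undefined quantile)
      expect_true(inherits(seg, "error") && inherits(orc, "error"))
      next
    }
    expect_identical(seg$household_id, orc$household_id)
    expect_identical(seg$c1_adult_phys_and_mental, orc$c1)
    expect_identical(seg$c2_child_problem, orc$c2)
    expect_identical(seg$c3_vulnerability, orc$c3)
    expect_identical(seg$c4_top_spend, orc$c4)
    expect_equal(seg$per_capita, orc$per_capita)
    expect_identical(seg$in_segment, orc$in_segment)
    for (f in c("homelessness", "high_ae", "substance_abuse", "lone_parent",
                "child_in_care", "deprived", "multi_service")) {
      expect_identical(seg[[f]], orc[[f]])
    }
  }
})
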