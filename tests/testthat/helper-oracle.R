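# Brute-force oracles: plain-loop re-readings of the definitions, kept
# independent of the vectorised implementation they check.

oracle_person_costs <- function(contacts, cfg) {
  tariffs <- unlist(cfg$tariffs)
  out <- list()
  for (i in seq_len(nrow(contacts))) {
    r <- as.list(contacts[i, ])
    unit <- if (!is.na(r$unit_cost_override)) r$unit_cost_override
            else tariffs[[r$sector]]
    key <- r$person_id
    if (is.null(out[[key]])) out[[key]] <- stats::setNames(
      rep(0, length(hh_sectors())), hh_sectors())
    out[[key]][[r$sector]] <- out[[key]][[r$sector]] + r$n_contacts * unit
  }
  out
}

# literal per-household evaluation of the four-criterion definition
oracle_segment <- function(persons, conditions, contacts, cfg) {
  th <- cfg$thresholds
  persons <- as.data.frame(persons)
  conditions <- as.data.frame(conditions)
  contacts <- as.data.frame(contacts)
  keep <- !is.na(persons$household_id) & persons$household_id != ""
  persons <- persons[keep, ]
  counts <- table(persons$household_id)
  ok_hh <- names(counts)[counts <= th$max_household_size]
  persons <- persons[persons$household_id %in% ok_hh, ]

  codes_of <- function(pid) conditions$condition_code[conditions$person_id == pid]
  is_child <- function(pid) persons$age[persons$person_id == pid] <= th$child_age_max

  # deprivation cutoff over ALL retained households (mean member score)
  hh_imd <- sapply(ok_hh, function(h) {
    v <- persons$imd_score[persons$household_id == h]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  scored <- sort(hh_imd[!is.na(hh_imd)], decreasing = TRUE)
  m <- floor(th$deprivation_quantile * length(scored))
  dep_cut <- if (m < 1) Inf else scored[m]

  person_costs <- oracle_person_costs(contacts, cfg)
  child_codes <- union(cfg$child_problem_conditions,
                       cfg$vulnerability_codes$child_in_care)

  rows <- list()
  for (h in ok_hh) {
    mem <- persons$person_id[persons$household_id == h]
    kids <- mem[sapply(mem, is_child)]
    adults <- setdiff(mem, kids)
    if (length(kids) == 0) next
    c1 <- any(sapply(adults, function(p)
            any(codes_of(p) %in% cfg$physical_conditions))) &&
          any(sapply(adults, function(p)
            any(codes_of(p) %in% cfg$mental_conditions)))
    c2 <- any(sapply(kids, function(p) any(codes_of(p) %in% child_codes)))
    ae_per <- sapply(mem, function(p)
      sum(contacts$n_contacts[contacts$person_id == p &
                                contacts$sector == "ae"]))
    sub <- list(
      homelessness = any(sapply(mem, function(p)
        any(codes_of(p) %in% cfg$vulnerability_codes$homelessness))),
      high_ae = any(ae_per > th$ae_visits_per_year),
      substance_abuse = any(sapply(mem, function(p)
        any(codes_of(p) %in% cfg$vulnerability_codes$substance_abuse))),
      lone_parent = length(adults) == 1 && length(kids) >= 1,
      child_in_care = any(sapply(kids, function(p)
        any(codes_of(p) %in% cfg$vulnerability_codes$child_in_care))),
      deprived = !is.na(hh_imd[[h]]) && hh_imd[[h]] >= dep_cut,
      multi_service = length(unique(
        contacts$sector[contacts$person_id %in% mem])) >=
        th$distinct_services_min)
    total <- sum(sapply(mem, function(p) {
      pc <- person_costs[[p]]
      if (is.null(pc)) 0 else sum(pc)
    }))
    rows[[h]] <- c(list(household_id = h, c1 = c1, c2 = c2,
                        c3 = Reduce(`|`, sub),
                        per_capita = total / length(mem)), sub)
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  df <- df[order(df$household_id), , drop = FALSE]
  pc <- sort(df$per_capita, decreasing = TRUE)
  m4 <- floor((1 - th$spend_quantile) * nrow(df))
  if (m4 < 1) stop("oracle: quantile undefined")
  thr <- pc[m4]
  df$c4 <- df$per_capita >= thr
  df$in_segment <- df$c1 & df$c2 & df$c3 & df$c4
  rownames(df) <- NULL
  df
}

# per-person loop classification for the unmet-need strata
oracle_strata <- function(persons, conditions, contacts, complex_hids, cfg,
                          cohort_hids) {
  res <- list(no_prior_contact = c(a = 0, b = 0, c = 0, d = 0),
              known_to_services = c(a = 0, b = 0, c = 0, d = 0))
  persons <- as.data.frame(persons)
  for (i in seq_len(nrow(persons))) {
    p <- persons[i, ]
    if (!p$household_id %in% cohort_hids) next
    codes <- conditions$condition_code[conditions$person_id == p$person_id]
    prior <- any(codes %in% cfg$mental_conditions) ||
      any(contacts$sector == "mental_health" & !contacts$emergency &
            contacts$person_id == p$person_id)
    event <- any(contacts$emergency &
                   contacts$reason_class %in% cfg$mh_reason_classes &
                   contacts$person_id == p$person_id)
    stratum <- if (prior) "known_to_services" else "no_prior_contact"
    exposed <- p$household_id %in% complex_hids
    cell <- if (exposed && event) "a" else if (exposed) "b"
            else if (event) "c" else "d"
    res[[stratum]][[cell]] <- res[[stratum]][[cell]] + 1
  }
  res
}
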