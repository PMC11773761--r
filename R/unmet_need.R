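## Unmet-need contrast: odds of emergency mental-health attendance in
## complex vs other households, stratified by prior mental-health service
## contact or diagnosis. High odds in the no-prior-contact stratum indicate
## needs not met upstream (the inverse care law): people reach crisis
## services without ever reaching routine ones.

#' Build the two prior-contact strata
#'
#' Partitions cohort persons (members of households with children) by prior
#' mental-health engagement: `known_to_services` when a person carries any
#' mental-set condition code or has any non-emergency mental-health sector
#' contact, `no_prior_contact` otherwise. Within each stratum a 2x2 table
#' crosses household type (complex / other) with emergency mental-health
#' attendance in the year (any contact with the emergency flag and a
#' mental-health reason class).
#'
#' @param persons,conditions,contacts Validated input tables.
#' @param segments Output of [segment_households()].
#' @param cfg A `hhseg_config`.
#' @return `data.table`, one row per stratum: `stratum`, cells `a` (complex,
#'   event), `b` (complex, no event), `c` (other, event), `d` (other, no
#'   event), and `degenerate` (TRUE when any margin is empty).
#' @export
build_strata <- function(persons, conditions, contacts, segments, cfg) {
  x <- cohort_persons(persons, segments)
  prior_ids <- union(
    conditions[condition_code %in% cfg$mental_conditions, person_id],
    contacts[sector == "mental_health" & emergency == FALSE, person_id])
  event_ids <- unique(contacts[emergency == TRUE &
                                 reason_class %in% cfg$mh_reason_classes,
                               person_id])
  x[, stratum := data.table::fifelse(person_id %in% prior_ids,
                                     "known_to_services", "no_prior_contact")]
  x[, event := person_id %in% event_ids]
  x[, complex := group == "complex"]
  cells <- x[, .(
    a = sum(complex & event), b = sum(complex & !event),
    c = sum(!complex & event), d = sum(!complex & !event)
  ), by = stratum]
  template <- data.table::data.table(
    stratum = c("no_prior_contact", "known_to_services"))
  cells <- merge(template, cells, by = "stratum", all.x = TRUE, sort = FALSE)
  for (col in c("a", "b", "c", "d")) {
    data.table::set(cells, which(is.na(cells[[col]])), col, 0L)
  }
  cells[, degenerate := (a + b == 0L) | (c + d == 0L) | (a + c == 0L) |
          (b + d == 0L)]
  cells[]
}

#' Odds ratio with Wald interval for a 2x2 table
#'
#' Closed form `OR = (a d)/(b c)` with the 95% Wald interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, cross-checked
#' against the interaction term of a saturated Poisson log-linear model of
#' the cell counts; the two routes must agree to six significant figures.
#' Zero cells abort unless `correction = TRUE`, which applies the
#' Haldane-Anscombe 0.5 continuity correction (flagged in the result).
#'
#' @param a,b,c,d Cell counts: exposed event / exposed non-event /
#'   unexposed event / unexposed non-event.
#' @param correction Apply the 0.5 continuity correction to zero-cell
#'   tables (default off, never silent).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `or`, `ci_low`, `ci_high`, `or_loglinear`, `corrected`.
#' @export
estimate_or <- function(a, b, c, d, correction = FALSE, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("negative cell count")
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correction) {
      stop("degenerate 2x2 table: zero cell(s) [",
           paste(names(cells)[cells == 0], collapse = ", "),
           "]; set correction = TRUE for the Haldane-Anscombe estimate")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or <- (cells[["a"]] * cells[["d"]]) / (cells[["b"]] * cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ## dual path: saturated log-linear model, interaction = log OR
  dd <- data.frame(n = unname(cells),
                   exposed = c(1, 1, 0, 0), event = c(1, 0, 1, 0))
  ## corrected tables carry half counts; the non-integer Poisson warning is
  ## expected and uninformative there
  fit <- suppressWarnings(
    stats::glm(n ~ exposed * event, family = stats::poisson(), data = dd))
  or_ll <- exp(unname(stats::coef(fit)[["exposed:event"]]))
  list(or = unname(or),
       ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)),
       or_loglinear = or_ll,
       corrected = corrected)
}

#' Stratified unmet-need analysis
#'
#' Builds the two prior-contact strata and estimates the complex-vs-other
#' odds ratio of emergency mental-health attendance within each.
#'
#' @inheritParams build_strata
#' @param correction Passed to [estimate_or()].
#' @return `data.table`: stratum, cells, `or`, `ci_low`, `ci_high`,
#'   `or_loglinear`, `corrected`, `degenerate`.
#' @export
unmet_need_analysis <- function(persons, conditions, contacts, segments, cfg,
                                correction = FALSE) {
  strata <- build_strata(persons, conditions, contacts, segments, cfg)
  est <- lapply(seq_len(nrow(strata)), function(i) {
    r <- strata[i]
    if (r$degenerate && !correction) {
      return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  or_loglinear = NA_real_, corrected = FALSE))
    }
    tryCatch(estimate_or(r$a, r$b, r$c, r$d, correction = correction),
             error = function(e) list(or = NA_real_, ci_low = NA_real_,
                                      ci_high = NA_real_,
                                      or_loglinear = NA_real_,
                                      corrected = FALSE))
  })
  cbind(strata, data.table::rbindlist(lapply(est, data.table::as.data.table)))
}
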