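## Cost-weighted utilisation.
##
## Contacts are converted to currency with a per-sector unit tariff; a
## per-contact override supersedes the tariff where supplied. Costs are
## abstract currency units for one analysis year. Per-capita household spend
## divides the household total by the full head count, children included.

#' Cost contacts per person and sector
#'
#' Person cost in a sector is the sum over that person's contact rows of
#' `n_contacts` times the unit cost (row override if present, else the
#' sector tariff). Sectors with no observed contacts cost zero.
#'
#' @param contacts Validated contact `data.table`.
#' @param cfg A `hhseg_config` whose `tariffs` covers every sector present.
#' @return Wide `data.table`: `person_id`, one cost column per sector in
#'   [hh_sectors()], and `total`.
#' @export
cost_contacts <- function(contacts, cfg) {
  contacts <- data.table::as.data.table(contacts)
  tariffs <- unlist(cfg$tariffs)
  missing <- setdiff(unique(contacts$sector), names(tariffs))
  if (length(missing)) {
    stop("config error: no tariff for sector(s): ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(contacts)) {
    empty <- data.table::data.table(person_id = character())
    for (s in hh_sectors()) empty[, (s) := numeric()]
    empty[, total := numeric()]
    return(empty[])
  }
  x <- data.table::copy(contacts)
  x[, unit_cost := data.table::fifelse(is.na(unit_cost_override),
                                       tariffs[sector], unit_cost_override)]
  long <- x[, .(cost = sum(n_contacts * unit_cost)), by = .(person_id, sector)]
  wide <- data.table::dcast(long, person_id ~ sector, value.var = "cost",
                            fill = 0)
  for (s in setdiff(hh_sectors(), names(wide))) wide[, (s) := 0]
  data.table::setcolorder(wide, c("person_id", hh_sectors()))
  wide[, total := rowSums(.SD), .SDcols = hh_sectors()]
  data.table::setorder(wide, person_id)
  wide[]
}

#' Aggregate person costs to households and compute per-capita spend
#'
#' Household sector costs are member sums; members with no contacts
#' contribute zero. Per-capita spend is the household total divided by
#' `n_members` (all members, adults and children alike).
#'
#' @param households Output of [build_households()] (or the
#'   children-restricted subset); must carry the `members` attribute.
#' @param person_costs Output of [cost_contacts()].
#' @return `data.table`: `household_id`, per-sector costs, `total`,
#'   `per_capita`.
#' @export
household_costs <- function(households, person_costs) {
  members <- attr(households, "members")
  if (is.null(members)) stop("households lack the 'members' attribute; ",
                             "use build_households()")
  pc <- merge(members, person_costs, by = "person_id", all.x = TRUE)
  sect <- hh_sectors()
  for (s in c(sect, "total")) {
    data.table::set(pc, which(is.na(pc[[s]])), s, 0)
  }
  hc <- pc[, lapply(.SD, sum), by = household_id, .SDcols = c(sect, "total")]
  hc <- merge(households[, .(household_id, n_members)], hc,
              by = "household_id", all.x = TRUE)
  for (s in c(sect, "total")) {
    data.table::set(hc, which(is.na(hc[[s]])), s, 0)
  }
  hc[, per_capita := total / n_members]
  hc[, n_members := NULL]
  data.table::setorder(hc, household_id)
  hc[]
}

#' Sector shares of segment spend
#'
#' Distribution of total spend across sectors for members of the given
#' households (normally the complex segment). Shares sum to one.
#'
#' @param household_ids Character vector of household ids defining the group.
#' @param household_costs Output of [household_costs()].
#' @return `data.table`: `sector`, `amount`, `share`.
#' @export
cost_share_by_sector <- function(household_ids, household_costs) {
  x <- household_costs[household_id %in% household_ids]
  amounts <- vapply(hh_sectors(), function(s) sum(x[[s]]), numeric(1))
  tot <- sum(amounts)
  if (tot <= 0) stop("cost shares undefined: zero total spend in group")
  data.table::data.table(sector = hh_sectors(), amount = unname(amounts),
                         share = unname(amounts) / tot)
}
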