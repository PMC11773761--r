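## Command-line pipeline: simulate | segment | profile | unmet-need | all.
##
## Every stage writes CSV outputs plus a JSON run manifest (config hash,
## input digests, seed, stage timings, exclusion counts, output list) into
## the designated output directory and nowhere else. Identical inputs,
## config and seed give byte-identical outputs.

usage_error <- function(msg) {
  stop(structure(class = c("hhseg_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

parse_args <- function(args, spec) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    flag <- args[[i]]
    if (!startsWith(flag, "--")) usage_error(paste0("unexpected argument: ", flag))
    key <- substring(flag, 3L)
    if (!key %in% spec) usage_error(paste0("unknown flag: ", flag))
    if (i + 1L > length(args)) usage_error(paste0("flag ", flag, " needs a value"))
    out[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

config_digest <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

file_digests <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  as.list(tools::md5sum(unlist(paths)))
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_simulate <- function(cfg, syncfg, out_dir) {
  pop <- generate_population(syncfg)
  un <- plant_unmet_need(pop, syncfg)
  pop$contacts <- un$contacts
  write_population(pop, out_dir)
  write_table(un$person_strata, file.path(out_dir, "strata_truth.csv"))
  pop
}

stage_segment <- function(tables, cfg, out_dir) {
  seg <- segment_households(tables$persons, tables$conditions,
                            tables$contacts, cfg)
  write_table(seg, file.path(out_dir, "segments.csv"))
  seg
}

stage_profile <- function(tables, seg, cfg, out_dir) {
  rep <- profile_report(tables$persons, tables$conditions, tables$contacts,
                        seg, cfg)
  write_table(rep$criteria_table, file.path(out_dir, "criteria_table.csv"))
  write_table(rep$prevalence_table, file.path(out_dir, "prevalence_table.csv"))
  write_table(rep$demographics, file.path(out_dir, "demographics.csv"))
  write_table(rep$size_summary, file.path(out_dir, "size_summary.csv"))
  write_table(rep$age_sex_density, file.path(out_dir, "age_sex_density.csv"))
  write_table(rep$cost_shares, file.path(out_dir, "cost_shares.csv"))
  write_table(rep$service_intersections,
              file.path(out_dir, "intersections.csv"))
  write_table(rep$mh_reason_breakdown, file.path(out_dir, "mh_breakdown.csv"))
  write_table(rep$ae_mh_by_age_sex, file.path(out_dir, "ae_mh_by_age_sex.csv"))
  rep
}

stage_unmet_need <- function(tables, seg, cfg, out_dir) {
  res <- unmet_need_analysis(tables$persons, tables$conditions,
                             tables$contacts, seg, cfg)
  write_table(res, file.path(out_dir, "strata.csv"))
  res
}

#' Run the pipeline from command-line style arguments
#'
#' Subcommands: `simulate` (synthetic population to CSV), `segment`
#' (classify households), `profile` (descriptive reports), `unmet-need`
#' (stratified odds ratios), `all` (simulate then everything downstream).
#' Flags: `--config` (YAML/JSON run config), `--persons` / `--conditions` /
#' `--contacts` (input CSVs for the non-simulating stages), `--out`
#' (output directory, required), `--seed` (integer, overrides the config
#' seed), `--n-households` (simulate/all). A usage error (unknown
#' subcommand or flag, missing input) aborts before any output is written.
#'
#' @param args Character vector, e.g.
#'   `c("all", "--seed", "7", "--out", "run")`.
#' @return Exit status 0 invisibly; stage outputs and `manifest.json` are
#'   written under `--out`.
#' @export
run_pipeline <- function(args) {
  if (!length(args)) usage_error("no subcommand given")
  sub <- args[[1L]]
  if (!sub %in% c("simulate", "segment", "profile", "unmet-need", "all")) {
    usage_error(paste0("unknown subcommand: ", sub))
  }
  opts <- parse_args(args[-1L],
                     c("config", "persons", "conditions", "contacts", "out",
                       "seed", "n-households"))
  if (is.null(opts$out)) usage_error("--out is required")
  cfg <- if (is.null(opts$config)) default_config() else load_config(opts$config)
  seed <- if (is.null(opts$seed)) cfg$random_seed else as.integer(opts$seed)

  needs_inputs <- sub %in% c("segment", "profile", "unmet-need")
  if (needs_inputs &&
      (is.null(opts$persons) || is.null(opts$conditions) ||
       is.null(opts$contacts))) {
    usage_error(paste0("subcommand '", sub,
                       "' needs --persons, --conditions and --contacts"))
  }

  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    v <- force(expr)
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), s,
                                                  units = "secs")), 3)
    v
  }

  exclusions <- NULL
  if (sub %in% c("simulate", "all")) {
    nh <- if (is.null(opts[["n-households"]])) 1000L
          else as.integer(opts[["n-households"]])
    syncfg <- synthetic_config(n_households = nh, seed = seed)
    pop <- tick("simulate", stage_simulate(cfg, syncfg, opts$out))
    tables <- list(persons = pop$persons, conditions = pop$conditions,
                   contacts = pop$contacts)
  } else {
    tables <- tick("load", load_tables(opts$persons, opts$conditions,
                                       opts$contacts, cfg))
  }

  if (sub %in% c("segment", "profile", "unmet-need", "all")) {
    seg <- tick("segment", stage_segment(tables, cfg, opts$out))
    exclusions <- attr(seg, "exclusions")
    if (sub %in% c("profile", "all")) {
      tick("profile", stage_profile(tables, seg, cfg, opts$out))
    }
    if (sub %in% c("unmet-need", "all")) {
      tick("unmet_need", stage_unmet_need(tables, seg, cfg, opts$out))
    }
  }

  outputs <- sort(setdiff(list.files(opts$out), "manifest.json"))
  manifest <- list(
    subcommand = sub,
    config_hash = config_digest(cfg),
    input_digests = if (needs_inputs) {
      file_digests(list(opts$persons, opts$conditions, opts$contacts))
    } else list(),
    seed = seed,
    exclusions = exclusions,
    stage_seconds = timings,
    outputs = outputs,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 3)
  )
  write_manifest(opts$out, manifest)
  invisible(0L)
}
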