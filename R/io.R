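#' Read a life table from a delimited file
#'
#' Two-column format (`age`, `qx`) with optional per-sex columns
#' (`qx_female`, `qx_male`), tab-delimited with a header. When per-sex
#' columns are present and `female_weight` is given, the combined `qx` is
#' recomputed as the weighted mixture.
#'
#' @param path File path.
#' @param female_weight Optional cohort share of women for sex weighting.
#' @return Validated life-table data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path, female_weight = NULL) {
  df <- utils::read.delim(path)
  if (!all(c("age", "qx") %in% names(df)) &&
      !all(c("age", "qx_female", "qx_male") %in% names(df))) {
    stop("life table needs columns age + qx (or qx_female/qx_male)", call. = FALSE)
  }
  if (!is.null(female_weight)) {
    if (!all(c("qx_female", "qx_male") %in% names(df))) {
      stop("sex weighting requested but per-sex columns absent", call. = FALSE)
    }
    stopifnot(female_weight >= 0, female_weight <= 1)
    df$qx <- female_weight * df$qx_female + (1 - female_weight) * df$qx_male
  }
  if (any(df$qx < 0 | df$qx > 1)) stop("qx outside [0,1]", call. = FALSE)
  if (any(diff(df$age) != 1)) stop("life table ages must be consecutive integers", call. = FALSE)
  df[, intersect(c("age", "qx", "qx_female", "qx_male"), names(df))]
}

#' Write a life table
#' @param life_table Data frame with `age`, `qx` (and optional per-sex columns).
#' @param path Output path.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.table(life_table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an efficacy table
#'
#' Tab-delimited with columns `treatment` and, for each outcome in
#' `h2r`, `h2m`, `sae`: `rr_<outcome>`, `rr_<outcome>_lo`, `rr_<outcome>_hi`.
#'
#' @param path File path.
#' @return Validated efficacy data frame.
#' @export
read_efficacy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_efficacy_table(df)
}

#' @rdname read_efficacy_table
#' @param efficacy Efficacy data frame.
#' @export
write_efficacy_table <- function(efficacy, path) {
  validate_efficacy_table(efficacy)
  utils::write.table(efficacy, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an efficacy table
#'
#' Checks positivity of all point estimates and CI bounds and the ordering
#' `lo <= point <= hi` for every outcome.
#'
#' @param efficacy Efficacy data frame.
#' @return The data frame, invisibly.
#' @export
validate_efficacy_table <- function(efficacy) {
  need <- c("treatment",
            as.vector(outer(c("rr_h2r", "rr_h2m", "rr_sae"),
                            c("", "_lo", "_hi"), paste0)))
  missing <- setdiff(need, names(efficacy))
  if (length(missing)) {
    stop("efficacy table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (out in c("h2r", "h2m", "sae")) {
    pt <- efficacy[[paste0("rr_", out)]]
    lo <- efficacy[[paste0("rr_", out, "_lo")]]
    hi <- efficacy[[paste0("rr_", out, "_hi")]]
    if (any(pt <= 0 | lo <= 0 | hi <= 0)) {
      stop("relative risks must be positive (outcome ", out, ")", call. = FALSE)
    }
    if (any(lo > pt | pt > hi)) {
      stop("CI bounds must bracket the point estimate (outcome ", out, ")",
           call. = FALSE)
    }
  }
  invisible(efficacy)
}

#' Load and validate a run configuration
#'
#' YAML configuration with explicit schema versioning. Required fields:
#' `schema_version`, `currency_year` (must be `"THB-2022"`; untagged monetary
#' configurations are refused to prevent silent price-year errors). Optional
#' fields with documented defaults: `strategies` (all twelve), `settings`
#' (start age 56, 200-cycle horizon, 3% discount, switch after 1 failing
#' cycle, no half-cycle correction), `psa` (`n = 5000` iterations and a
#' master seed), `paths` to a life table and efficacy table, and
#' `output_dir`. Every assumption default in force is logged once at load.
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version)) stop("config lacks schema_version", call. = FALSE)
  if (!identical(cfg$currency_year, "THB-2022")) {
    stop("monetary values must be tagged currency_year: THB-2022", call. = FALSE)
  }
  strategies <- cfg$strategies %||% ra_strategies()
  unknown <- setdiff(strategies, ra_strategies())
  if (length(unknown)) {
    stop("unknown strategy name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(strategies)) stop("duplicate strategy names", call. = FALSE)
  s <- cfg$settings %||% list()
  settings <- economic_settings(
    annual_discount_rate = s$annual_discount_rate %||% 0.03,
    cycle_length = s$cycle_length %||% 0.5,
    thb_per_usd = s$thb_per_usd %||% 34.53,
    wtp_threshold = s$wtp_threshold %||% 160000,
    start_age = s$start_age %||% 56,
    horizon_cycles = s$horizon_cycles %||% 200,
    switch_after = s$switch_after %||% 1,
    half_cycle = s$half_cycle %||% FALSE)
  p <- cfg$psa %||% list()
  psa <- list(n_iterations = p$n_iterations %||% 5000,
              master_seed = p$master_seed %||% 20220101)
  if (psa$n_iterations < 1 || psa$master_seed < 1) {
    stop("psa iteration count and master seed must be positive", call. = FALSE)
  }
  defaults_used <- c(
    if (is.null(cfg$mtx_only_cost)) "mtx_only_cost = 10% of SoC+MTX (assumption)",
    if (is.null(s$switch_after)) "switch_after = 1 cycle of inadequate response",
    "infusion schedules: infliximab-type 5 then 3 per cycle, rituximab-type 2 per cycle")
  for (msg in defaults_used) message("[config] assumption default in force: ", msg)
  out <- list(schema_version = cfg$schema_version,
              currency_year = cfg$currency_year,
              strategies = strategies,
              settings = settings,
              psa = psa,
              mtx_only_cost = cfg$mtx_only_cost,
              paths = cfg$paths %||% list(),
              output_dir = cfg$output_dir %||% "results")
  class(out) <- "run_config"
  out
}

#' Write a run configuration to YAML
#' @param config A `run_config` list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build model inputs from a run configuration
#'
#' Loads the life table and efficacy table named in the configuration (or
#' generates the synthetic defaults) and assembles the input bundle.
#'
#' @param config A `run_config` from [load_config()].
#' @return An `ra_inputs` bundle.
#' @export
inputs_from_config <- function(config) {
  life_table <- if (!is.null(config$paths$life_table)) {
    read_life_table(config$paths$life_table)
  }
  efficacy <- if (!is.null(config$paths$efficacy)) {
    read_efficacy_table(config$paths$efficacy)
  }
  inputs <- ra_model_inputs(efficacy = efficacy, life_table = life_table,
                            settings = config$settings,
                            seed = config$psa$master_seed)
  if (!is.null(config$mtx_only_cost)) {
    inputs$costs$mtx_only <- config$mtx_only_cost
  }
  inputs$strategies <- config$strategies
  inputs
}

#' Write a results bundle with a reproducibility manifest
#'
#' Writes the deterministic base-case table, per-strategy traces, and (when
#' present) PSA draws, CEAC, tornado and cost-effectiveness-plane tables as
#' delimited files, plus a JSON manifest recording the configuration hash,
#' master seed, package version and the file list.
#'
#' @param results List with elements `base_case` (required) and optionally
#'   `traces` (named list of `cohort_trace`), `psa`, `ceac`, `tornado`,
#'   `ce_plane`.
#' @param output_dir Output directory (created if needed).
#' @param config The `run_config` the results were produced under.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, output_dir, config) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(fname) { files <<- c(files, fname); file.path(output_dir, fname) }

  write_base_case(results$base_case, put("base_case.tsv"))
  for (nm in names(results$traces)) {
    write_cohort_trace(results$traces[[nm]], put(paste0("trace_", nm, ".tsv")))
  }
  if (!is.null(results$psa)) {
    psa_df <- data.frame(iteration = seq_len(results$psa$n_iterations),
                         cost = results$psa$cost, qalys = results$psa$qalys,
                         check.names = FALSE)
    utils::write.table(psa_df, put("psa_iterations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  for (nm in intersect(c("ceac", "tornado", "ce_plane"), names(results))) {
    utils::write.table(results[[nm]], put(paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    master_seed = config$psa$master_seed,
    package_version = as.character(utils::packageVersion("ramcea")),
    files = files)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
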