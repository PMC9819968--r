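#' Pipeline drivers
#'
#' Thin, file-oriented entry points that chain the package stages the way
#' the command-line tool does: each reads CSV/YAML inputs, runs one stage,
#' writes its result tables to `out_dir` and records a run manifest
#' (`manifest_<stage>.json`) listing inputs, parameters and outputs.
#'
#' @name pipeline
NULL

write_manifest <- function(stage, out_dir, inputs, outputs, config) {
  manifest <- list(
    stage = stage,
    inputs = inputs,
    outputs = outputs,
    config = unclass(config),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

config_hash <- function(config) {
  # stable content hash: serialize the canonicalized parameter list
  vals <- unclass(config)
  vals <- vals[order(names(vals))]
  txt <- paste(names(vals),
               vapply(vals, function(v) paste(format(v), collapse = ","),
                      character(1)),
               collapse = ";")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 997)) %% 2^31
}

resolve_panel <- function(panel, yields) {
  if (is.character(panel)) {
    read_city_panel(panel, yields = yields)
  } else {
    as_city_panel(as.data.frame(panel), yields = yields)
  }
}

#' @rdname pipeline
#' @param panel A `city_panel` or path to a panel CSV.
#' @param out_dir Output directory (created if needed).
#' @param factors,yields Constant tables or paths to them.
#' @param config An [analysis_config()] or path to a config YAML.
#' @return `run_account`: invisibly, the `threedef_result`.
#' @export
run_account <- function(panel, out_dir, factors = default_factor_table(),
                        yields = default_yield_table(),
                        config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_config(config)
  if (is.character(factors)) factors <- read_factor_table(factors)
  if (is.character(yields)) yields <- read_yield_table(yields)
  panel <- resolve_panel(panel, yields)
  accounts <- footprint_accounts(panel, yields, factors,
                                 retention = config$retention)
  tdf <- threedef(accounts)
  outputs <- c(
    accounts = file.path(out_dir, "accounts.csv"),
    threedef = file.path(out_dir, "threedef.csv"),
    land_depth = file.path(out_dir, "land_depth.csv"),
    changes = file.path(out_dir, "change_table.csv")
  )
  write_results(as.data.frame(accounts), outputs[["accounts"]])
  write_results(as.data.frame(tdf), outputs[["threedef"]])
  write_results(land_depth_table(tdf), outputs[["land_depth"]])
  write_results(change_table(tdf), outputs[["changes"]])
  write_manifest("account", out_dir, inputs = "panel",
                 outputs = as.list(outputs), config = config)
  invisible(tdf)
}

#' @rdname pipeline
#' @param results A `threedef_result` or path to a threedef CSV written
#'   by [run_account()].
#' @return `run_classify`: invisibly, the `ef_typology`.
#' @export
run_classify <- function(results, out_dir, config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_config(config)
  if (is.character(results)) {
    results <- utils::read.csv(results, stringsAsFactors = FALSE)
    class(results) <- c("threedef_result", "data.frame")
  }
  if (nrow(results) == 0) stop("run_classify: empty results",
                               call. = FALSE)
  ty <- classify_sustainability(results, k = config$k,
                                linkage = config$linkage)
  outputs <- c(typology = file.path(out_dir, "typology.csv"))
  write_results(as.data.frame(ty), outputs[["typology"]])
  write_manifest("classify", out_dir, inputs = "threedef results",
                 outputs = as.list(outputs), config = config)
  invisible(ty)
}

#' @rdname pipeline
#' @param slices Passed to [run_importance_analysis()].
#' @return `run_importance`: invisibly, the `ef_importance` table.
#' @export
run_importance <- function(panel, results, out_dir,
                           config = analysis_config(),
                           yields = default_yield_table(),
                           slices = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(config)) config <- read_config(config)
  if (is.character(yields)) yields <- read_yield_table(yields)
  panel <- resolve_panel(panel, yields)
  if (is.character(results)) {
    results <- utils::read.csv(results, stringsAsFactors = FALSE)
    class(results) <- c("threedef_result", "data.frame")
  }
  imp <- run_importance_analysis(panel, results, config = config,
                                 slices = slices)
  outputs <- c(importance = file.path(out_dir, "importance.csv"))
  write_results(as.data.frame(imp), outputs[["importance"]])
  write_manifest("importance", out_dir, inputs = "panel + results",
                 outputs = as.list(outputs), config = config)
  invisible(imp)
}

#' @rdname pipeline
#' @param scenario A [scenario_config()] or path to a scenario YAML
#'   whose keys match its arguments.
#' @param out_path Path of the panel CSV to write.
#' @return `run_simulate`: invisibly, the generated `city_panel`.
#' @export
run_simulate <- function(scenario = scenario_config(), out_path) {
  if (is.character(scenario)) {
    vals <- yaml::read_yaml(scenario)
    if (is.null(vals)) vals <- list()
    keep <- intersect(names(vals), names(formals(scenario_config)))
    scenario <- do.call(scenario_config, vals[keep])
  }
  panel <- generate_panel(scenario)
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  write_results(as.data.frame(panel), out_path)
  truth_path <- file.path(dirname(out_path), "panel_truth.csv")
  write_results(attr(panel, "truth"), truth_path)
  write_manifest("simulate", dirname(out_path), inputs = "scenario",
                 outputs = list(panel = out_path, truth = truth_path),
                 config = scenario)
  invisible(panel)
}
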