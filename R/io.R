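# Keys accepted in each config-file section, mapped onto constructor
# arguments. Scenario and numerics keys feed scenario_config(); parameter
# keys are dimensional overrides fed to default_parameters().
config_keys <- list(
  scenario = c("case", "n0", "a0", "d"),
  numerics = c("N", "t_end", "rtol", "atol", "snapshot_dt", "eps_H",
               "guard", "max_neg", "hmax", "stop_at_t90", "seed"),
  parameters = c("Lambda1", "fd", "lambda3", "lambda4", "lambda5",
                 "lambda6", "lambda7", "lambda8", "lambda_m9", "lambda_n9",
                 "lambda_m10", "lambda_n10", "Ftot", "Gtot", "Dc", "Da",
                 "A0", "M0", "L")
)

#' Read a scenario configuration file
#'
#' Parses the flat `key = value` format with sections `[scenario]`,
#' `[parameters]` and `[numerics]`. Lines starting with `#` or `;` are
#' comments. Keys are the argument names of [scenario_config()] (scenario
#' and numerics sections) and of [default_parameters()] /
#' [default_scales()] (parameters section, dimensional units as documented
#' there). Values omitted from the file keep their defaults.
#'
#' @param path Path to the config file. An empty or absent `[scenario]`
#'   section defaults to case 2 with `a0 = 0`-style arguments only if
#'   `case` is given; otherwise `case` must be present to build a scenario.
#' @param overrides Named list applied on top of the file values (highest
#'   precedence, e.g. parsed command-line flags).
#'
#' @return List with `config` (a `chondro_config`), `dim_params`
#'   (a `chondro_params` with any overrides applied), `scales`
#'   (a `chondro_scales`) and `raw` (the merged key-value lists).
#' @export
read_scenario_config <- function(path, overrides = list()) {
  lines <- if (is.null(path)) character(0) else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    readLines(path, warn = FALSE)
  }
  section <- "scenario"
  vals <- list(scenario = list(), numerics = list(), parameters = list())
  for (ln in lines) {
    ln <- sub("[#;].*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      if (!section %in% names(config_keys))
        stop("unknown config section [", section, "]", call. = FALSE)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse config line: '", ln, "'", call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    vals[[section]][[key]] <- val
  }
  for (sec in names(vals)) {
    unknown <- setdiff(names(vals[[sec]]), config_keys[[sec]])
    if (length(unknown))
      stop("unknown key(s) in [", sec, "]: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  # overrides use the flat key names; route each to its section
  for (key in names(overrides)) {
    sec <- names(config_keys)[vapply(config_keys, function(k) key %in% k,
                                     logical(1))][1]
    if (is.na(sec)) stop("unknown config key: ", key, call. = FALSE)
    vals[[sec]][[key]] <- overrides[[key]]
  }
  coerce <- function(key, val) {
    if (key %in% c("stop_at_t90")) {
      out <- as.logical(val)
      if (is.na(out)) stop("key '", key, "' expects a logical value",
                           call. = FALSE)
      return(out)
    }
    out <- suppressWarnings(as.numeric(val))
    if (is.na(out)) stop("key '", key, "' expects a number, got '", val,
                         "'", call. = FALSE)
    out
  }
  for (sec in names(vals))
    vals[[sec]] <- mapply(coerce, names(vals[[sec]]), vals[[sec]],
                          SIMPLIFY = FALSE)
  if (is.null(vals$scenario$case))
    stop("config must specify 'case' (1, 2 or 3)", call. = FALSE)
  scale_keys <- intersect(names(vals$parameters), c("A0", "M0", "L"))
  scales <- do.call(default_scales, vals$parameters[scale_keys])
  par_over <- vals$parameters[setdiff(names(vals$parameters), scale_keys)]
  dim_params <- do.call(default_parameters, par_over)
  config <- do.call(scenario_config, c(vals$scenario, vals$numerics))
  list(config = config, dim_params = dim_params, scales = scales,
       raw = vals)
}

#' Run manifest
#'
#' Collects everything needed to reproduce a simulation bit-for-bit with
#' the same package version: the resolved configuration, dimensional and
#' dimensionless parameters, grid and solver settings, termination reason
#' and wall time.
#'
#' @param result A `chondro_sim`.
#' @return A named list suitable for JSON serialisation.
#' @export
run_manifest <- function(result) {
  stopifnot(inherits(result, "chondro_sim"))
  cfg <- unclass(result$config)
  cfg$seed <- NULL
  list(
    package = "chondrosim",
    version = as.character(utils::packageVersion("chondrosim")),
    config = cfg,
    dimensional_parameters = if (!is.null(result$dim_params))
      unclass(result$dim_params) else NULL,
    dimensionless_parameters = unclass(result$params),
    scales = unclass(result$scales),
    grid = list(N = result$grid$N, h = result$grid$h),
    termination = result$termination,
    wall_time_s = unname(result$diagnostics$wall_time),
    steady_residual = result$diagnostics$steady_residual
  )
}

#' Write simulation snapshots as a long-format CSV
#'
#' One row per (time, node): columns `t`, `x`, `m`, `n`, `c`, `b`, `a`,
#' `f`, `g`. With `dimensional = TRUE`, columns `t_hours`, `x_mm` and
#' dimensional concentrations/densities are appended using the stored
#' scales.
#'
#' @param result A `chondro_sim` (not aborted).
#' @param path Output CSV path.
#' @param dimensional Append dimensional columns.
#' @return `path`, invisibly.
#' @export
write_states_csv <- function(result, path, dimensional = FALSE) {
  stopifnot(inherits(result, "chondro_sim"))
  if (is.null(result$states))
    stop("aborted run holds no snapshots", call. = FALSE)
  nt <- length(result$times)
  df <- do.call(rbind, lapply(seq_len(nt), function(i) {
    s <- result$states[, , i]
    data.frame(t = result$times[i], x = result$grid$x,
               m = s["m", ], n = s["n", ], c = s["c", ], b = s["b", ],
               a = s["a", ],
               f = recover_fraction(s["p", ], s["m", ],
                                    result$config$guard),
               g = recover_fraction(s["q", ], s["n", ],
                                    result$config$guard))
  }))
  if (dimensional && !is.null(result$dim_params)) {
    df$t_hours <- dimensional_time(df$t, result$dim_params)
    df$x_mm <- df$x * result$scales$L * 1e3
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#'
#' The summary carries the outcome classification, final yield, `t90`
#' (dimensionless and in hours) and the full [run_manifest()].
#'
#' @param result A `chondro_sim`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path) {
  out <- classify_outcome(result)
  doc <- list(
    outcome = out$label,
    N_final = out$N_final,
    initial_msc = out$initial_msc,
    t90 = if (is.na(result$t90)) NULL else result$t90,
    t90_hours = if (is.na(result$t90) || is.null(result$dim_params)) NULL
      else dimensional_time(result$t90, result$dim_params),
    manifest = run_manifest(result)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a phase sweep as tidy CSV plus JSON sidecar
#'
#' @param sweep A `chondro_sweep`.
#' @param csv_path Output CSV path (columns `a0`, `n0`, `d`, `label`,
#'   `N_final`, `t90`).
#' @param json_path Optional sidecar path recording the base configuration
#'   and software version.
#' @param base_config The sweep's base `chondro_config` (echoed in the
#'   sidecar).
#' @return `csv_path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, csv_path, json_path = NULL,
                            base_config = NULL) {
  stopifnot(inherits(sweep, "chondro_sweep"))
  utils::write.csv(as.data.frame(sweep), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    doc <- list(
      package = "chondrosim",
      version = as.character(utils::packageVersion("chondrosim")),
      base_config = if (!is.null(base_config)) {
        cfg <- unclass(base_config); cfg$seed <- NULL; cfg
      } else NULL,
      cells = nrow(sweep)
    )
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(csv_path)
}
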