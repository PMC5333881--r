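## io: run configuration (YAML/JSON), pipeline outputs and provenance.
## The functions, scripts and vignette are the package's interface; a run
## configuration document makes full analyses reproducible from a single
## file.

#' Default run configuration
#'
#' All tunable quantities of the pipeline in one nested list. Physical
#' quantities carry customary units in the document (mm, mmHg, L/min) and
#' are converted to SI on load by the consuming functions.
#'
#' @return nested list (classes `run_config`/`list`).
#' @export
default_config <- function() {
  structure(list(
    ages = c(40, 60, 75),
    geometry = list(source = "synthetic", vtk_path = NULL,
                    trunk_length_m = 0.50, straight_distance_m = 0.36,
                    height_reduction_per_decade = 0.01),
    inflow = list(mean_flow_lmin = 5.79, heart_rate_bpm = 60,
                  systolic_fraction = 0.33, reverse_fraction = 0.03),
    solver = list(dx_m = 0.01, cfl = 0.8, min_cycles = 6, max_cycles = 24,
                  tol_mmHg = 0.4, rho_kgm3 = 1060, mu_pas = 4.0e-3),
    calibration = list(pwv_tol_ms = 0.2, ep_tol_mmHg = 0.5, max_iter = 20,
                       damping = "auto"),
    seed = 1,
    output_dir = NULL), class = c("run_config", "list"))
}

#' Read / write a run configuration (YAML or JSON by extension)
#'
#' Unknown fields raise an error naming the offending path; missing
#' fields take their defaults. `write_run_config(read_run_config(path))`
#' is idempotent.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config`: a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unrecognized config format (use .yaml or .json): ", path)
  validate_config(raw)
}

validate_config <- function(raw, defaults = default_config()) {
  check <- function(given, def, where) {
    extra <- setdiff(names(given), names(def))
    if (length(extra))
      stop("unknown configuration field", if (length(extra) > 1) "s",
           ": ", paste0(where, extra, collapse = ", "))
    for (nm in names(given))
      if (is.list(def[[nm]]) && is.list(given[[nm]]))
        check(given[[nm]], def[[nm]], paste0(where, nm, "."))
  }
  check(raw, defaults, "")
  out <- utils::modifyList(defaults, raw, keep.null = TRUE)
  class(out) <- c("run_config", "list")
  out
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  plain <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path)
  else if (grepl("\\.json$", path))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else stop("unrecognized config format (use .yaml or .json): ", path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Drives [age_report()] from a `run_config`; when `output_dir` is set,
#' writes the metrics, correlations, PWV and pressure tables as CSV, the
#' run report as JSON, and a provenance block (package version, R
#' version, configuration echo, convergence residuals).
#'
#' @param config a `run_config` (see [default_config()]).
#' @return the [age_report()] result, invisibly when writing files.
#' @export
run_pipeline <- function(config = default_config()) {
  set.seed(config$seed)
  tree_len <- config$geometry$trunk_length_m
  straight <- config$geometry$straight_distance_m
  if (identical(config$geometry$source, "vtk")) {
    cl <- read_centerline_vtk(config$geometry$vtk_path)
    main <- cl$lines[[which.max(vapply(cl$lines, `[[`, 0, "arc_length"))]]
    tree_len <- main$arc_length
    straight <- sqrt(sum((main$points[nrow(main$points), ] -
                          main$points[1, ])^2))
  }
  inflow <- generate_inflow(inflow_spec(
    mean_flow_lmin = config$inflow$mean_flow_lmin,
    heart_rate = config$inflow$heart_rate_bpm,
    systolic_fraction = config$inflow$systolic_fraction,
    reverse_fraction = config$inflow$reverse_fraction))
  sc <- solver_config(dx = config$solver$dx_m, cfl = config$solver$cfl,
                      min_cycles = config$solver$min_cycles,
                      max_cycles = config$solver$max_cycles,
                      tol_mmHg = config$solver$tol_mmHg,
                      rho = config$solver$rho_kgm3,
                      mu = config$solver$mu_pas)
  rep <- age_report(ages = config$ages, inflow = inflow, config = sc,
                    damping = config$calibration$damping)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) utils::write.csv(
      df, file.path(config$output_dir, f), row.names = FALSE)
    w(rep$metrics, "metrics.csv")
    w(rep$pwv, "pwv.csv")
    w(rep$pressures, "pressures.csv")
    w(rep$correlations$spatial, "correlation_spatial.csv")
    w(rep$correlations$temporal, "correlation_temporal.csv")
    prov <- list(
      package = "aortapulse",
      version = as.character(utils::packageVersion("aortapulse")),
      r_version = R.version.string,
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      convergence = lapply(rep$solutions, function(s)
        list(cycles = s$cycles, converged = s$converged,
             residual_mmHg = pa_to_mmHg(s$resid[length(s$resid)]))),
      support = lapply(rep$runs, function(r)
        list(k_s = as.list(r$support$k_s), c_s = as.list(r$support$c_s),
             pwv = r$support$pwv, wk_scale = r$wk_scale)))
    jsonlite::write_json(prov,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
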