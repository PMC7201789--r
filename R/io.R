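#' Write or read a simulation trace CSV
#'
#' The on-disk schema is versioned in a leading comment line
#' (`# apsafe-trace v1 period=<min>`), followed by a standard CSV with the
#' [simulate_patient()] columns.
#'
#' @param trace A trace data frame.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv` the
#'   trace with its sampling period restored.
#' @export
write_trace_csv <- function(trace, path) {
  period <- trace_period(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# apsafe-trace v1 period=%g", period), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^# apsafe-trace v1 period=([0-9.]+)$",
                                  header))[[1L]]
  if (length(m) != 2L)
    stop("not an apsafe trace file (bad header): ", path)
  tr <- utils::read.csv(path, comment.char = "#")
  needed <- c("time_min", "G", "G_rf", "u_d", "bolus", "IOB_hat", "IOB_bar",
              "arm", "patient_id")
  missing <- setdiff(needed, names(tr))
  if (length(missing))
    stop("trace file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  attr(tr, "sample_period") <- as.numeric(m[2L])
  class(tr) <- c("sim_trace", "data.frame")
  tr
}

#' Default run configuration
#'
#' The full default configuration block: controller gains and references,
#' SAFE layer, DRB tuner thresholds and gains, IOB kinetics, and simulation
#' settings. All values can be overridden field-by-field in a JSON or YAML
#' config file.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    controller = list(kp_tdi_divisor = 2250, td = 90, g_r = 100,
                      gamma = 0.42, k_ifb = 0.05),
    safe = list(tau = 10, W = 350, lambda = 0.1),
    drb = list(g_trigger = 150, g_release = 140, t_iob_slope = 1.5,
               day_gain = 1.3, night_gain = 1.1,
               day_start = "06:00", night_start = "23:00"),
    iob = list(k_dia = 0.013),
    simulation = list(sample_period = 5, cgm_sd = 0)
  )
}

#' Read a configuration file (JSON or YAML)
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file, or `NULL` for pure
#'   defaults.
#' @return A config list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(cfg, user)
}

#' Write a configuration file
#'
#' @param cfg A config list.
#' @param path Destination (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

# build parameter objects from a config list
config_params <- function(cfg) {
  list(
    sparams = safe_params(tau = cfg$safe$tau, W = cfg$safe$W,
                          lambda = cfg$safe$lambda),
    dparams = drb_params(g_trigger = cfg$drb$g_trigger,
                         g_release = cfg$drb$g_release,
                         t_iob_slope = cfg$drb$t_iob_slope,
                         schedule = kiob_schedule(cfg$drb$day_gain,
                                                  cfg$drb$night_gain,
                                                  cfg$drb$day_start,
                                                  cfg$drb$night_start)),
    iparams = iob_params(k_dia = cfg$iob$k_dia)
  )
}

#' Write a run manifest
#'
#' Records everything needed for a bit-identical re-run: seed, scenario,
#' arms, cohort size, config, package version, and any per-run failures.
#'
#' @param path Destination JSON path.
#' @param seed,scenario_name,arms,n_patients,days Run identification.
#' @param cfg Config list used.
#' @param failures Data frame of failed runs.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, scenario_name, arms, n_patients, days,
                           cfg, failures = NULL) {
  man <- list(package = "apsafe",
              version = as.character(utils::packageVersion("apsafe")),
              seed = seed, scenario = scenario_name, arms = arms,
              n_patients = n_patients, days = days, config = cfg,
              failures = if (is.null(failures) || nrow(failures) == 0)
                list() else failures)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
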