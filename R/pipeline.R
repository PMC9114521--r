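# Run configuration, trace I/O, and group-comparison reporting.
#
# Configuration files are YAML or JSON with a fixed schema; unknown keys are
# rejected by name. Quantities that practitioners quote in bench units accept
# unit-suffixed strings (conductivity "50 uS/cm", frequency "12 MHz") and are
# stored in SI. Trace and result files are comma-separated UTF-8 text with a
# header and "." decimal separator; files carry full precision and rounding
# happens only at presentation.

#' Default run configuration
#'
#' The fully-populated configuration a minimal file is merged into. Sections:
#' `dielectrics` (particle/medium), `electrical` (voltage, frequency),
#' `device` (geometry, see [device_geometry_defaults()]), `controller`
#' (see [controller_config()]), `populations`, `analysis`
#' (stress mode, calibration pair, histogram bins, estimator), and `seed`.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    dielectrics = list(
      particle = list(eps_rel = 60, sigma = 0.01, radius = 7.5e-6),
      medium = list(eps_rel = 78, sigma = 0.005)
    ),
    electrical = list(voltage_vpp = 10, frequency = 12e6),
    device = device_geometry_defaults(),
    controller = list(
      capture_count_threshold = 10L, stretch_duration_s = 10,
      voltage_vpp = 10, frequency_hz = 12e6, capture_flow_ul_h = 3,
      release_flow_ul_min = 150, frame_rate_fps = 50,
      release_count_target = 0L, release_efficiency = 1.0,
      max_capture_attempts = 20L, capture_attempt_period_s = 15,
      release_duration_s = 5
    ),
    populations = list(
      normal = list(mean_strain = 0.0864, cv_strain = 0.35,
                    mean_length_um = 16, sd_length_um = 1.5,
                    noise_sd_um = 0.05, p_broken = 0.02, tau_s = 2),
      treated = list(mean_strain = 0.1013, cv_strain = 0.35,
                     mean_length_um = 16, sd_length_um = 1.5,
                     noise_sd_um = 0.05, p_broken = 0.02, tau_s = 2)
    ),
    analysis = list(
      stress_mode = "calibration",      # or "physics"
      reference_modulus_pa = 203.7,
      reference_strain = 0.0864,
      n_geom = NA_real_,                # physics mode only
      bin_width = 0.03,
      hist_upper = 0.18,
      estimator = "minmax",
      broken_fraction = 0.5
    )
  )
}

parse_quantity <- function(x, kind, key) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("config key `", key, "` must be numeric or a unit string",
         call. = FALSE)
  }
  m <- regmatches(x, regexec("^\\s*([-0-9.eE+]+)\\s*([A-Za-zu/%]*)\\s*$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse quantity `", x, "` for config key `", key, "`",
         call. = FALSE)
  }
  val <- as.numeric(m[2])
  unit <- m[3]
  conv <- switch(kind,
    conductivity = c("S/m" = 1, "mS/m" = 1e-3, "uS/cm" = 1e-4,
                     "µS/cm" = 1e-4),
    frequency = c("Hz" = 1, "kHz" = 1e3, "MHz" = 1e6, "GHz" = 1e9),
    voltage = c("V" = 1, "mV" = 1e-3),
    stop("unknown quantity kind ", kind, call. = FALSE))
  if (!unit %in% names(conv)) {
    stop("unsupported unit `", unit, "` for config key `", key,
         "` (expected one of: ", paste(names(conv), collapse = ", "), ")",
         call. = FALSE)
  }
  val * unname(conv[unit])
}

# internal: recursive merge with unknown-key rejection
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown config key `", full, "`", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop("config key `", full, "` must be a section", call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (by file extension), merges over [default_config()],
#' rejects unknown keys by full name, and applies unit conversions
#' (conductivities may be given as e.g. `"50 uS/cm"`, frequencies as
#' `"12 MHz"`).
#'
#' @param path configuration file.
#' @return validated nested list (class `run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  cfg <- merge_config(default_config(), raw)
  cfg$dielectrics$particle$sigma <-
    parse_quantity(cfg$dielectrics$particle$sigma, "conductivity",
                   "dielectrics.particle.sigma")
  cfg$dielectrics$medium$sigma <-
    parse_quantity(cfg$dielectrics$medium$sigma, "conductivity",
                   "dielectrics.medium.sigma")
  cfg$electrical$frequency <-
    parse_quantity(cfg$electrical$frequency, "frequency",
                   "electrical.frequency")
  cfg$electrical$voltage_vpp <-
    parse_quantity(cfg$electrical$voltage_vpp, "voltage",
                   "electrical.voltage_vpp")
  cfg$controller$frequency_hz <-
    parse_quantity(cfg$controller$frequency_hz, "frequency",
                   "controller.frequency_hz")
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read length traces from delimited text
#'
#' Long-format CSV with a header and required columns `cell_id`, `time_s`,
#' `length_um` (optional `group`, `batch`). Rows with non-numeric time or
#' length are rejected individually and reported with their file line
#' numbers.
#'
#' @param path CSV file.
#' @return `data.frame` of validated traces; rejected line numbers in
#'   attribute `"rejected_lines"`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = TRUE,
             fileEncoding = "UTF-8"),
    error = function(e) stop("cannot read `", path, "`: ",
                             conditionMessage(e), call. = FALSE))
  required <- c("cell_id", "time_s", "length_um")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("trace file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(raw)) stop("trace file `", path, "` contains no rows",
                       call. = FALSE)
  time_s <- suppressWarnings(as.numeric(raw$time_s))
  length_um <- suppressWarnings(as.numeric(raw$length_um))
  bad <- which(is.na(time_s) | is.na(length_um) | !nzchar(raw$cell_id))
  if (length(bad)) {
    warning("rejected ", length(bad), " malformed row(s) at file line(s) ",
            paste(bad + 1L, collapse = ", "))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  if (!length(keep)) stop("no valid rows in `", path, "`", call. = FALSE)
  out <- data.frame(cell_id = raw$cell_id[keep], time_s = time_s[keep],
                    length_um = length_um[keep], stringsAsFactors = FALSE)
  for (opt in c("group", "batch")) {
    if (opt %in% names(raw)) out[[opt]] <- raw[[opt]][keep]
  }
  attr(out, "rejected_lines") <- bad + 1L
  out
}

#' Write traces or per-cell results to delimited text
#'
#' Plain CSV, header, UTF-8, full precision (rounding is presentation-only).
#' A write-then-read round trip reproduces the numeric values.
#'
#' @param path output file.
#' @param x `data.frame` to write.
#' @return the path, invisibly.
#' @export
write_results <- function(path, x) {
  stopifnot(is.data.frame(x))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results
#' @export
write_traces <- write_results

#' Write a run manifest
#'
#' JSON record of the effective configuration, seed, package version and R
#' version, so that any results file can be traced to the run that produced
#' it.
#'
#' @param path output JSON file.
#' @param config the effective configuration list.
#' @param seed the run seed.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, config, seed) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    seed = seed,
    package = "depmech",
    package_version = as.character(utils::packageVersion("depmech")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' Compare two analyzed groups
#'
#' Descriptive comparison of two per-cell result tables (from
#' [analyze_traces()]): per-group n, mean/median strain, central 75%
#' interval, mean modulus, their deltas, the interval-proportion table, and
#' itemized quality-control exclusions. Significance testing is deliberately
#' left to the user (a hook, not a hidden default).
#'
#' @param results_a,results_b result `data.frame`s from [analyze_traces()].
#' @param labels length-2 character, group display labels.
#' @param bin_width,hist_upper histogram options for
#'   [strain_interval_proportions()].
#' @return object of class `comparison_report`.
#' @export
compare_groups <- function(results_a, results_b, labels = NULL,
                           bin_width = 0.03, hist_upper = 0.18) {
  grp <- function(res, fallback) {
    if (!is.null(res$group) && any(!is.na(res$group))) {
      unique(res$group[!is.na(res$group)])[1]
    } else fallback
  }
  if (is.null(labels)) {
    labels <- c(grp(results_a, "group_a"), grp(results_b, "group_b"))
  }
  summarize <- function(res, label) {
    ok <- res[res$qc_flag == "ok", , drop = FALSE]
    if (!nrow(ok)) {
      stop("group `", label, "` is empty after QC; exclusions: ",
           paste(sprintf("%s=%d", names(table(res$qc_flag)),
                         table(res$qc_flag)), collapse = ", "),
           call. = FALSE)
    }
    s <- population_summary(ok$strain)
    list(label = label, n_input = nrow(res), n_ok = nrow(ok),
         exclusions = as.list(table(res$qc_flag[res$qc_flag != "ok"])),
         mean_strain = s$mean, median_strain = s$median,
         strain_central75 = c(s$lower_12.5, s$upper_87.5),
         mean_modulus_pa = mean(ok$modulus_pa),
         proportions = strain_interval_proportions(ok$strain, bin_width,
                                                   hist_upper))
  }
  a <- summarize(results_a, labels[1])
  b <- summarize(results_b, labels[2])
  structure(list(
    groups = list(a, b),
    delta = list(
      mean_strain = b$mean_strain - a$mean_strain,
      median_strain = b$median_strain - a$median_strain,
      mean_modulus_pa = b$mean_modulus_pa - a$mean_modulus_pa
    ),
    bin_width = bin_width, hist_upper = hist_upper
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (g in x$groups) {
    cat(sprintf(
      "  %-12s n=%d (ok %d)  mean strain %.4f  median %.4f  75%% [%.4f, %.4f]  mean E %.1f Pa\n",
      g$label, g$n_input, g$n_ok, g$mean_strain, g$median_strain,
      g$strain_central75[1], g$strain_central75[2], g$mean_modulus_pa))
  }
  cat(sprintf("  delta: mean strain %+.4f, median %+.4f, mean E %+.1f Pa\n",
              x$delta$mean_strain, x$delta$median_strain,
              x$delta$mean_modulus_pa))
  invisible(x)
}
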