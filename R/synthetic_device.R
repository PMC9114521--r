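# Synthetic device and controller simulator.
#
# Stands in for the physical chip so every pipeline stage is testable without
# measurements: stochastic per-port capture keyed by the narrow-mouth size,
# saturating-exponential stretch traces sampled at video frame rate with
# additive detection noise, and the three-state capture-stretch-release
# controller triggered by cell-count and time thresholds. All randomness runs
# through a single seeded generator per call; the seed is recorded in the
# event log.

#' Per-port capture probability model
#'
#' Probabilities that one attempt round leaves a port empty, single-occupied,
#' or multiple-occupied, keyed by the narrow-mouth size in um. The 6 um mouth
#' carries the measured single-capture efficiency 0.842; the other mouth sizes
#' carry qualitative defaults (narrower mouths miss more often, wider mouths
#' multi-capture more often) and are placeholders for user measurements.
#'
#' @param table named list: each entry `list(p_none=, p_single=, p_multiple=)`
#'   summing to 1, keyed by mouth size (`"4"`, `"6"`, ...).
#' @return an object of class `capture_model`.
#' @export
capture_model <- function(table = NULL) {
  if (is.null(table)) {
    table <- list(
      `4` = list(p_none = 0.28, p_single = 0.70, p_multiple = 0.02),
      `6` = list(p_none = 0.10, p_single = 0.842, p_multiple = 0.058),
      `8` = list(p_none = 0.09, p_single = 0.77, p_multiple = 0.14),
      `10` = list(p_none = 0.08, p_single = 0.65, p_multiple = 0.27)
    )
  }
  for (key in names(table)) {
    p <- unlist(table[[key]][c("p_none", "p_single", "p_multiple")])
    if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-9) {
      stop("capture probabilities for mouth ", key,
           " must lie in [0,1] and sum to 1", call. = FALSE)
    }
  }
  structure(list(table = table), class = "capture_model")
}

capture_probs <- function(model, mouth_um) {
  key <- as.character(mouth_um)
  if (!key %in% names(model$table)) {
    stop("no capture probabilities for narrow-mouth size ", key, " um",
         call. = FALSE)
  }
  unlist(model$table[[key]][c("p_none", "p_single", "p_multiple")])
}

#' Simulate one capture round across the port array
#'
#' Independent multinomial draws per port.
#'
#' @param model a [capture_model()].
#' @param n_ports number of ports.
#' @param mouth_um narrow-mouth size key (default 6).
#' @param seed optional seed for reproducibility (global RNG state is
#'   restored afterwards).
#' @return character vector of length `n_ports` with values `"none"`,
#'   `"single"`, `"multiple"`.
#' @export
simulate_capture <- function(model, n_ports, mouth_um = 6, seed = NULL) {
  if (!inherits(model, "capture_model")) {
    stop("`model` must be a capture_model", call. = FALSE)
  }
  p <- capture_probs(model, mouth_um)
  with_seed(seed, sample(c("none", "single", "multiple"), n_ports,
                         replace = TRUE, prob = p))
}

#' Synthetic cell-population model
#'
#' True strains are lognormal with a given mean and coefficient of variation
#' (strains are positive and right-skewed in measured populations); initial
#' lengths are normal; a small fraction of cells break under flow.
#'
#' @param label group label (e.g. `"normal"`, `"treated"`).
#' @param mean_strain population mean of the true strain.
#' @param cv_strain coefficient of variation of the true strain.
#' @param mean_length_um,sd_length_um initial (suspended) cell length, um.
#' @param noise_sd_um per-frame length detection noise, um.
#' @param p_broken probability a cell breaks during the cycle.
#' @param tau_s first-order response time constant of the stretch, s.
#' @return an object of class `population_model`.
#' @export
population_model <- function(label, mean_strain, cv_strain = 0.35,
                             mean_length_um = 16, sd_length_um = 1.5,
                             noise_sd_um = 0.05, p_broken = 0.02,
                             tau_s = 2) {
  if (!is.numeric(mean_strain) || mean_strain <= 0 ||
      !is.numeric(mean_length_um) || mean_length_um <= 0) {
    stop("population means must be positive", call. = FALSE)
  }
  if (cv_strain < 0 || sd_length_um < 0 || noise_sd_um < 0 || tau_s < 0) {
    stop("dispersion parameters must be non-negative", call. = FALSE)
  }
  if (p_broken < 0 || p_broken > 1) {
    stop("`p_broken` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(label = label, mean_strain = mean_strain,
                 cv_strain = cv_strain, mean_length_um = mean_length_um,
                 sd_length_um = sd_length_um, noise_sd_um = noise_sd_um,
                 p_broken = p_broken, tau_s = tau_s),
            class = "population_model")
}

#' Draw synthetic cells from a population model
#'
#' @param model a [population_model()].
#' @param n number of cells (> 0).
#' @param seed optional seed.
#' @return `data.frame` with `cell_id`, `group`, `true_strain`,
#'   `init_length_um`, `broken`.
#' @export
sample_cells <- function(model, n, seed = NULL) {
  if (!inherits(model, "population_model")) {
    stop("`model` must be a population_model", call. = FALSE)
  }
  if (!is.numeric(n) || n < 1L) stop("`n` must be positive", call. = FALSE)
  n <- as.integer(n)
  with_seed(seed, {
    if (model$cv_strain > 0) {
      sdlog <- sqrt(log(1 + model$cv_strain^2))
      meanlog <- log(model$mean_strain) - sdlog^2 / 2
      strain <- rlnorm(n, meanlog, sdlog)
    } else {
      strain <- rep(model$mean_strain, n)
    }
    len <- rnorm(n, model$mean_length_um, model$sd_length_um)
    len <- pmax(len, model$mean_length_um / 4)  # guard against tiny draws
    broken <- runif(n) < model$p_broken
    data.frame(cell_id = sprintf("%s_%05d", model$label, seq_len(n)),
               group = model$label, true_strain = strain,
               init_length_um = len, broken = broken,
               stringsAsFactors = FALSE)
  })
}

#' Controller configuration
#'
#' Operating parameters of the three-state automation: capture at low flow
#' until enough single cells are trapped, a fixed-duration DEP stretch, and a
#' high-flow release.
#'
#' @param capture_count_threshold single-cell count triggering the stretch
#'   state.
#' @param stretch_duration_s stretch-state duration, s.
#' @param voltage_vpp stretch voltage, V peak-to-peak.
#' @param frequency_hz stretch frequency, Hz.
#' @param capture_flow_ul_h capture-state inlet flow, uL/h.
#' @param release_flow_ul_min release-state buffer flow, uL/min.
#' @param frame_rate_fps camera frame rate during stretch, frames/s.
#' @param release_count_target remaining-cell count ending the release state.
#' @param release_efficiency per-cell release probability per cycle.
#' @param max_capture_attempts cap on capture rounds per cycle.
#' @param capture_attempt_period_s wall time per capture round, s.
#' @param release_duration_s wall time of the release state, s.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(capture_count_threshold = 10L,
                              stretch_duration_s = 10,
                              voltage_vpp = 10,
                              frequency_hz = 12e6,
                              capture_flow_ul_h = 3,
                              release_flow_ul_min = 150,
                              frame_rate_fps = 50,
                              release_count_target = 0L,
                              release_efficiency = 1.0,
                              max_capture_attempts = 20L,
                              capture_attempt_period_s = 15,
                              release_duration_s = 5) {
  pos <- c(capture_count_threshold, stretch_duration_s, voltage_vpp,
           frequency_hz, capture_flow_ul_h, release_flow_ul_min,
           frame_rate_fps, max_capture_attempts, capture_attempt_period_s,
           release_duration_s)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("controller parameters must be positive", call. = FALSE)
  }
  if (release_count_target < 0) {
    stop("`release_count_target` must be >= 0", call. = FALSE)
  }
  if (release_efficiency < 0 || release_efficiency > 1) {
    stop("`release_efficiency` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    capture_count_threshold = as.integer(capture_count_threshold),
    stretch_duration_s = stretch_duration_s, voltage_vpp = voltage_vpp,
    frequency_hz = frequency_hz, capture_flow_ul_h = capture_flow_ul_h,
    release_flow_ul_min = release_flow_ul_min, frame_rate_fps = frame_rate_fps,
    release_count_target = as.integer(release_count_target),
    release_efficiency = release_efficiency,
    max_capture_attempts = as.integer(max_capture_attempts),
    capture_attempt_period_s = capture_attempt_period_s,
    release_duration_s = release_duration_s
  ), class = "controller_config")
}

#' Simulate one stretch trace
#'
#' Intact cells follow the saturating first-order response
#' `L(t) = L0 (1 + strain (1 - exp(-t / tau)))` plus Gaussian frame noise,
#' sampled at the frame rate for the stretch duration (inclusive endpoints:
#' `duration * fps + 1` samples). Broken cells instead emit a collapsing
#' trace: the length drops to a small fraction of L0 at a random time and
#' stays there.
#'
#' @param cell one-row `data.frame` as produced by [sample_cells()].
#' @param config a [controller_config()].
#' @param noise_sd_um frame noise sd, um.
#' @param tau_s response time constant, s.
#' @param t0_s absolute start time of the stretch phase, s.
#' @param seed optional seed.
#' @return long-format `data.frame` with `cell_id`, `time_s` (absolute),
#'   `length_um`, `group`.
#' @export
simulate_stretch_trace <- function(cell, config, noise_sd_um = 0.05,
                                   tau_s = 2, t0_s = 0, seed = NULL) {
  stopifnot(inherits(config, "controller_config"))
  t <- seq(0, config$stretch_duration_s, by = 1 / config$frame_rate_fps)
  with_seed(seed, {
    if (isTRUE(cell$broken)) {
      t_break <- runif(1, 0.05, config$stretch_duration_s * 0.8)
      base <- cell$init_length_um *
        ifelse(t < t_break, 1 + cell$true_strain * (1 - exp(-t / max(tau_s, 1e-9))),
               0.3)
    } else {
      base <- cell$init_length_um *
        (1 + cell$true_strain * (1 - exp(-t / max(tau_s, 1e-9))))
    }
    noise <- if (noise_sd_um > 0) rnorm(length(t), 0, noise_sd_um) else 0
    len <- pmax(base + noise, 0.05)
    data.frame(cell_id = cell$cell_id, time_s = t0_s + t, length_um = len,
               group = cell$group, stringsAsFactors = FALSE)
  })
}

#' Run capture-stretch-release cycles
#'
#' Simulates the full three-state automation: per cycle, capture rounds are
#' drawn for the empty ports until the single-cell count reaches the
#' threshold (or the attempt cap), then a stretch phase of exactly the
#' configured duration emits one trace per single-occupied port, then the
#' release state clears each occupied port with the configured efficiency.
#' Ports holding multiple cells are blocked but excluded from measurement.
#'
#' @param config a [controller_config()].
#' @param capture a [capture_model()].
#' @param population a [population_model()].
#' @param n_cycles number of cycles.
#' @param n_ports ports in the array (default 20).
#' @param mouth_um narrow-mouth size key.
#' @param seed seed for the run (single generator; recorded in the log).
#' @param emit_traces set `FALSE` to skip trace synthesis (state-machine and
#'   occupancy bookkeeping only).
#' @return object of class `event_log`: `events` (cycle, state, entry time),
#'   `occupancy` (per cycle and port), `traces` (long format), `measured`
#'   (cells measured per cycle), `seed`, `config`, and the achieved
#'   throughput in cells/min.
#' @export
run_cycles <- function(config, capture, population, n_cycles,
                       n_ports = 20L, mouth_um = 6, seed = 1L,
                       emit_traces = TRUE) {
  stopifnot(inherits(config, "controller_config"),
            inherits(capture, "capture_model"),
            inherits(population, "population_model"))
  if (config$capture_count_threshold > n_ports) {
    stop("capture_count_threshold exceeds the number of ports: unreachable",
         call. = FALSE)
  }
  p <- capture_probs(capture, mouth_um)
  with_seed(seed, {
    t_now <- 0
    events <- vector("list", 3L * n_cycles)
    occup <- vector("list", n_cycles)
    traces <- vector("list", n_cycles)
    measured <- integer(n_cycles)
    occ <- rep("none", n_ports)
    ev <- 0L
    for (cy in seq_len(n_cycles)) {
      # --- capture state
      ev <- ev + 1L
      events[[ev]] <- data.frame(cycle = cy, state = "capture", time_s = t_now)
      attempts <- 0L
      repeat {
        attempts <- attempts + 1L
        empty <- which(occ == "none")
        if (length(empty)) {
          occ[empty] <- sample(c("none", "single", "multiple"),
                               length(empty), replace = TRUE, prob = p)
        }
        if (sum(occ == "single") >= config$capture_count_threshold ||
            attempts >= config$max_capture_attempts) {
          break
        }
      }
      t_now <- t_now + attempts * config$capture_attempt_period_s
      # --- stretch state
      ev <- ev + 1L
      events[[ev]] <- data.frame(cycle = cy, state = "stretch", time_s = t_now)
      singles <- which(occ == "single")
      measured[cy] <- length(singles)
      occup[[cy]] <- data.frame(cycle = cy, port = seq_len(n_ports),
                                occupancy = occ, stringsAsFactors = FALSE)
      if (emit_traces && length(singles)) {
        cells <- sample_cells(population, length(singles))
        cells$cell_id <- sprintf("%s_c%04d_p%02d", population$label, cy,
                                 singles)
        tr <- lapply(seq_len(nrow(cells)), function(i) {
          simulate_stretch_trace(cells[i, ], config,
                                 noise_sd_um = population$noise_sd_um,
                                 tau_s = population$tau_s, t0_s = t_now)
        })
        traces[[cy]] <- do.call(rbind, tr)
      }
      t_now <- t_now + config$stretch_duration_s
      # --- release state
      ev <- ev + 1L
      events[[ev]] <- data.frame(cycle = cy, state = "release", time_s = t_now)
      occupied <- which(occ != "none")
      released <- occupied[runif(length(occupied)) < config$release_efficiency]
      occ[released] <- "none"
      t_now <- t_now + config$release_duration_s
    }
    events <- do.call(rbind, events[seq_len(ev)])
    all_traces <- if (emit_traces) do.call(rbind, traces) else NULL
    structure(list(
      events = events,
      occupancy = do.call(rbind, occup),
      traces = all_traces,
      measured = measured,
      seed = seed,
      config = config,
      total_time_s = t_now,
      throughput_cells_per_min = sum(measured) / (t_now / 60)
    ), class = "event_log")
  })
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf(
    "<event_log> %d cycles, %d cells measured, %.1f cells/min (seed %s)\n",
    max(x$events$cycle), sum(x$measured), x$throughput_cells_per_min,
    format(x$seed)))
  invisible(x)
}

#' End-to-end parameter-recovery harness
#'
#' Generates two synthetic populations, synthesizes their stretch traces,
#' runs the full analysis pipeline, and reports recovered group-mean strains
#' and moduli against the generator truth with Monte-Carlo standard errors.
#' Both strain estimators are reported: the definitional min/max rule (which
#' is positively biased under frame noise — the bias of taking a maximum over
#' many noisy samples) and the model-based fit (consistent under the
#' generator's noise model).
#'
#' @param pop_a,pop_b [population_model()] objects.
#' @param n_per_group cells per group.
#' @param config a [controller_config()].
#' @param stress stretching stress, Pa (default calibrated from the normal
#'   reference pair 203.7 Pa at strain 0.0864).
#' @param seed seed.
#' @return object of class `recovery_report`: per group, the truth, the
#'   recovered means under each estimator with standard errors, and the
#'   recovered mean moduli.
#' @export
end_to_end_recovery <- function(pop_a, pop_b, n_per_group, config = NULL,
                                stress = calibrate_stress(203.7, 0.0864),
                                seed = 1L) {
  if (is.null(config)) config <- controller_config()
  with_seed(seed, {
    groups <- list(pop_a, pop_b)
    out <- lapply(groups, function(pop) {
      cells <- sample_cells(pop, n_per_group)
      tr <- lapply(seq_len(nrow(cells)), function(i) {
        simulate_stretch_trace(cells[i, ], config,
                               noise_sd_um = pop$noise_sd_um,
                               tau_s = pop$tau_s)
      })
      traces <- do.call(rbind, tr)
      res_mm <- analyze_traces(traces, stress, estimator = "minmax")
      res_md <- analyze_traces(traces, stress, estimator = "model")
      ok_mm <- res_mm[res_mm$qc_flag == "ok", ]
      ok_md <- res_md[res_md$qc_flag == "ok", ]
      list(
        label = pop$label,
        n = n_per_group,
        n_ok = nrow(ok_mm),
        truth_mean_strain = pop$mean_strain,
        truth_mean_modulus = stress / pop$mean_strain,
        minmax = list(
          mean_strain = mean(ok_mm$strain),
          se_strain = stats::sd(ok_mm$strain) / sqrt(nrow(ok_mm)),
          mean_modulus = mean(ok_mm$modulus_pa)),
        model = list(
          mean_strain = mean(ok_md$strain),
          se_strain = stats::sd(ok_md$strain) / sqrt(nrow(ok_md)),
          mean_modulus = mean(ok_md$modulus_pa)),
        results_minmax = res_mm,
        results_model = res_md
      )
    })
    structure(list(groups = out, stress = stress, seed = seed),
              class = "recovery_report")
  })
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> stress =", x$stress, "Pa\n")
  for (g in x$groups) {
    cat(sprintf(
      "  %s: truth %.4f | minmax %.4f (se %.4f) | model %.4f (se %.4f) [n_ok %d]\n",
      g$label, g$truth_mean_strain, g$minmax$mean_strain, g$minmax$se_strain,
      g$model$mean_strain, g$model$se_strain, g$n_ok))
  }
  invisible(x)
}
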