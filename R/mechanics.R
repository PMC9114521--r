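# Strain and Young's modulus analysis of per-cell length traces.
#
# The device records a length-time trace per trapped cell at video frame rate.
# Strain uses the device's definitional rule: the minimum detected length is
# the initial length L0 and the maximum the final stretched length, so
# strain = (Lmax - L0) / L0 regardless of where min and max occur in time.
# Because stretching stress is not observable per cell, the modulus uses
# either a physics-mode stress (dep_stress) or a stress calibrated from a
# reference (modulus, strain) pair; calibration mode is the default since it
# is the only mode with printed ground truth.

#' Per-cell length trace
#'
#' @param cell_id identifier.
#' @param time_s sampling times in seconds, strictly increasing, length >= 2.
#' @param length_um detected lengths in um, positive and finite.
#' @param group,batch optional metadata labels.
#' @return an object of class `length_trace`.
#' @export
length_trace <- function(cell_id, time_s, length_um, group = NA_character_,
                         batch = NA_character_) {
  if (length(time_s) < 2L) {
    stop("invalid trace: fewer than 2 samples", call. = FALSE)
  }
  if (length(time_s) != length(length_um)) {
    stop("`time_s` and `length_um` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(time_s)) || any(diff(time_s) <= 0)) {
    stop("`time_s` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(length_um)) || any(length_um <= 0)) {
    stop("`length_um` must be positive and finite", call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id), time_s = time_s,
                 length_um = length_um, group = group, batch = batch),
            class = "length_trace")
}

#' Strain from a length trace (min/max rule)
#'
#' `L0 = min(lengths)`, `Lmax = max(lengths)`,
#' `strain = (Lmax - L0) / L0`; the temporal order of the extremes is
#' irrelevant and the result is invariant under uniform rescaling of all
#' lengths. Traces containing non-finite lengths are returned invalid with a
#' reason rather than raising.
#'
#' @param trace a [length_trace()], or a list/data.frame with `time_s` and
#'   `length_um` (and optionally `cell_id`).
#' @return one-row `data.frame`: `cell_id`, `L0_um`, `Lmax_um`, `strain`,
#'   `valid`, `reason` (`"ok"`, `"zero-strain"` for a constant trace, or the
#'   rejection reason).
#' @examples
#' strain_from_trace(length_trace("a", c(0, 1), c(20, 21.728)))$strain # 0.0864
#' @export
strain_from_trace <- function(trace) {
  cell_id <- if (!is.null(trace$cell_id)) as.character(trace$cell_id[1]) else NA
  len <- trace$length_um
  if (is.null(len) || length(len) < 2L) {
    stop("invalid trace: fewer than 2 samples", call. = FALSE)
  }
  if (any(!is.finite(len)) || any(len[is.finite(len)] <= 0)) {
    return(data.frame(cell_id = cell_id, L0_um = NA_real_, Lmax_um = NA_real_,
                      strain = NA_real_, valid = FALSE,
                      reason = "non-finite or non-positive length",
                      stringsAsFactors = FALSE))
  }
  L0 <- min(len)
  Lmax <- max(len)
  strain <- (Lmax - L0) / L0
  data.frame(cell_id = cell_id, L0_um = L0, Lmax_um = Lmax, strain = strain,
             valid = TRUE, reason = if (strain == 0) "zero-strain" else "ok",
             stringsAsFactors = FALSE)
}

#' Calibrate the stretching stress from a reference pair
#'
#' Inverts `E = sigma / epsilon`: a reference Young's modulus and strain give
#' the (shared) stretching stress `sigma = E_ref * strain_ref`. The measured
#' modulus-strain products of the two untreated reference populations agree to
#' four significant figures (17.59968 Pa vs 17.59932 Pa), consistent with a
#' single device-level stress.
#'
#' @param E_ref reference modulus, Pa.
#' @param strain_ref reference strain (> 0).
#' @return stress in Pa.
#' @examples
#' calibrate_stress(203.7, 0.0864)  # 17.59968 Pa
#' @export
calibrate_stress <- function(E_ref, strain_ref) {
  if (!is.numeric(strain_ref) || any(!is.finite(strain_ref)) ||
      any(strain_ref <= 0)) {
    stop("`strain_ref` must be positive and finite", call. = FALSE)
  }
  E_ref * strain_ref
}

#' Young's modulus result for one cell
#'
#' @param strain dimensionless strain (> 0 for a measurable cell).
#' @param stress stress in Pa.
#' @param cell_id optional identifier.
#' @return one-row `data.frame` with `cell_id`, `strain`, `stress_pa`,
#'   `modulus_pa`; `modulus_pa` is `NA` (cell unmeasurable) when
#'   `strain <= 0`.
#' @export
modulus_from_strain <- function(strain, stress, cell_id = NA_character_) {
  modulus <- ifelse(is.finite(strain) & strain > 0, stress / strain, NA_real_)
  data.frame(cell_id = cell_id, strain = strain, stress_pa = stress,
             modulus_pa = modulus, stringsAsFactors = FALSE)
}

#' Model-based strain estimate from a noisy trace
#'
#' Fits the saturating first-order response
#' `L(t) = L0 (1 + strain (1 - exp(-t / tau)))` by linear least squares in
#' `(L0, L0 * strain)` profiled over `tau` (golden-section search on
#' `log(tau)`). Unlike the min/max rule, this estimator is unbiased under
#' additive frame noise because the noise averages out over the trace.
#'
#' @param trace a [length_trace()] or list with `time_s`, `length_um`.
#' @param tau_bounds search interval for the response time constant, s.
#' @return list with `L0_um`, `strain`, `tau_s`, `rss`.
#' @export
fit_stretch_response <- function(trace, tau_bounds = NULL) {
  t <- trace$time_s - trace$time_s[1]  # response clock starts at stretch onset
  y <- trace$length_um
  if (length(t) < 4L) stop("model fit needs at least 4 samples", call. = FALSE)
  if (is.null(tau_bounds)) tau_bounds <- c(max(t) / 500, 4 * max(t))
  X1 <- rep(1, length(t))
  rss_at <- function(log_tau) {
    basis <- 1 - exp(-t / exp(log_tau))
    fit <- stats::.lm.fit(cbind(X1, basis), y)
    sum(fit$residuals^2)
  }
  opt <- optimize(rss_at, interval = log(tau_bounds))
  tau <- exp(opt$minimum)
  fit <- stats::.lm.fit(cbind(X1, 1 - exp(-t / tau)), y)
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  list(L0_um = a, strain = b / a, tau_s = tau, rss = opt$objective)
}

#' Analyze a set of length traces into strain and modulus results
#'
#' Runs per-cell strain estimation and modulus computation with quality
#' control: traces whose length collapses below `broken_fraction` of the
#' starting value are flagged broken (lysed/lost cells), and cells with zero
#' or negative strain are flagged unmeasurable; both are excluded from group
#' statistics but itemized in the output.
#'
#' @param traces long-format `data.frame` with columns `cell_id`, `time_s`,
#'   `length_um` and optional `group`, `batch`.
#' @param stress stretching stress in Pa (e.g. from [calibrate_stress()] or
#'   [dep_stress()]).
#' @param estimator `"minmax"` (the definitional rule; default) or `"model"`
#'   (saturating-exponential fit, [fit_stretch_response()]).
#' @param broken_fraction a trace is broken when `min(length)` falls below
#'   this fraction of its first sample.
#' @return `data.frame` with one row per cell: `cell_id`, `group`, `batch`,
#'   `n_frames`, `L0_um`, `Lmax_um`, `strain`, `stress_pa`, `modulus_pa`,
#'   `qc_flag` (`"ok"`, `"broken"`, `"nonpositive_strain"`, `"invalid"`).
#' @export
analyze_traces <- function(traces, stress, estimator = c("minmax", "model"),
                           broken_fraction = 0.5) {
  estimator <- match.arg(estimator)
  required <- c("cell_id", "time_s", "length_um")
  if (!is.data.frame(traces) || !all(required %in% names(traces))) {
    stop("`traces` must contain columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(traces)) stop("`traces` is empty", call. = FALSE)
  has_group <- "group" %in% names(traces)
  has_batch <- "batch" %in% names(traces)
  pieces <- split(traces, traces$cell_id)
  rows <- lapply(pieces, function(tr) {
    tr <- tr[order(tr$time_s), , drop = FALSE]
    out <- data.frame(
      cell_id = as.character(tr$cell_id[1]),
      group = if (has_group) as.character(tr$group[1]) else NA_character_,
      batch = if (has_batch) as.character(tr$batch[1]) else NA_character_,
      n_frames = nrow(tr), L0_um = NA_real_, Lmax_um = NA_real_,
      strain = NA_real_, stress_pa = stress, modulus_pa = NA_real_,
      qc_flag = "invalid", stringsAsFactors = FALSE)
    if (nrow(tr) < 2L || any(!is.finite(tr$length_um)) ||
        any(tr$length_um <= 0, na.rm = TRUE)) {
      return(out)
    }
    sr <- strain_from_trace(tr)
    out$L0_um <- sr$L0_um
    out$Lmax_um <- sr$Lmax_um
    strain <- sr$strain
    if (estimator == "model" && nrow(tr) >= 4L) {
      strain <- fit_stretch_response(tr)$strain
    }
    out$strain <- strain
    if (min(tr$length_um) < broken_fraction * tr$length_um[1]) {
      out$qc_flag <- "broken"
    } else if (!is.finite(strain) || strain <= 0) {
      out$qc_flag <- "nonpositive_strain"
    } else {
      out$qc_flag <- "ok"
      out$modulus_pa <- stress / strain
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Proportions of cells per strain interval
#'
#' Half-open bins `[lo, hi)` of a fixed width from 0 up to `upper`, plus an
#' overflow bin `[upper, Inf)`; proportions over all input strains sum to 1.
#' This is the interval-proportion histogram used to compare populations.
#'
#' @param strains numeric vector of strains (non-empty).
#' @param bin_width bin width (default 0.03).
#' @param upper start of the overflow bin (default 0.18).
#' @return `data.frame` with `lower`, `upper`, `count`, `proportion`; the last
#'   row is the overflow bin.
#' @export
strain_interval_proportions <- function(strains, bin_width = 0.03,
                                        upper = 0.18) {
  if (!length(strains) || any(!is.finite(strains))) {
    stop("`strains` must be a non-empty finite vector", call. = FALSE)
  }
  if (bin_width <= 0 || upper <= 0) {
    stop("`bin_width` and `upper` must be positive", call. = FALSE)
  }
  lo <- seq(0, upper - bin_width, by = bin_width)
  hi <- lo + bin_width
  counts <- vapply(seq_along(lo), function(k) {
    sum(strains >= lo[k] & strains < hi[k])
  }, numeric(1))
  overflow <- sum(strains >= upper)
  below <- sum(strains < 0)
  # negative strains cannot occur from the min/max rule; count them under 0
  counts[1] <- counts[1] + below
  data.frame(lower = c(lo, upper), upper = c(hi, Inf),
             count = c(counts, overflow),
             proportion = c(counts, overflow) / length(strains))
}

#' Population summary: n, mean, median, central 75% interval
#'
#' The central 75% interval is the (12.5th, 87.5th) percentile pair of the
#' data, the inter-quantile band drawn as the box in the population charts.
#'
#' @param values numeric vector (non-empty).
#' @return list with `n`, `mean`, `median`, `lower_12.5`, `upper_87.5`.
#' @export
population_summary <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("`values` must be non-empty", call. = FALSE)
  qs <- unname(quantile(values, c(0.125, 0.875)))
  list(n = length(values), mean = mean(values), median = median(values),
       lower_12.5 = qs[1], upper_87.5 = qs[2])
}
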