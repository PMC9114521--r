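# DEP electromechanical core: complex permittivity, Clausius-Mossotti factor,
# force, stress, and Young's modulus for a homogeneous dielectric sphere.

#' Dielectric body (particle or suspending medium)
#'
#' A homogeneous dielectric described by its relative permittivity and ohmic
#' conductivity; particles additionally carry a radius. This is the common
#' parameter container for all DEP calculations.
#'
#' @param eps_rel relative permittivity (dimensionless, > 0).
#' @param sigma conductivity in S/m (>= 0).
#' @param radius particle radius in m (> 0), or `NULL` for a medium.
#' @return an object of class `dielectric_body`.
#' @examples
#' buffer <- dielectric_body(eps_rel = 78, sigma = 0.005)   # 50 uS/cm buffer
#' cell   <- dielectric_body(eps_rel = 60, sigma = 0.01, radius = 7.5e-6)
#' @export
dielectric_body <- function(eps_rel, sigma, radius = NULL) {
  if (!is.numeric(eps_rel) || length(eps_rel) != 1L || !is.finite(eps_rel) ||
      eps_rel <= 0) {
    stop("`eps_rel` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single non-negative finite number (S/m)",
         call. = FALSE)
  }
  if (!is.null(radius)) {
    if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
        radius <= 0) {
      stop("`radius` must be a single positive finite number (m)",
           call. = FALSE)
    }
  }
  structure(list(eps_rel = eps_rel, sigma = sigma, radius = radius),
            class = "dielectric_body")
}

#' @export
print.dielectric_body <- function(x, ...) {
  cat("<dielectric_body> eps_rel =", x$eps_rel, ", sigma =", x$sigma, "S/m")
  if (!is.null(x$radius)) cat(", radius =", x$radius, "m")
  cat("\n")
  invisible(x)
}

as_dielectric_body <- function(x, what = "body") {
  if (inherits(x, "dielectric_body")) return(x)
  if (is.list(x) && all(c("eps_rel", "sigma") %in% names(x))) {
    return(dielectric_body(x$eps_rel, x$sigma, x$radius))
  }
  stop("`", what, "` must be a dielectric_body (see dielectric_body())",
       call. = FALSE)
}

check_freq <- function(freq) {
  if (!is.numeric(freq) || length(freq) < 1L || any(!is.finite(freq)) ||
      any(freq <= 0)) {
    stop("`freq` must be positive and finite (Hz)", call. = FALSE)
  }
  freq
}

#' Complex permittivity of a dielectric body
#'
#' Computes `eps* = eps - j sigma / omega` with `omega = 2 pi f` (angular
#' frequency; the standard DEP convention) and `eps = eps_rel * eps0` absolute.
#'
#' @param body a [dielectric_body()].
#' @param freq field frequency in Hz (> 0); may be a vector.
#' @return complex vector, F/m; the imaginary part is always <= 0.
#' @examples
#' complex_permittivity(dielectric_body(78, 0.005), 12e6)
#' @export
complex_permittivity <- function(body, freq) {
  body <- as_dielectric_body(body)
  check_freq(freq)
  complex(real = body$eps_rel * EPS0,
          imaginary = -body$sigma / (2 * pi * freq))
}

#' Clausius-Mossotti factor
#'
#' The complex polarizability contrast of a homogeneous sphere in a medium,
#' `fcm = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*)`. Its real part governs the
#' sign and magnitude of the DEP force and lies in `[-0.5, 1]` for any
#' physically admissible parameters.
#'
#' @param particle,medium [dielectric_body()] objects.
#' @param freq field frequency in Hz (> 0); may be a vector.
#' @return complex vector of the same length as `freq`.
#' @examples
#' cm_factor(dielectric_body(60, 0.01), dielectric_body(78, 0.005), 12e6)
#' @export
cm_factor <- function(particle, medium, freq) {
  particle <- as_dielectric_body(particle, "particle")
  medium <- as_dielectric_body(medium, "medium")
  ep <- complex_permittivity(particle, freq)
  em <- complex_permittivity(medium, freq)
  den <- ep + 2 * em
  if (any(Mod(den) == 0)) {
    stop("degenerate Clausius-Mossotti denominator (eps_p* + 2 eps_m* = 0)",
         call. = FALSE)
  }
  (ep - em) / den
}

# Frequency-limit real parts of fcm: conductivity-dominated (f -> 0) and
# permittivity-dominated (f -> infinity).
cm_limits <- function(particle, medium) {
  sp <- particle$sigma; sm <- medium$sigma
  low <- if (sp + 2 * sm > 0) (sp - sm) / (sp + 2 * sm) else NA_real_
  high <- (particle$eps_rel - medium$eps_rel) /
    (particle$eps_rel + 2 * medium$eps_rel)
  if (is.na(low)) low <- high  # both conductivities zero: no dispersion
  c(low = low, high = high)
}

#' DEP regime at a given frequency
#'
#' Classifies the DEP response by the sign of `Re(fcm)`: `"positive"` (p-DEP,
#' attraction toward field maxima), `"negative"` (n-DEP, repulsion), or
#' `"null"` within a zero tolerance.
#'
#' @inheritParams cm_factor
#' @param tol absolute tolerance on `Re(fcm)` treated as zero.
#' @return character scalar (or vector over `freq`).
#' @export
dep_regime <- function(particle, medium, freq, tol = 1e-12) {
  re <- Re(cm_factor(particle, medium, freq))
  out <- ifelse(abs(re) <= tol, "null", ifelse(re > 0, "positive", "negative"))
  out
}

#' Crossover frequency of the DEP spectrum
#'
#' Frequency at which `Re(fcm)` changes sign. For the homogeneous sphere the
#' closed form is
#' `fc = (1/2pi) sqrt(-[(sp - sm)(sp + 2 sm)] / [(ep - em)(ep + 2 em)])`
#' (absolute permittivities); a crossover exists only when the low- and
#' high-frequency limits of `Re(fcm)` differ in sign.
#'
#' @inheritParams cm_factor
#' @return crossover frequency in Hz, or `NA_real_` when no sign change
#'   exists (absence is a value, not an error).
#' @export
crossover_frequency <- function(particle, medium) {
  particle <- as_dielectric_body(particle, "particle")
  medium <- as_dielectric_body(medium, "medium")
  lim <- cm_limits(particle, medium)
  if (lim["low"] == 0 || lim["high"] == 0) return(NA_real_)
  if (sign(lim["low"]) == sign(lim["high"])) return(NA_real_)
  sp <- particle$sigma; sm <- medium$sigma
  ep <- particle$eps_rel * EPS0; em <- medium$eps_rel * EPS0
  rad <- -((sp - sm) * (sp + 2 * sm)) / ((ep - em) * (ep + 2 * em))
  if (!is.finite(rad) || rad <= 0) return(NA_real_)
  unname(sqrt(rad) / (2 * pi))
}

#' Time-averaged DEP force on a spherical particle
#'
#' `F = 2 pi r^3 eps_m Re(fcm) grad(E_rms^2)` with `eps_m` the absolute medium
#' permittivity. The particle must carry a radius.
#'
#' @inheritParams cm_factor
#' @param grad_E2rms gradient of the squared rms field, V^2/m^3.
#' @return force in N (signed along the field-gradient direction).
#' @export
dep_force <- function(particle, medium, freq, grad_E2rms) {
  particle <- as_dielectric_body(particle, "particle")
  medium <- as_dielectric_body(medium, "medium")
  if (is.null(particle$radius)) {
    stop("`particle` must have a radius to evaluate the DEP force",
         call. = FALSE)
  }
  re_fcm <- Re(cm_factor(particle, medium, freq))
  2 * pi * particle$radius^3 * medium$eps_rel * EPS0 * re_fcm * grad_E2rms
}

#' Stress-model parameters
#'
#' Bundles the geometric constant `n`, reference field strength `E0`, medium
#' and frequency entering the DEP stretching stress
#' `sigma = n Re(fcm) eps_m E0^2`.
#'
#' @param n_geom dimensionless geometric constant (from the field solver).
#' @param E0 reference field strength, V/m (>= 0).
#' @param medium a [dielectric_body()].
#' @param freq field frequency, Hz (> 0).
#' @return an object of class `stress_parameters`.
#' @export
stress_parameters <- function(n_geom, E0, medium, freq) {
  if (!is.numeric(n_geom) || length(n_geom) != 1L || !is.finite(n_geom)) {
    stop("`n_geom` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 < 0) {
    stop("`E0` must be a single non-negative finite number (V/m)",
         call. = FALSE)
  }
  check_freq(freq)
  structure(list(n_geom = n_geom, E0 = E0,
                 medium = as_dielectric_body(medium, "medium"), freq = freq),
            class = "stress_parameters")
}

#' DEP stretching stress on a trapped cell
#'
#' `sigma_stress = n Re(fcm) eps_m E0^2` (Pa), with `eps_m` absolute. The sign
#' follows `Re(fcm)`: stretching requires the p-DEP regime.
#'
#' @param params a [stress_parameters()] object.
#' @param particle the cell's [dielectric_body()].
#' @return stress in Pa.
#' @export
dep_stress <- function(params, particle) {
  if (!inherits(params, "stress_parameters")) {
    stop("`params` must be a stress_parameters object", call. = FALSE)
  }
  re_fcm <- Re(cm_factor(particle, params$medium, params$freq))
  params$n_geom * re_fcm * params$medium$eps_rel * EPS0 * params$E0^2
}

#' Young's modulus from stress and strain
#'
#' `E = sigma / epsilon`. A cell that did not stretch (strain <= 0) is
#' unmeasurable and raises an error rather than returning an infinity.
#'
#' @param stress stress in Pa.
#' @param strain dimensionless strain (> 0).
#' @return modulus in Pa.
#' @examples
#' youngs_modulus(calibrate_stress(203.7, 0.0864), 0.1013)  # 173.7 Pa
#' @export
youngs_modulus <- function(stress, strain) {
  if (!is.numeric(strain) || any(!is.finite(strain)) || any(strain <= 0)) {
    stop("`strain` must be positive and finite: a non-stretched cell is ",
         "unmeasurable", call. = FALSE)
  }
  stress / strain
}

#' Clausius-Mossotti spectrum over a frequency grid
#'
#' Evaluates `fcm` on a (by default log-spaced) frequency grid and reports the
#' crossover frequency, if any. This is the tabular product behind DEP
#' operating-point selection.
#'
#' @inheritParams cm_factor
#' @param freqs frequency grid in Hz; default 200 points from 1 kHz to 1 GHz.
#' @return a `data.frame` with columns `freq_hz`, `re_fcm`, `im_fcm`, carrying
#'   the crossover frequency (Hz or `NA`) as attribute `"crossover_hz"`.
#' @export
cm_spectrum <- function(particle, medium,
                        freqs = 10^seq(3, 9, length.out = 200)) {
  fcm <- cm_factor(particle, medium, freqs)
  out <- data.frame(freq_hz = freqs, re_fcm = Re(fcm), im_fcm = Im(fcm))
  attr(out, "crossover_hz") <- crossover_frequency(particle, medium)
  out
}
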