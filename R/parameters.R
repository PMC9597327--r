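#' Kinetic and composition parameters of the growth model
#'
#' Container for the eight kinetic constants of the Droop-Monod growth and
#' nitrogen-uptake model together with the empirical composition
#' correlations (quota-dependent absorption coefficient, reciprocal
#' quota-TFA law, constant specific EPA content). Defaults are the fitted
#' values for *P. tricornutum* grown in 5 L flat-panel photobioreactors.
#'
#' @param mu_max Maximum specific growth rate, day^-1.
#' @param K_d Biomass decay rate, day^-1.
#' @param Q_min Minimum (subsistence) nitrogen quota, mg N mg^-1 DCW;
#'   growth ceases at `Q = Q_min`.
#' @param Q_max Maximum nitrogen quota, mg N mg^-1 DCW; uptake ceases at
#'   `Q = Q_max`.
#' @param U_max Maximum specific nitrogen uptake rate, mg N mg^-1 DCW day^-1.
#' @param K_N Half-saturation constant for nitrogen uptake, mg N L^-1.
#' @param K_I Half-saturation constant for light, µmol m^-2 s^-1.
#' @param n Hill exponent of the light response, dimensionless (>= 1).
#' @param ka_slope,ka_intercept Linear quota dependence of the biomass
#'   absorption coefficient, `Ka = ka_slope * Q + ka_intercept`
#'   (L mg^-1 m^-1).
#' @param tfa_coeff,tfa_exponent,tfa_offset Reciprocal quota dependence of
#'   the specific TFA content,
#'   `C_TFA = tfa_coeff * Q^(-tfa_exponent) + tfa_offset` (mg g^-1 DCW).
#' @param epa_content Constant specific EPA content, mg g^-1 DCW.
#'
#' @return An object of class `kinetic_parameters` (a validated named list).
#' @seealso [validate_parameters()], [initial_parameter_guess()]
#' @examples
#' p <- kinetic_parameters()          # fitted defaults
#' p$mu_max
#' kinetic_parameters(mu_max = 2.0)   # override one constant
#' @export
kinetic_parameters <- function(mu_max = 2.4,
                               K_d = 0.010,
                               Q_min = 0.034,
                               Q_max = 0.12,
                               U_max = 0.59,
                               K_N = 0.010,
                               K_I = 50,
                               n = 1.9,
                               ka_slope = 2.74,
                               ka_intercept = 0.21,
                               tfa_coeff = 3.68,
                               tfa_exponent = 1.32,
                               tfa_offset = 42.2,
                               epa_content = 55) {
  p <- structure(
    list(mu_max = mu_max, K_d = K_d, Q_min = Q_min, Q_max = Q_max,
         U_max = U_max, K_N = K_N, K_I = K_I, n = n,
         ka_slope = ka_slope, ka_intercept = ka_intercept,
         tfa_coeff = tfa_coeff, tfa_exponent = tfa_exponent,
         tfa_offset = tfa_offset, epa_content = epa_content),
    class = "kinetic_parameters")
  validate_parameters(p)
}

#' Names of the eight fitted kinetic constants
#'
#' The subset of [kinetic_parameters()] fields that are estimated during
#' calibration; the composition-correlation coefficients are held fixed
#' unless refitted with [fit_empirical_correlations()].
#'
#' @return Character vector of field names.
#' @export
kinetic_parameter_names <- function() {
  c("mu_max", "K_d", "Q_min", "Q_max", "U_max", "K_N", "K_I", "n")
}

#' Validate a kinetic parameter set
#'
#' Checks every invariant of the parameter container: strict positivity of
#' all constants, `Q_min < Q_max`, and `n >= 1`. All violations are
#' collected and reported together, by field name.
#'
#' @param p A `kinetic_parameters` object (or a named list with the same
#'   fields).
#' @return `p`, unchanged, invisibly classed as `kinetic_parameters`.
#' @export
validate_parameters <- function(p) {
  required <- c(kinetic_parameter_names(),
                "ka_slope", "ka_intercept", "tfa_coeff", "tfa_exponent",
                "tfa_offset", "epa_content")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0L)
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  problems <- character(0)
  for (f in required) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      problems <- c(problems, sprintf("%s: not a finite scalar", f))
    else if (v <= 0)
      problems <- c(problems, sprintf("%s: must be strictly positive (got %g)", f, v))
  }
  if (is.numeric(p$Q_min) && is.numeric(p$Q_max) &&
      is.finite(p$Q_min) && is.finite(p$Q_max) && p$Q_min >= p$Q_max)
    problems <- c(problems,
                  sprintf("Q_min: must be < Q_max (got Q_min = %g, Q_max = %g)",
                          p$Q_min, p$Q_max),
                  sprintf("Q_max: must be > Q_min (got Q_max = %g, Q_min = %g)",
                          p$Q_max, p$Q_min))
  if (is.numeric(p$n) && is.finite(p$n) && p$n < 1)
    problems <- c(problems, sprintf("n: must be >= 1 (got %g)", p$n))
  if (length(problems) > 0L)
    stop("invalid kinetic parameters:\n  ",
         paste(problems, collapse = "\n  "))
  if (!inherits(p, "kinetic_parameters")) class(p) <- "kinetic_parameters"
  p
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Droop-Monod kinetic parameters\n")
  cat(sprintf("  mu_max %g /d | K_d %g /d | K_I %g umol/m2/s | n %g\n",
              x$mu_max, x$K_d, x$K_I, x$n))
  cat(sprintf("  Q_min %g | Q_max %g mgN/mgDCW | U_max %g | K_N %g mgN/L\n",
              x$Q_min, x$Q_max, x$U_max, x$K_N))
  cat(sprintf("  Ka = %g Q + %g ; C_TFA = %g Q^-%g + %g ; C_EPA = %g mg/g\n",
              x$ka_slope, x$ka_intercept, x$tfa_coeff, x$tfa_exponent,
              x$tfa_offset, x$epa_content))
  invisible(x)
}

#' Reactor geometry and illumination configuration
#'
#' @param geometry `"flat_panel"` (one illuminated face, light path
#'   `path_length_L`) or `"bubble_column"` (three light banks around a
#'   column of radius `radius_R`).
#' @param incident_intensity_Io Incident light intensity per illuminated
#'   face (flat panel) or per light bank (column), µmol m^-2 s^-1.
#' @param path_length_L Light path length of the flat panel, m.
#' @param radius_R Column radius, m.
#' @param photoperiod_light_h Hours of light per 24 h day.
#' @param volume Working volume, L (metadata only; the model is written per
#'   litre and does not use it).
#'
#' @return An object of class `reactor_config`.
#' @examples
#' reactor_config("flat_panel", incident_intensity_Io = 350)
#' reactor_config("bubble_column", incident_intensity_Io = 360,
#'                photoperiod_light_h = 16)
#' @export
reactor_config <- function(geometry = c("flat_panel", "bubble_column"),
                           incident_intensity_Io,
                           path_length_L = 0.05,
                           radius_R = 0.095,
                           photoperiod_light_h = 12,
                           volume = NA_real_) {
  geometry <- match.arg(geometry)
  stopifnot(is.numeric(incident_intensity_Io), incident_intensity_Io >= 0,
            photoperiod_light_h >= 0, photoperiod_light_h <= 24)
  if (geometry == "flat_panel") {
    if (!is.numeric(path_length_L) || path_length_L <= 0)
      stop("path_length_L must be positive for flat_panel geometry")
  } else {
    if (!is.numeric(radius_R) || radius_R <= 0)
      stop("radius_R must be positive for bubble_column geometry")
  }
  structure(
    list(geometry = geometry,
         incident_intensity_Io = incident_intensity_Io,
         path_length_L = if (geometry == "flat_panel") path_length_L else NA_real_,
         radius_R = if (geometry == "bubble_column") radius_R else NA_real_,
         photoperiod_light_h = photoperiod_light_h,
         volume = volume),
    class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  dim <- if (x$geometry == "flat_panel")
    sprintf("L = %g m", x$path_length_L) else sprintf("R = %g m", x$radius_R)
  cat(sprintf("%s reactor: Io = %g umol/m2/s per %s, %s, %g:%g h light:dark\n",
              x$geometry, x$incident_intensity_Io,
              if (x$geometry == "flat_panel") "face" else "bank", dim,
              x$photoperiod_light_h, 24 - x$photoperiod_light_h))
  invisible(x)
}

#' Culture state at a time point
#'
#' @param X Biomass concentration, mg DCW L^-1 (>= 0).
#' @param N Medium nitrogen concentration, mg N L^-1 (>= 0).
#' @param Q Intracellular nitrogen quota, mg N mg^-1 DCW.
#' @param t Time, days.
#' @return An object of class `culture_state`.
#' @export
culture_state <- function(X, N, Q, t = 0) {
  stopifnot(X >= 0, N >= 0, Q > 0)
  structure(list(X = X, N = N, Q = Q, t = t), class = "culture_state")
}

#' Growth-medium nitrogen specification
#'
#' @param nitrogen_N0 Initial nitrogen concentration, mg N L^-1.
#' @param description Free-text description, e.g. `"4 x f/2"`.
#' @return An object of class `medium_spec`.
#' @seealso [f2_nitrogen()]
#' @export
medium_spec <- function(nitrogen_N0, description = "") {
  stopifnot(is.numeric(nitrogen_N0), nitrogen_N0 >= 0)
  structure(list(nitrogen_N0 = nitrogen_N0, description = description),
            class = "medium_spec")
}

#' Nitrogen concentration of f/2-strength medium
#'
#' Converts a multiple of f/2 medium strength to mg N L^-1. Standard f/2
#' supplies nitrate as NaNO3 at 880 µM, so 1x f/2 carries
#' 880e-6 mol L^-1 x 14 g N mol^-1 = 12.32 mg N L^-1.
#'
#' @param multiple Medium strength as a multiple of f/2 (e.g. 4 for 4x f/2).
#' @return Nitrogen concentration, mg N L^-1.
#' @examples
#' f2_nitrogen(4)   # 49.28 mg N / L
#' @export
f2_nitrogen <- function(multiple = 1) {
  stopifnot(multiple >= 0)
  multiple * 880e-6 * 14 * 1000
}

#' Literature-based initial guess for the kinetic constants
#'
#' Returns the parameter set used to start calibration when no data-driven
#' estimates are supplied: literature values for the maximum growth rate,
#' decay, uptake and light-response constants, and round quota bounds.
#'
#' @return A `kinetic_parameters` object with the initial-guess kinetic
#'   constants and the default composition coefficients.
#' @export
initial_parameter_guess <- function() {
  kinetic_parameters(mu_max = 2, K_d = 0.01, Q_min = 0.04, Q_max = 0.13,
                     U_max = 0.5, K_N = 0.01, K_I = 60, n = 1.9)
}
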