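# Quota clamping tolerance: absorbs integrator rounding just outside
# [Q_min, Q_max]; genuine violations beyond it are programming errors.
.Q_TOL <- 1e-9

clamp_quota <- function(Q, p, strict_min = TRUE) {
  if (strict_min && any(Q < p$Q_min - .Q_TOL))
    stop(sprintf("quota %g below Q_min = %g: outside the Droop-invariant range",
                 min(Q), p$Q_min))
  pmin(pmax(Q, p$Q_min), p$Q_max)
}

#' Specific growth rate under combined light and nitrogen limitation
#'
#' Monod light kinetics with Hill exponent `n` multiplied by the
#' normalized Droop quota factor:
#' `mu = mu_max * Iav^n/(K_I^n + Iav^n) * (1 - Q_min/Q)/(1 - Q_min/Q_max)`.
#' The quota factor equals 0 at `Q = Q_min` (growth shut-off) and 1 at
#' `Q = Q_max`, so `mu_max` is attained under saturating light at full
#' quota. `Q` is clamped to `[Q_min, Q_max]` within a 1e-9 tolerance to
#' absorb integrator rounding; values below that signal an integration bug
#' and raise an error.
#'
#' @param Iav Culture-averaged light intensity, µmol m^-2 s^-1.
#' @param Q Nitrogen quota, mg N mg^-1 DCW.
#' @param p A [kinetic_parameters()] object.
#' @return Specific growth rate, day^-1.
#' @examples
#' p <- kinetic_parameters()
#' growth_rate(50, 0.12, p)   # half-saturation at full quota: mu_max/2
#' growth_rate(350, 0.034, p) # Droop shut-off: 0
#' @export
growth_rate <- function(Iav, Q, p) {
  if (any(Iav < 0)) stop("Iav must be non-negative")
  Q <- clamp_quota(Q, p)
  light <- ifelse(Iav == 0, 0, Iav^p$n / (p$K_I^p$n + Iav^p$n))
  droop <- (1 - p$Q_min / Q) / (1 - p$Q_min / p$Q_max)
  p$mu_max * light * droop
}

#' Specific nitrogen uptake rate
#'
#' Monod dependence on the external nitrogen concentration combined with
#' a linear down-regulation as the quota fills:
#' `U = U_max * N/(K_N + N) * (1 - Q/Q_max)`; zero at `N = 0` and at
#' `Q = Q_max`.
#'
#' @param N Medium nitrogen concentration, mg N L^-1.
#' @inheritParams growth_rate
#' @return Uptake rate, mg N mg^-1 DCW day^-1.
#' @examples
#' p <- kinetic_parameters()
#' uptake_rate(p$K_N, 0.034, p)  # half-saturation at empty quota
#' @export
uptake_rate <- function(N, Q, p) {
  if (any(N < 0)) stop("N must be non-negative")
  Q <- clamp_quota(Q, p, strict_min = FALSE)
  p$U_max * N / (p$K_N + N) * (1 - Q / p$Q_max)
}

#' Quota-dependent biomass absorption coefficient
#'
#' Linear empirical correlation `Ka = ka_slope * Q + ka_intercept`; the
#' coefficient falls under nitrogen starvation as photosynthetic pigments
#' are degraded.
#'
#' @inheritParams growth_rate
#' @return Absorption coefficient, L mg^-1 m^-1.
#' @examples
#' absorption_coefficient(0.14, kinetic_parameters())  # ~0.6
#' @export
absorption_coefficient <- function(Q, p = kinetic_parameters()) {
  if (any(Q < 0)) stop("Q must be non-negative")
  p$ka_slope * Q + p$ka_intercept
}

#' Specific total-fatty-acid content from the nitrogen quota
#'
#' Reciprocal power-law correlation
#' `C_TFA = tfa_coeff * Q^(-tfa_exponent) + tfa_offset`: fatty acids
#' accumulate as the quota is drawn down under nitrogen starvation,
#' approaching the offset asymptote at large quota.
#'
#' @inheritParams growth_rate
#' @return Specific TFA content, mg g^-1 DCW; strictly decreasing in `Q`.
#' @examples
#' tfa_content(0.12, kinetic_parameters())  # ~100 mg/g at full quota
#' tfa_content(0.04, kinetic_parameters())  # ~300 mg/g when starved
#' @export
tfa_content <- function(Q, p = kinetic_parameters()) {
  if (any(Q <= 0)) stop("Q must be strictly positive")
  p$tfa_coeff * Q^(-p$tfa_exponent) + p$tfa_offset
}

#' Fatty-acid composition profile of the biomass
#'
#' Combines the quota-TFA correlation with the constant specific EPA
#' content: `C_EPA = epa_content`, `epa_fraction = C_EPA / C_TFA(Q)`, and
#' volumetric concentrations `C * X / 1000` (mg g^-1 x mg L^-1 -> mg L^-1).
#'
#' @inheritParams growth_rate
#' @param X Biomass concentration, mg L^-1.
#' @return List with `C_TFA`, `C_EPA` (mg g^-1 DCW), `epa_fraction`
#'   (dimensionless), `TFA_volumetric`, `EPA_volumetric` (mg L^-1).
#' @examples
#' composition(0.12, 1000, kinetic_parameters())
#' @export
composition <- function(Q, X, p = kinetic_parameters()) {
  if (any(X < 0)) stop("X must be non-negative")
  C_TFA <- tfa_content(Q, p)
  C_EPA <- rep(p$epa_content, length.out = length(C_TFA))
  list(C_TFA = C_TFA,
       C_EPA = C_EPA,
       epa_fraction = C_EPA / C_TFA,
       TFA_volumetric = C_TFA * X / 1000,
       EPA_volumetric = C_EPA * X / 1000)
}
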