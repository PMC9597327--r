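#' Packaged reference cultivation scenarios
#'
#' Three scenarios mirroring the experimental set-ups the model was
#' developed and validated on:
#'
#' * `"5L_flat_panel_4xf2"` — 5 L flat-panel reactor, light path 0.05 m,
#'   incident intensity 350 µmol m^-2 s^-1 on one face, 12:12 h
#'   light:dark, 4x f/2 medium (49.28 mg N L^-1), inoculum OD550 0.05,
#'   16 days. The reference batch for calibration and validation.
#' * `"50L_column_N_limited"` — 50 L bubble column, radius 0.095 m, three
#'   banks at 360 µmol m^-2 s^-1 each, 16:8 h light:dark, 5x f/2 medium
#'   (61.6 mg N L^-1), inoculum OD550 0.08, 14 days.
#' * `"50L_column_N_sufficient"` — as above with nitrate boosted to
#'   15x f/2 (184.8 mg N L^-1).
#'
#' @param name Scenario name; see Details.
#' @param p Parameter set used to convert the inoculum OD to biomass and
#'   to set the inoculum quota (`Q_max`, nutrient-replete flask culture).
#' @return A scenario list with elements `name`, `reactor`, `schedule`,
#'   `medium`, `initial` ([culture_state()]), `duration`, `parameters`.
#' @examples
#' sc <- scenario("5L_flat_panel_4xf2")
#' sc$initial$X   # inoculum biomass from OD 0.05
#' @export
scenario <- function(name = c("5L_flat_panel_4xf2",
                              "50L_column_N_limited",
                              "50L_column_N_sufficient"),
                     p = kinetic_parameters()) {
  name <- match.arg(name)
  spec <- switch(
    name,
    "5L_flat_panel_4xf2" = list(
      reactor = reactor_config("flat_panel", incident_intensity_Io = 350,
                               path_length_L = 0.05,
                               photoperiod_light_h = 12, volume = 5),
      medium = medium_spec(f2_nitrogen(4), "4 x f/2"),
      od = 0.05, duration = 16),
    "50L_column_N_limited" = list(
      reactor = reactor_config("bubble_column", incident_intensity_Io = 360,
                               radius_R = 0.095,
                               photoperiod_light_h = 16, volume = 50),
      medium = medium_spec(f2_nitrogen(5), "5 x f/2"),
      od = 0.08, duration = 14),
    "50L_column_N_sufficient" = list(
      reactor = reactor_config("bubble_column", incident_intensity_Io = 360,
                               radius_R = 0.095,
                               photoperiod_light_h = 16, volume = 50),
      medium = medium_spec(f2_nitrogen(15), "15 x f/2 nitrate, 5 x f/2 trace"),
      od = 0.08, duration = 14))
  Q0 <- p$Q_max
  list(name = name,
       reactor = spec$reactor,
       schedule = light_schedule(spec$reactor$photoperiod_light_h),
       medium = spec$medium,
       initial = culture_state(X = biomass_from_od(spec$od, p, Q0),
                               N = spec$medium$nitrogen_N0, Q = Q0),
       duration = spec$duration,
       parameters = p)
}

#' @rdname scenario
#' @return `list_scenarios()`: character vector of packaged scenario
#'   names.
#' @export
list_scenarios <- function() {
  c("5L_flat_panel_4xf2", "50L_column_N_limited", "50L_column_N_sufficient")
}
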