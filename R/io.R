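# Flat "key: value" configuration files: one scenario or parameter set per
# file, '#' comments, UTF-8. Numbers are written with 17 significant
# digits so a write/read round trip is bit-exact.

parse_config_lines <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = " | "))
  vals <- lapply(kv, function(x) {
    v <- trimws(x[3])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
  })
  setNames(vals, vapply(kv, `[`, character(1), 2))
}

read_config_file <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  parse_config_lines(readLines(file, warn = FALSE))
}

format_config_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

write_config_file <- function(x, file) {
  stopifnot(length(names(x)) == length(x), all(nzchar(names(x))))
  writeLines(paste0(names(x), ": ",
                    vapply(x, format_config_value, character(1))), file)
  invisible(file)
}

#' Read / write a kinetic parameter set as a flat config file
#'
#' The file holds one `key: value` pair per parameter field (see
#' [kinetic_parameters()] for the schema); `#` starts a comment. Writing
#' and re-reading reproduces the parameter set bit-exactly.
#'
#' @param file Path.
#' @return A `kinetic_parameters` object (read) or `file` invisibly
#'   (write).
#' @examples
#' f <- tempfile(fileext = ".cfg")
#' write_parameters(kinetic_parameters(), f)
#' identical(read_parameters(f), kinetic_parameters())
#' @export
read_parameters <- function(file) {
  cfg <- read_config_file(file)
  known <- names(formals(kinetic_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown parameter field(s) in ", file, ": ",
         paste(unknown, collapse = ", "))
  do.call(kinetic_parameters, cfg)
}

#' @rdname read_parameters
#' @param p A `kinetic_parameters` object.
#' @export
write_parameters <- function(p, file) {
  validate_parameters(p)
  write_config_file(unclass(p), file)
}

#' Read / write a scenario as a flat config file
#'
#' A scenario file carries the reactor geometry and illumination, the
#' medium, the inoculum and the run duration as `key: value` pairs:
#' `name`, `geometry` (`flat_panel` | `bubble_column`),
#' `incident_intensity_Io`, `path_length_L` or `radius_R`,
#' `photoperiod_light_h`, `volume`, `nitrogen_N0`, `medium_description`,
#' `initial_od` (or `initial_X`), `initial_Q` (optional; defaults to
#' `Q_max`), `duration`. Any [kinetic_parameters()] field may be added to
#' override the default constants.
#'
#' @param file Path.
#' @param p Baseline parameters that scenario-file overrides are applied
#'   to.
#' @return A scenario list (see [scenario()]) or `file` invisibly.
#' @export
read_scenario_config <- function(file, p = kinetic_parameters()) {
  cfg <- read_config_file(file)
  need <- c("geometry", "incident_intensity_Io", "photoperiod_light_h",
            "nitrogen_N0", "duration")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L)
    stop("scenario config ", file, " is missing field(s): ",
         paste(miss, collapse = ", "))
  par_fields <- intersect(names(cfg), names(formals(kinetic_parameters)))
  if (length(par_fields) > 0L)
    p <- validate_parameters(modifyList(p, cfg[par_fields]))
  reactor <- reactor_config(
    geometry = cfg$geometry,
    incident_intensity_Io = cfg$incident_intensity_Io,
    path_length_L = if (!is.null(cfg$path_length_L)) cfg$path_length_L else 0.05,
    radius_R = if (!is.null(cfg$radius_R)) cfg$radius_R else 0.095,
    photoperiod_light_h = cfg$photoperiod_light_h,
    volume = if (!is.null(cfg$volume)) cfg$volume else NA_real_)
  Q0 <- if (!is.null(cfg$initial_Q)) cfg$initial_Q else p$Q_max
  X0 <- if (!is.null(cfg$initial_X)) cfg$initial_X
        else if (!is.null(cfg$initial_od)) biomass_from_od(cfg$initial_od, p, Q0)
        else stop("scenario config needs initial_X or initial_od")
  list(name = if (!is.null(cfg$name)) cfg$name else basename(file),
       reactor = reactor,
       schedule = light_schedule(cfg$photoperiod_light_h),
       medium = medium_spec(cfg$nitrogen_N0,
                            if (!is.null(cfg$medium_description))
                              cfg$medium_description else ""),
       initial = culture_state(X = X0, N = cfg$nitrogen_N0, Q = Q0),
       duration = cfg$duration,
       parameters = p)
}

#' @rdname read_scenario_config
#' @param sc A scenario list as returned by [scenario()] or
#'   [read_scenario_config()].
#' @export
write_scenario_config <- function(sc, file) {
  r <- sc$reactor
  cfg <- list(name = sc$name, geometry = r$geometry,
              incident_intensity_Io = r$incident_intensity_Io)
  if (r$geometry == "flat_panel") cfg$path_length_L <- r$path_length_L
  else cfg$radius_R <- r$radius_R
  cfg$photoperiod_light_h <- r$photoperiod_light_h
  if (!is.na(r$volume)) cfg$volume <- r$volume
  cfg$nitrogen_N0 <- sc$medium$nitrogen_N0
  if (nzchar(sc$medium$description))
    cfg$medium_description <- sc$medium$description
  cfg$initial_X <- sc$initial$X
  cfg$initial_Q <- sc$initial$Q
  cfg$duration <- sc$duration
  write_config_file(cfg, file)
}
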