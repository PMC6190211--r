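#' Simulation scenario presets
#'
#' A scenario bundles geometry, physical parameters, the AC drive, and the
#' time-integration controls of one numerical experiment. Two presets cover
#' the study conditions:
#' \describe{
#'   \item{\code{static_chamber}}{closed 1000 x 200 um chamber, 50 um gate on
#'     the bottom wall, no through-flow, integrated to t = 100 s.}
#'   \item{\code{continuous_flow}}{1000 x 50 um channel with a parabolic
#'     pressure-driven inlet flow of mean 50 um/s, integrated to t = 17 s.}
#' }
#' Drive defaults to 4 V at 10 Hz. Overrides are applied last and may address
#' nested fields as \code{geometry.height}, \code{params.k_on},
#' \code{drive.V0}, or top-level fields \code{t_end}, \code{dt},
#' \code{mesh_resolution}.
#'
#' @param name preset name, one of \code{"static_chamber"},
#'   \code{"continuous_flow"}.
#' @param overrides optional named list of overrides, e.g.
#'   \code{list(drive.V0 = 8, params.k_on = 1515)}.
#' @return An object of class \code{iceo_scenario} with fields \code{name},
#'   \code{geometry}, \code{params}, \code{drive}, \code{t_end}, \code{dt},
#'   \code{mesh_resolution}.
#' @examples
#' sc <- make_scenario("static_chamber")
#' sc$geometry$height   # 200 um
#' sc$params$C0         # 1e-7 mol/m^3
#' @export
make_scenario <- function(name, overrides = NULL) {
  presets <- c("static_chamber", "continuous_flow")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets)) {
    stop("make_scenario: unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ", paste(presets, collapse = ", "))
  }
  if (name == "static_chamber") {
    geom <- channel_geometry(length = 1000e-6, height = 200e-6,
                             inlet_mean_velocity = 0)
    t_end <- 100
  } else {
    geom <- channel_geometry(length = 1000e-6, height = 50e-6,
                             inlet_mean_velocity = 50e-6)
    t_end <- 17
  }
  sc <- structure(list(name = name,
                       geometry = geom,
                       params = physical_params(),
                       drive = drive_signal(V0 = 4, freq = 10),
                       t_end = t_end,
                       dt = 0.25,
                       mesh_resolution = 1),
                  class = "iceo_scenario")
  if (!is.null(overrides)) sc <- apply_overrides(sc, overrides)
  validate_scenario(sc)
  sc
}

apply_overrides <- function(sc, overrides) {
  if (!is.list(overrides) || is.null(names(overrides)) ||
      any(names(overrides) == "")) {
    stop("make_scenario: overrides must be a fully named list")
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- overrides[[key]]
    if (length(parts) == 1L) {
      if (!parts %in% names(sc)) stop("make_scenario: unknown override '", key, "'")
      sc[[parts]] <- val
    } else if (length(parts) == 2L) {
      if (!parts[1] %in% c("geometry", "params", "drive") ||
          !parts[2] %in% names(sc[[parts[1]]])) {
        stop("make_scenario: unknown override '", key, "'")
      }
      sc[[parts[1]]][[parts[2]]] <- val
    } else {
      stop("make_scenario: unknown override '", key, "'")
    }
  }
  # re-derive dependent fields
  sc$drive <- drive_signal(sc$drive$V0, sc$drive$freq)
  p <- sc$params
  sc$params <- physical_params(sigma_f = p$sigma_f, eps_f = p$eps_f,
                               eta = p$eta, delta = p$delta,
                               lambda_D = p$lambda_D, D_antigen = p$D_antigen,
                               D_ion = p$D_ion, k_on = p$k_on,
                               k_off = p$k_off, R_T = p$R_T, C0 = p$C0)
  g <- sc$geometry
  sc$geometry <- channel_geometry(length = g$length, height = g$height,
                                  gate_width = g$gate_width,
                                  gate_height = g$gate_height,
                                  gate_center_x = g$gate_center_x,
                                  functionalized_span = g$functionalized_span,
                                  inlet_mean_velocity = g$inlet_mean_velocity)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "iceo_scenario"))
  if (sc$t_end <= 0 || sc$dt <= 0 || sc$dt > sc$t_end) {
    stop("scenario: need 0 < dt <= t_end")
  }
  # thin-double-layer assumption
  if (sc$params$lambda_D >= 1e-3 * sc$geometry$gate_width) {
    stop("scenario: lambda_D violates the thin-double-layer assumption ",
         "(must be < 1e-3 x gate width)")
  }
  invisible(sc)
}

#' Generate a one-axis parameter sweep
#'
#' Produces one scenario per requested value along a sweep axis. Dimensionless
#' axes are mapped onto physical knobs: the Damkohler number
#' \code{Da = k_on * R_T * h / D} is varied by rescaling \code{k_on}
#' (holding \code{k_off} fixed), and the Peclet number \code{Pe = u * h / D}
#' by rescaling the inlet mean velocity.
#'
#' @param scenario base scenario from \code{\link{make_scenario}}.
#' @param axis one of \code{"voltage"}, \code{"frequency"}, \code{"Da"},
#'   \code{"Pe"}, \code{"gate_height"}.
#' @param values numeric vector of axis values (V, Hz, dimensionless,
#'   dimensionless, m respectively).
#' @return A list of \code{iceo_scenario}, one per value, each named
#'   \code{<base>_<axis>_<value>}.
#' @examples
#' sweep_grid(make_scenario("static_chamber"), "voltage", c(2, 4, 8, 16, 32))
#' @export
sweep_grid <- function(scenario, axis, values) {
  axes <- c("voltage", "frequency", "Da", "Pe", "gate_height")
  if (!axis %in% axes) {
    stop("sweep_grid: axis must be one of ", paste(axes, collapse = ", "))
  }
  if (length(values) == 0 || !is.numeric(values)) {
    stop("sweep_grid: values must be a non-empty numeric vector")
  }
  if (axis == "Pe" && scenario$geometry$inlet_mean_velocity == 0) {
    stop("sweep_grid: Pe sweep requires a flow-through scenario (no inlet in '",
         scenario$name, "')")
  }
  h <- scenario$geometry$height
  D <- scenario$params$D_antigen
  lapply(seq_along(values), function(i) {
    v <- values[i]
    ov <- switch(axis,
                 voltage = list(drive.V0 = v),
                 frequency = list(drive.freq = v),
                 Da = list(params.k_on = v * D / (scenario$params$R_T * h)),
                 Pe = list(geometry.inlet_mean_velocity = v * D / h),
                 gate_height = list(geometry.gate_height = v))
    sc <- apply_overrides(scenario, ov)
    validate_scenario(sc)
    sc$name <- sprintf("%s_%s_%g", scenario$name, axis, v)
    sc
  })
}

#' Serialize a scenario to YAML (SI units in the key names)
#'
#' @param scenario an \code{iceo_scenario}.
#' @param path optional file path; if missing, the YAML string is returned.
#' @return \code{path} invisibly, or the YAML text.
#' @export
scenario_to_yaml <- function(scenario, path = NULL) {
  g <- scenario$geometry; p <- scenario$params; d <- scenario$drive
  obj <- list(
    name = scenario$name,
    geometry = list(length_m = g$length, height_m = g$height,
                    gate_width_m = g$gate_width, gate_height_m = g$gate_height,
                    gate_center_x_m = g$gate_center_x,
                    functionalized_span_m = as.numeric(g$functionalized_span),
                    inlet_mean_velocity_m_per_s = g$inlet_mean_velocity),
    params = list(sigma_f_S_per_m = p$sigma_f, eps_f_F_per_m = p$eps_f,
                  eta_Pa_s = p$eta, delta = p$delta, lambda_D_m = p$lambda_D,
                  D_antigen_m2_per_s = p$D_antigen, D_ion_m2_per_s = p$D_ion,
                  k_on_m3_per_mol_s = p$k_on, k_off_per_s = p$k_off,
                  R_T_mol_per_m2 = p$R_T, C0_mol_per_m3 = p$C0),
    drive = list(V0_V = d$V0, freq_Hz = d$freq),
    t_end_s = scenario$t_end, dt_s = scenario$dt,
    mesh_resolution = scenario$mesh_resolution)
  txt <- yaml::as.yaml(obj, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Load a scenario from YAML written by \code{\link{scenario_to_yaml}}
#'
#' @param path file path or a YAML string.
#' @return An \code{iceo_scenario}.
#' @export
scenario_from_yaml <- function(path) {
  obj <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  g <- obj$geometry; p <- obj$params; d <- obj$drive
  sc <- structure(list(
    name = obj$name,
    geometry = channel_geometry(length = g$length_m, height = g$height_m,
                                gate_width = g$gate_width_m,
                                gate_height = g$gate_height_m,
                                gate_center_x = g$gate_center_x_m,
                                functionalized_span = as.numeric(g$functionalized_span_m),
                                inlet_mean_velocity = g$inlet_mean_velocity_m_per_s),
    params = physical_params(sigma_f = p$sigma_f_S_per_m,
                             eps_f = p$eps_f_F_per_m, eta = p$eta_Pa_s,
                             delta = p$delta, lambda_D = p$lambda_D_m,
                             D_antigen = p$D_antigen_m2_per_s,
                             D_ion = p$D_ion_m2_per_s,
                             k_on = p$k_on_m3_per_mol_s,
                             k_off = p$k_off_per_s, R_T = p$R_T_mol_per_m2,
                             C0 = p$C0_mol_per_m3),
    drive = drive_signal(V0 = d$V0_V, freq = d$freq_Hz),
    t_end = obj$t_end_s, dt = obj$dt_s,
    mesh_resolution = obj$mesh_resolution), class = "iceo_scenario")
  validate_scenario(sc)
  sc
}

#' @export
print.iceo_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s, drive %g V at %g Hz, t_end %g s, dt %g s\n",
              x$name,
              if (x$geometry$inlet_mean_velocity > 0) "continuous flow" else "closed chamber",
              x$drive$V0, x$drive$freq, x$t_end, x$dt))
  print(x$geometry)
  invisible(x)
}
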