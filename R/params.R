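#' Physical parameters of the electrolyte, double layer, and binding reaction
#'
#' Bundles the fluid, induced-double-layer, and Langmuir-kinetics constants
#' used throughout the simulator, all in SI units. The diffuse-layer
#' capacitance is the Debye capacitance \code{C_D = eps_f / lambda_D}; the
#' Stern-layer capacitance follows from the capacitance ratio
#' \code{delta = C_D / C_S}. The Debye length, if not given, is derived from
#' the conductivity via \code{\link{debye_length_from_conductivity}}.
#'
#' @param sigma_f electrical conductivity of the solution (S/m).
#' @param eps_f absolute permittivity of the fluid (F/m); default is water
#'   (relative permittivity ~80).
#' @param eta dynamic viscosity (Pa s).
#' @param delta capacitance ratio of diffuse to Stern layer (dimensionless,
#'   >= 0). 0 means no Stern layer.
#' @param lambda_D Debye screening length (m), or \code{NULL} to derive it
#'   from \code{sigma_f}, \code{eps_f} and \code{D_ion}.
#' @param D_antigen diffusivity of the antigen (m^2/s).
#' @param D_ion small-ion diffusivity (m^2/s), used only to derive
#'   \code{lambda_D}.
#' @param k_on association rate constant (m^3/(mol s)).
#' @param k_off dissociation rate constant (1/s).
#' @param R_T immobilized receptor surface concentration (mol/m^2).
#' @param C0 initial/bulk antigen concentration (mol/m^3).
#' @return An object of class \code{iceo_params}: a named list with the above
#'   fields plus derived \code{C_D} and \code{C_S} (F/m^2).
#' @examples
#' p <- physical_params()
#' p$lambda_D     # ~37.6 nm at 1 mS/m
#' p$C_D          # Debye capacitance eps_f / lambda_D
#' @export
physical_params <- function(sigma_f = 1e-3,
                            eps_f = 7.08e-10,
                            eta = 1e-3,
                            delta = 0,
                            lambda_D = NULL,
                            D_antigen = 1e-11,
                            D_ion = 2e-9,
                            k_on = 1e3,
                            k_off = 1e-3,
                            R_T = 3.3e-8,
                            C0 = 1e-7) {
  if (is.null(lambda_D)) {
    lambda_D <- debye_length_from_conductivity(sigma_f, eps_f, D_ion)
  }
  vals <- list(sigma_f = sigma_f, eps_f = eps_f, eta = eta, delta = delta,
               lambda_D = lambda_D, D_antigen = D_antigen, D_ion = D_ion,
               k_on = k_on, k_off = k_off, R_T = R_T, C0 = C0)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("physical_params: field '", nm, "' must be a finite scalar")
    }
  }
  if (delta < 0) stop("physical_params: delta must be >= 0")
  strict <- setdiff(names(vals), c("delta", "k_on"))
  for (nm in strict) {
    if (vals[[nm]] <= 0) stop("physical_params: field '", nm, "' must be > 0")
  }
  if (k_on < 0) stop("physical_params: k_on must be >= 0")
  vals$C_D <- eps_f / lambda_D
  vals$C_S <- if (delta > 0) vals$C_D / delta else Inf
  structure(vals, class = "iceo_params")
}

#' Debye length from solution conductivity
#'
#' For a symmetric electrolyte the conductivity, permittivity, and ionic
#' diffusivity are linked by \code{sigma/eps = D_ion/lambda_D^2}, so the
#' screening length follows directly from the measured conductivity:
#' \code{lambda_D = sqrt(eps_f * D_ion / sigma_f)}.
#'
#' @param sigma_f conductivity (S/m).
#' @param eps_f absolute permittivity (F/m).
#' @param D_ion ionic diffusivity (m^2/s).
#' @return Debye length in meters.
#' @examples
#' debye_length_from_conductivity(1e-3, 7.08e-10, 2e-9)  # ~3.76e-8 m
#' @export
debye_length_from_conductivity <- function(sigma_f, eps_f, D_ion) {
  if (any(c(sigma_f, eps_f, D_ion) <= 0) ||
      any(!is.finite(c(sigma_f, eps_f, D_ion)))) {
    stop("debye_length_from_conductivity: all inputs must be positive finite")
  }
  sqrt(eps_f * D_ion / sigma_f)
}

#' AC drive signal
#'
#' The driving electrode pair is energized with \code{V0 * cos(omega * t)};
#' the right electrode is grounded.
#'
#' @param V0 voltage amplitude (V), >= 0.
#' @param freq field frequency (Hz), > 0.
#' @return An object of class \code{iceo_drive} with fields \code{V0},
#'   \code{freq}, and \code{omega = 2*pi*freq}.
#' @export
drive_signal <- function(V0 = 4, freq = 10) {
  if (!is.numeric(V0) || V0 < 0) stop("drive_signal: V0 must be >= 0")
  if (!is.numeric(freq) || freq <= 0) stop("drive_signal: freq must be > 0")
  structure(list(V0 = V0, freq = freq, omega = 2 * pi * freq),
            class = "iceo_drive")
}

#' Rectangular channel geometry with a floating gate electrode
#'
#' The channel is a rectangle (origin at the bottom-left corner, x axial,
#' y upward). A polarizable gate electrode of width \code{gate_width} sits on
#' the bottom wall centered at \code{gate_center_x}; its functionalized
#' (antibody-coated) segment is an interval on the gate top surface.
#'
#' @param length,height channel dimensions (m).
#' @param gate_width,gate_height gate electrode dimensions (m).
#' @param gate_center_x axial position of the gate center (m).
#' @param functionalized_span length-2 numeric, axial interval of the
#'   functionalized segment (m); defaults to the left half of the gate.
#' @param inlet_mean_velocity mean inlet velocity (m/s); 0 for a closed
#'   chamber.
#' @return An object of class \code{iceo_geometry}.
#' @export
channel_geometry <- function(length = 1000e-6, height = 200e-6,
                             gate_width = 50e-6, gate_height = 200e-9,
                             gate_center_x = length / 2,
                             functionalized_span = NULL,
                             inlet_mean_velocity = 0) {
  if (length <= 0 || height <= 0) stop("channel_geometry: degenerate channel")
  if (gate_width <= 0 || gate_height <= 0) stop("channel_geometry: degenerate gate")
  x0 <- gate_center_x - gate_width / 2
  x1 <- gate_center_x + gate_width / 2
  if (x0 < 0 || x1 > length) stop("channel_geometry: gate extends outside the bottom wall")
  if (gate_height >= height / 10) stop("channel_geometry: gate_height must be < height/10")
  if (is.null(functionalized_span)) functionalized_span <- c(x0, gate_center_x)
  if (functionalized_span[1] < x0 - 1e-12 || functionalized_span[2] > x1 + 1e-12 ||
      diff(functionalized_span) <= 0) {
    stop("channel_geometry: functionalized_span must be a non-empty interval on the gate top")
  }
  if (inlet_mean_velocity < 0) stop("channel_geometry: inlet_mean_velocity must be >= 0")
  structure(list(length = length, height = height,
                 gate_width = gate_width, gate_height = gate_height,
                 gate_center_x = gate_center_x,
                 functionalized_span = functionalized_span,
                 inlet_mean_velocity = inlet_mean_velocity),
            class = "iceo_geometry")
}

#' @export
print.iceo_params <- function(x, ...) {
  cat("Physical parameters (SI):\n")
  cat(sprintf("  sigma_f = %.3g S/m, eps_f = %.3g F/m, eta = %.3g Pa s\n",
              x$sigma_f, x$eps_f, x$eta))
  cat(sprintf("  lambda_D = %.3g m, delta = %.3g, C_D = %.3g F/m^2\n",
              x$lambda_D, x$delta, x$C_D))
  cat(sprintf("  D = %.3g m^2/s, k_on = %.3g m^3/(mol s), k_off = %.3g 1/s\n",
              x$D_antigen, x$k_on, x$k_off))
  cat(sprintf("  R_T = %.3g mol/m^2, C0 = %.3g mol/m^3\n", x$R_T, x$C0))
  invisible(x)
}

#' @export
print.iceo_geometry <- function(x, ...) {
  cat(sprintf("Channel %g x %g um, gate %g um wide x %g nm high at x = %g um\n",
              x$length * 1e6, x$height * 1e6, x$gate_width * 1e6,
              x$gate_height * 1e9, x$gate_center_x * 1e6))
  cat(sprintf("  functionalized [%g, %g] um, inlet mean velocity %g um/s\n",
              x$functionalized_span[1] * 1e6, x$functionalized_span[2] * 1e6,
              x$inlet_mean_velocity * 1e6))
  invisible(x)
}
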