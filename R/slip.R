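#' Induced zeta potential on the gate
#'
#' The potential drop across the diffuse part of the induced double layer,
#' \code{zeta = (V0g - phi)/(1 + delta)}, evaluated at each gate facet
#' midpoint.
#'
#' @param field \code{iceo_potential}.
#' @param mesh the mesh the field was solved on.
#' @param params \code{\link{physical_params}}.
#' @return List: \code{s} (arclength, m), \code{zeta} (complex phasor, V).
#' @export
induced_zeta <- function(field, mesh, params) {
  gp <- mesh$gate
  phi_mid <- (field$phi[gp$nodes[, 1]] + field$phi[gp$nodes[, 2]]) / 2
  list(s = gp$s, zeta = (field$V0g - phi_mid) / (1 + params$delta))
}

#' Time-averaged ICEO slip velocity on the gate
#'
#' Generalized Helmholtz-Smoluchowski slip for AC forcing:
#' \deqn{\langle u_{slip}\rangle = -\frac{\varepsilon_f}{\eta}\,
#'   \frac{1}{2}\,\mathrm{Re}\!\left(\tilde\zeta\,\tilde E_t^{*}\right),}
#' evaluated per gate facet with the tangential field phasor from
#' \code{\link{surface_fields}}. Because both the induced zeta and the
#' tangential field scale linearly with the drive amplitude, the slip is
#' quadratic in \code{V0}. On a flat centered gate the profile is an odd
#' function of the distance from the gate center, directing fluid along the
#' surface from both gate edges toward the center, with the jets rising above
#' the center (a pair of counter-rotating vortices).
#'
#' @param field \code{iceo_potential}.
#' @param mesh the mesh the field was solved on.
#' @param params \code{\link{physical_params}}.
#' @return Object of class \code{iceo_slip}: \code{s} (facet midpoint
#'   arclength, m), \code{slip} (signed tangential velocity, m/s, along
#'   increasing arclength), \code{length}, \code{tangent}, \code{nodes}
#'   (facet node pairs), and provenance (\code{drive}, \code{params}).
#' @export
timeavg_slip <- function(field, mesh, params) {
  gp <- mesh$gate
  sf <- surface_fields(field, mesh)
  z <- induced_zeta(field, mesh, params)
  slip <- -(params$eps_f / params$eta) * 0.5 * Re(z$zeta * Conj(sf$Et))
  structure(list(s = gp$s, slip = slip, length = gp$length,
                 tangent = gp$tangent, nodes = gp$nodes,
                 functionalized = gp$functionalized, side = gp$side,
                 drive = field$drive, params = params),
            class = "iceo_slip")
}

#' Zero slip profile on a mesh's gate (unenergized drive)
#'
#' @param mesh an \code{iceo_mesh}.
#' @return An \code{iceo_slip} with zero velocity everywhere.
#' @export
zero_slip <- function(mesh) {
  gp <- mesh$gate
  structure(list(s = gp$s, slip = numeric(length(gp$s)), length = gp$length,
                 tangent = gp$tangent, nodes = gp$nodes,
                 functionalized = gp$functionalized, side = gp$side,
                 drive = NULL, params = NULL),
            class = "iceo_slip")
}

#' Closed-form DC-limit ICEO slip on a flat gate
#'
#' In the low-frequency (insulator) limit the induced zeta on a flat gate in
#' a uniform field \code{E0} is \code{zeta = E0 * x / (1 + delta)} (x the
#' signed distance from the gate center), and the time-averaged slip is
#' \deqn{\langle u_s^{DC}\rangle = -\varepsilon_f E_0^2 x / (2 \eta (1+\delta)).}
#'
#' @param x signed distance from the gate center (m).
#' @param E0 applied field amplitude (V/m).
#' @param params \code{\link{physical_params}}.
#' @param half_width gate half-width (m); \code{|x|} beyond it is rejected.
#' @return Slip velocity (m/s), signed along +x.
#' @examples
#' dc_limit_slip(25e-6, 4000, physical_params())  # ~ -1.42e-4 m/s
#' @export
dc_limit_slip <- function(x, E0, params, half_width = 25e-6) {
  if (any(abs(x) > half_width * (1 + 1e-9))) {
    stop("dc_limit_slip: |x| exceeds the gate half-width")
  }
  -params$eps_f * E0^2 * x / (2 * params$eta * (1 + params$delta))
}

#' Surface-averaged slip speed
#'
#' Length-weighted mean of the slip magnitude over the gate facets (the
#' conventional unsigned "surface-averaged slip velocity" of frequency and
#' voltage sweeps).
#'
#' @param profile an \code{iceo_slip}.
#' @return Mean |slip| in m/s.
#' @export
surface_avg_slip <- function(profile) {
  stopifnot(inherits(profile, "iceo_slip"), length(profile$slip) > 0)
  sum(profile$length * abs(profile$slip)) / sum(profile$length)
}

#' Single-relaxation frequency response of the slip
#'
#' Reduced RC model: the induced zeta rolls off as
#' \code{1/(1 + j f/f_c)} while the tangential field stays fixed, so the
#' time-averaged slip follows a Lorentzian,
#' \code{u(f) = u_plateau / (1 + (f/f_c)^2)} - exactly 50 percent of the
#' plateau at \code{f = f_c}.
#'
#' @param freq frequency (Hz).
#' @param f_c relaxation frequency (Hz).
#' @param u_plateau low-frequency slip plateau (m/s).
#' @return Slip (m/s).
#' @export
reduced_rc_response <- function(freq, f_c, u_plateau) {
  stopifnot(all(freq > 0), f_c > 0)
  u_plateau / (1 + (freq / f_c)^2)
}

#' Slip profile as a data frame
#'
#' @param x an \code{iceo_slip}.
#' @param ... unused.
#' @return data.frame with arclength (m) and slip (m/s).
#' @export
as.data.frame.iceo_slip <- function(x, ...) {
  data.frame(s = x$s, slip = x$slip, length = x$length,
             functionalized = x$functionalized)
}
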