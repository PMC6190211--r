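#' Damkohler number
#'
#' \code{Da = k_on * R_T * h / D}: ratio of the surface reaction velocity to
#' the diffusive transport velocity over the channel height. \code{Da >> 1}
#' marks transport-limited binding.
#'
#' @param params \code{\link{physical_params}}.
#' @param h channel height (m).
#' @return Dimensionless Da.
#' @examples
#' damkohler(physical_params(), 200e-6)  # 660 at the default parameter set
#' @export
damkohler <- function(params, h) {
  stopifnot(h > 0)
  params$k_on * params$R_T * h / params$D_antigen
}

#' Peclet number
#'
#' \code{Pe = u * h / D}: ratio of axial convective to diffusive transport.
#'
#' @param u inlet mean velocity (m/s), >= 0.
#' @param h channel height (m).
#' @param D diffusivity (m^2/s).
#' @return Dimensionless Pe.
#' @export
peclet <- function(u, h, D) {
  stopifnot(h > 0, D > 0, u >= 0)
  u * h / D
}

#' Run the full coupled pipeline for one scenario
#'
#' Builds the mesh, solves the potential phasor and ICEO slip (skipped at
#' \code{V0 = 0}), solves the Stokes flow (skipped in a quiescent closed
#' chamber), and integrates the coupled transport-reaction problem.
#'
#' @param scenario an \code{iceo_scenario}.
#' @param t_end,dt optional overrides of the scenario's time controls.
#' @param mesh optional prebuilt mesh (must match the geometry), to share
#'   meshes across paired runs.
#' @return Object of class \code{iceo_run}: \code{scenario}, \code{mesh},
#'   \code{potential}, \code{slip}, \code{flow}, \code{binding},
#'   \code{slip_avg} (surface-averaged slip speed, m/s).
#' @export
run_scenario <- function(scenario, t_end = NULL, dt = NULL, mesh = NULL) {
  stopifnot(inherits(scenario, "iceo_scenario"))
  if (is.null(t_end)) t_end <- scenario$t_end
  if (is.null(dt)) dt <- scenario$dt
  if (is.null(mesh)) mesh <- build_mesh(scenario$geometry, scenario$mesh_resolution)
  driven <- scenario$drive$V0 > 0
  pot <- NULL
  slip <- zero_slip(mesh)
  if (driven) {
    pot <- solve_potential_phasor(mesh, scenario$params, scenario$drive)
    slip <- timeavg_slip(pot, mesh, scenario$params)
  }
  inflow <- scenario$geometry$inlet_mean_velocity
  flow <- if (driven || inflow > 0) {
    solve_stokes(mesh, slip, inlet_mean_velocity = inflow)
  } else NULL
  binding <- simulate_binding(mesh, flow, scenario$params, t_end, dt)
  structure(list(scenario = scenario, mesh = mesh, potential = pot,
                 slip = slip, flow = flow, binding = binding,
                 slip_avg = if (driven) surface_avg_slip(slip) else 0),
            class = "iceo_run")
}

#' Binding enhancement factor Be
#'
#' Runs the coupled pipeline twice on the same mesh and time step - once
#' with the drive energized and once with \code{V0 = 0} - and returns
#' \code{Be = B / B0}, the ratio of surface-averaged bound concentration on
#' the functionalized segment at \code{t_eval}.
#'
#' @param scenario an \code{iceo_scenario} (its drive defines the "on" run).
#' @param t_eval evaluation time (s), defaults to the scenario's
#'   \code{t_end}.
#' @param off_run optional precomputed drive-off \code{iceo_run} on the same
#'   mesh/dt (lets sweeps share a single baseline).
#' @return Object of class \code{iceo_enhancement}: \code{Be}, \code{B_on},
#'   \code{B_off} (mol/m^2), \code{t_eval}, \code{scenario}, and the two
#'   runs.
#' @export
enhancement_factor <- function(scenario, t_eval = NULL, off_run = NULL) {
  if (is.null(t_eval)) t_eval <- scenario$t_end
  stopifnot(t_eval > 0, t_eval <= scenario$t_end + 1e-9)
  on_run <- run_scenario(scenario)
  if (is.null(off_run)) {
    off_sc <- apply_overrides(scenario, list(drive.V0 = 0))
    off_run <- run_scenario(off_sc, mesh = on_run$mesh)
  }
  B_on <- binding_at(on_run$binding, t_eval)
  B_off <- binding_at(off_run$binding, t_eval)
  if (B_off <= 0) stop("enhancement_factor: baseline B0 is not positive")
  structure(list(Be = B_on / B_off, B_on = B_on, B_off = B_off,
                 t_eval = t_eval, scenario = scenario,
                 on_run = on_run, off_run = off_run),
            class = "iceo_enhancement")
}

#' Run a one-axis sweep of the binding enhancement and slip
#'
#' Applies \code{\link{sweep_grid}} and evaluates, for every scenario on the
#' axis, the surface-averaged ICEO slip and (optionally) the binding
#' enhancement factor. Per-point failures are caught and recorded, and the
#' sweep continues. The drive-off baseline is recomputed whenever the axis
#' changes it (Da rescales \code{k_on}; Pe and gate height change the
#' geometry/flow), and shared otherwise.
#'
#' @param base base \code{iceo_scenario}.
#' @param axis sweep axis (see \code{\link{sweep_grid}}).
#' @param values axis values.
#' @param t_eval Be evaluation time (s), default the base \code{t_end}.
#' @param compute_be compute the (expensive) paired transient runs for Be.
#' @return Object of class \code{iceo_sweep}: \code{axis}, \code{table}
#'   (data.frame with \code{value}, \code{slip_avg}, \code{Be}, \code{B_on},
#'   \code{B_off}, \code{error}), \code{base}.
#' @export
run_sweep <- function(base, axis, values, t_eval = NULL, compute_be = TRUE) {
  scen <- sweep_grid(base, axis, values)
  if (is.null(t_eval)) t_eval <- base$t_end
  baseline_varies <- axis %in% c("Da", "Pe", "gate_height")
  off_run <- NULL
  rows <- lapply(seq_along(scen), function(i) {
    sc <- scen[[i]]
    out <- data.frame(value = values[i], slip_avg = NA_real_, Be = NA_real_,
                      B_on = NA_real_, B_off = NA_real_,
                      error = NA_character_)
    tryCatch({
      if (compute_be) {
        if (!baseline_varies && !is.null(off_run)) {
          ef <- enhancement_factor(sc, t_eval, off_run = off_run)
        } else {
          ef <- enhancement_factor(sc, t_eval)
          if (!baseline_varies) off_run <<- ef$off_run
        }
        out$Be <- ef$Be; out$B_on <- ef$B_on; out$B_off <- ef$B_off
        out$slip_avg <- ef$on_run$slip_avg
      } else {
        mesh <- build_mesh(sc$geometry, sc$mesh_resolution)
        if (sc$drive$V0 > 0) {
          pot <- solve_potential_phasor(mesh, sc$params, sc$drive)
          out$slip_avg <- surface_avg_slip(timeavg_slip(pot, mesh, sc$params))
        } else out$slip_avg <- 0
      }
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  structure(list(axis = axis, table = do.call(rbind, rows), base = base),
            class = "iceo_sweep")
}

#' Relaxation frequency from a slip-versus-frequency sweep
#'
#' Log-interpolates the frequency at which the surface-averaged slip falls
#' to half its low-frequency plateau (the plateau being the value at the
#' lowest swept frequency).
#'
#' @param sweep an \code{iceo_sweep} over the \code{frequency} axis, or a
#'   data.frame with columns \code{value} (Hz) and \code{slip_avg} (m/s).
#' @return Crossing frequency (Hz).
#' @export
relaxation_frequency_from_sweep <- function(sweep) {
  tab <- if (inherits(sweep, "iceo_sweep")) sweep$table else sweep
  tab <- tab[order(tab$value), ]
  f <- tab$value; u <- tab$slip_avg
  if (any(!is.finite(u))) stop("relaxation_frequency_from_sweep: sweep contains failed points")
  half <- u[1] / 2
  below <- which(u <= half)
  if (length(below) == 0 || below[1] == 1) {
    stop("relaxation_frequency_from_sweep: 50% crossing outside the sweep range")
  }
  i <- below[1]
  # interpolate log(f) against u between the bracketing points
  lf <- log(f[i - 1]) + (half - u[i - 1]) * (log(f[i]) - log(f[i - 1])) /
    (u[i] - u[i - 1])
  exp(lf)
}

#' @export
print.iceo_enhancement <- function(x, ...) {
  cat(sprintf("Be = %.3f  (B_on = %.3e, B_off = %.3e mol/m^2 at t = %g s)\n",
              x$Be, x$B_on, x$B_off, x$t_eval))
  invisible(x)
}

#' @export
print.iceo_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d points):\n", x$axis, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
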