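#' Solver settings
#'
#' @param dt Time step (s), or `"auto"` to use [stable_dt()].
#' @param steady_tol Steady-state tolerance: the field is declared steady when
#'   the largest nodal `|dP|/dt` falls below this rate (mmHg/s).
#' @param max_time Wall of simulated time (s) for steady-state searches.
#' @param safety Safety factor applied to the explicit stability bound when
#'   `dt = "auto"`.
#' @param record_dt Cadence (s) at which probe values are recorded; rounded to
#'   a whole number of time steps.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = "auto", steady_tol = 1e-3, max_time = 60,
                            safety = 0.9, record_dt = 0.05) {
  if (!identical(dt, "auto") && (!is.numeric(dt) || dt <= 0))
    stop("solver_settings: dt must be \"auto\" or a positive number")
  if (steady_tol <= 0) stop("solver_settings: steady_tol must be positive")
  structure(list(dt = dt, steady_tol = steady_tol, max_time = max_time,
                 safety = safety, record_dt = record_dt),
            class = "solver_settings")
}

#' Stability-limited time step for the explicit scheme
#'
#' The scheme is explicit in diffusion, so the step is bounded by the 3D
#' diffusion limit `dx^2 / (6 max(D, D'))`; a safety factor below one keeps a
#' conventional margin to the bound (the composite interface stencil is
#' slightly less stiff than the pure-PDMS interior).
#'
#' @param spec A [domain_spec()] (only `dx` is used).
#' @param tissue A [tissue_params()].
#' @param membrane A [membrane_params()].
#' @param safety Multiplicative safety factor, default 0.9.
#' @return Time step (s).
#' @examples
#' stable_dt(domain_spec(dx = 5), tissue_params(), membrane_params())
#' @export
stable_dt <- function(spec, tissue = tissue_params(),
                      membrane = membrane_params(), safety = 0.9) {
  safety * spec$dx^2 / (6 * max(tissue$D, membrane$D))
}

#' Initialise a PO2 field
#'
#' Builds a `field_state`: the 3D PO2 array plus its simulation time. By
#' default the field is uniform at the reaction equilibrium ([equilibrium_po2()]),
#' the natural cold start for an unperturbed, homogeneously perfused tissue.
#' If `window_po2` is given, window nodes are clamped to it immediately so
#' the state satisfies the boundary condition from `t = 0`.
#'
#' @param grid A [build_grid()] result.
#' @param tissue A [tissue_params()] (used for the default value).
#' @param value Uniform initial PO2 (mmHg); default `equilibrium_po2(tissue)`.
#' @param window_po2 Optional boundary PO2 to stamp onto window nodes.
#' @return An object of class `field_state` with elements `P` (array
#'   `nx` x `ny` x `nz`, mmHg) and `t` (s).
#' @export
init_state <- function(grid, tissue = tissue_params(), value = NULL,
                       window_po2 = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  if (is.null(value)) value <- equilibrium_po2(tissue)
  P <- array(value, dim = c(grid$nx, grid$ny, grid$nz))
  if (!is.null(window_po2)) P[, , 1][grid$window_mask] <- window_po2
  structure(list(P = P, t = 0), class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("PO2 field: %s nodes at t = %.4g s, range [%.3f, %.3f] mmHg\n",
              paste(dim(x$P), collapse = " x "), x$t,
              min(x$P), max(x$P)))
  invisible(x)
}

# Resolve probe coordinates (data.frame x, y, z in um) to 0-based linear
# node indices for the kernel. Returns integer vector with names.
probe_indices <- function(grid, probes) {
  if (is.null(probes)) return(integer(0))
  probes <- as.data.frame(probes)
  stopifnot(all(c("x", "y", "z") %in% names(probes)))
  idx <- integer(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    ix <- nearest_index(probes$x[i], grid$x, "probe x")
    iy <- nearest_index(probes$y[i], grid$y, "probe y")
    iz <- nearest_index(probes$z[i], grid$z, "probe z")
    idx[i] <- (ix - 1L) + grid$nx * ((iy - 1L) + grid$ny * (iz - 1L))
  }
  names(idx) <- if (!is.null(rownames(probes)) &&
                    !identical(rownames(probes), as.character(seq_len(nrow(probes)))))
    rownames(probes) else sprintf("probe_%d", seq_len(nrow(probes)))
  if (!is.null(probes$name)) names(idx) <- probes$name
  idx
}

# Shared kernel driver. Raises an informative error on instability.
advance_field <- function(state, grid, tissue, membrane, window_po2, dt,
                          nsteps, steady_tol = 0, stop_at_steady = FALSE,
                          probe_idx = integer(0), record_every = 0L,
                          top_po2 = NA_real_) {
  res <- advance_field_cpp(
    as.numeric(state$P), grid$nx, grid$ny, grid$nz,
    as.logical(grid$window_mask), window_po2,
    grid$n_pdms, dt, grid$spec$dx,
    tissue$D, tissue$k, membrane$D, membrane$k,
    tissue$K, tissue$P0, tissue$P50, tissue$M0 / tissue$k,
    as.integer(nsteps), steady_tol, stop_at_steady,
    as.integer(probe_idx), as.integer(record_every),
    if (is.na(top_po2)) 0 else top_po2, !is.na(top_po2))
  if (res$bad_node > 0) {
    iz <- (res$bad_node - 1) %/% (grid$nx * grid$ny)
    rem <- (res$bad_node - 1) %% (grid$nx * grid$ny)
    stop(sprintf(paste0("solver instability: non-finite or negative PO2 at node ",
                        "(x=%g, y=%g, z=%g um) at t = %.6g s; reduce dt"),
                 grid$x[rem %% grid$nx + 1], grid$y[rem %/% grid$nx + 1],
                 grid$z[iz + 1], state$t + (res$bad_step + 1) * dt))
  }
  res
}

#' Advance the field by a number of time steps
#'
#' One or more applications of the semi-implicit update at a fixed window
#' boundary PO2. Tissue nodes update by
#' `P+ = [P + dt (D lap(P) + K - (M0/k) P/(P+P50))] / (1 + dt K/P0)`
#' (linear source implicit, everything else explicit); PDMS nodes by pure
#' explicit diffusion; faces straddling the material interface use the
#' harmonic mean of `D*k` divided by the local solubility; outer faces are
#' zero-flux mirrors except the window nodes, which are reset to
#' `window_po2` every step.
#'
#' @param state A `field_state` (see [init_state()]).
#' @param dt Time step (s); must respect [stable_dt()].
#' @param grid,tissue,membrane Grid and material parameters.
#' @param window_po2 Boundary PO2 at the window (mmHg).
#' @param nsteps Number of steps to take (default 1).
#' @param top_po2 Optional fixed PO2 on the top plane (verification aid;
#'   `NA`, the default, keeps the production zero-flux top).
#' @return The advanced `field_state`.
#' @export
step_field <- function(state, dt, grid, tissue = tissue_params(),
                       membrane = membrane_params(), window_po2 = 0,
                       nsteps = 1L, top_po2 = NA_real_) {
  stopifnot(inherits(state, "field_state"), window_po2 >= 0)
  res <- advance_field(state, grid, tissue, membrane, window_po2, dt,
                       nsteps, top_po2 = top_po2)
  structure(list(P = array(res$P, dim = dim(state$P)),
                 t = state$t + res$steps * dt),
            class = "field_state")
}

#' March the field to steady state at a fixed window PO2
#'
#' Repeats the semi-implicit update until the largest nodal rate of change
#' `|dP|/dt` drops below `settings$steady_tol`, or `settings$max_time` of
#' simulated time elapses. The settle time reported is the first time the
#' criterion held.
#'
#' @param state Initial `field_state`.
#' @param window_po2 Window boundary PO2 (mmHg).
#' @param grid,tissue,membrane Grid and material parameters.
#' @param settings A [solver_settings()].
#' @param probes Optional data frame of probe coordinates (`x`, `y`, `z` in
#'   um, optional `name`) recorded every `settings$record_dt`.
#' @param top_po2 Optional fixed top-plane PO2 (verification aid).
#' @return A list: `state` (steady field), `settle_time` (s from the start of
#'   this call), `converged` (logical), `residual` (final max `|dP|/dt`,
#'   mmHg/s), and `trace` (data frame of `t` plus one column per probe, or
#'   `NULL`).
#' @export
run_to_steady_state <- function(state, window_po2, grid,
                                tissue = tissue_params(),
                                membrane = membrane_params(),
                                settings = solver_settings(),
                                probes = NULL, top_po2 = NA_real_) {
  stopifnot(inherits(state, "field_state"))
  dt <- if (identical(settings$dt, "auto"))
    stable_dt(grid$spec, tissue, membrane, settings$safety) else settings$dt
  nsteps <- ceiling(settings$max_time / dt)
  pidx <- probe_indices(grid, probes)
  rec <- if (length(pidx)) max(1L, round(settings$record_dt / dt)) else 0L
  res <- advance_field(state, grid, tissue, membrane, window_po2, dt, nsteps,
                       steady_tol = settings$steady_tol, stop_at_steady = TRUE,
                       probe_idx = pidx, record_every = rec, top_po2 = top_po2)
  if (!res$converged)
    warning(sprintf(paste0("run_to_steady_state: residual %.3g mmHg/s after ",
                           "%g s did not reach steady_tol = %g"),
                    res$max_dp / dt, settings$max_time, settings$steady_tol))
  trace <- NULL
  if (length(pidx)) {
    nr <- res$nrec
    trace <- data.frame(t = state$t + res$rec_steps[seq_len(nr)] * dt)
    tm <- res$trace[seq_len(nr), , drop = FALSE]
    colnames(tm) <- names(pidx)
    trace <- cbind(trace, as.data.frame(tm))
  }
  list(state = structure(list(P = array(res$P, dim = dim(state$P)),
                              t = state$t + res$steps * dt),
                         class = "field_state"),
       settle_time = res$steps * dt,
       converged = res$converged,
       residual = res$max_dp / dt,
       trace = trace)
}

#' Run a gas-challenge protocol
#'
#' Advances the field through the segments of a [gas_protocol()], switching
#' the window boundary PO2 instantaneously at each segment edge, and records
#' probe traces at a fixed cadence. Because the boundary is constant within a
#' segment, once the field reaches the steady-state tolerance the remainder
#' of the segment is held analytically (the field is a fixed point to within
#' `steady_tol`); set `fast_forward = FALSE` to integrate every step.
#'
#' @param state Initial `field_state` (commonly the steady state of the first
#'   segment's gas, mirroring an experiment that starts from a settled
#'   baseline).
#' @param protocol A [gas_protocol()].
#' @param grid,tissue,membrane Grid and material parameters.
#' @param probes Data frame of probe coordinates (`x`, `y`, `z` um, optional
#'   `name`).
#' @param settings A [solver_settings()].
#' @param fast_forward Hold the field once a segment settles (default TRUE).
#' @param snapshots Record the full field at the end of each segment.
#' @return A list: `trace` (data frame `t` + probe columns), `state` (final
#'   field), `snapshots` (list of `field_state` at segment ends, or `NULL`),
#'   `segment_settled` (logical per segment).
#' @export
run_protocol <- function(state, protocol, grid, tissue = tissue_params(),
                         membrane = membrane_params(), probes = NULL,
                         settings = solver_settings(), fast_forward = TRUE,
                         snapshots = FALSE) {
  stopifnot(inherits(protocol, "gas_protocol"))
  dt <- if (identical(settings$dt, "auto"))
    stable_dt(grid$spec, tissue, membrane, settings$safety) else settings$dt
  pidx <- probe_indices(grid, probes)
  rec <- if (length(pidx)) max(1L, round(settings$record_dt / dt)) else 0L
  t0 <- state$t
  traces <- list()
  snaps <- if (snapshots) vector("list", length(protocol$durations)) else NULL
  settled <- logical(length(protocol$durations))
  seg_start <- t0
  for (s in seq_along(protocol$durations)) {
    dur <- protocol$durations[s]
    wpo2 <- percent_to_po2(protocol$fractions[s], protocol$pressure,
                           protocol$humidified)
    nsteps <- round(dur / dt)
    res <- advance_field(state, grid, tissue, membrane, wpo2, dt, nsteps,
                         steady_tol = settings$steady_tol,
                         stop_at_steady = fast_forward,
                         probe_idx = pidx, record_every = rec)
    settled[s] <- res$converged || res$max_dp / dt < settings$steady_tol
    if (length(pidx)) {
      nr <- res$nrec
      tt <- seg_start + res$rec_steps[seq_len(nr)] * dt
      tm <- res$trace[seq_len(nr), , drop = FALSE]
      if (res$steps < nsteps && rec > 0) {
        # segment settled early: pad the plateau to the segment end
        extra <- seq(res$steps + rec, nsteps, by = rec)
        if (length(extra)) {
          tt <- c(tt, seg_start + extra * dt)
          tm <- rbind(tm, matrix(rep(tm[nr, ], each = length(extra)),
                                 nrow = length(extra)))
        }
      }
      colnames(tm) <- names(pidx)
      traces[[s]] <- cbind(data.frame(t = tt), as.data.frame(tm))
    }
    state <- structure(list(P = array(res$P, dim = dim(state$P)),
                            t = seg_start + dur),
                       class = "field_state")
    if (snapshots) snaps[[s]] <- state
    seg_start <- seg_start + dur
  }
  trace <- if (length(traces)) {
    out <- do.call(rbind, traces)
    out[!duplicated(out$t), , drop = FALSE]
  } else NULL
  list(trace = trace, state = state, snapshots = snaps,
       segment_settled = settled)
}
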