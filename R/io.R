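#' Load and resolve a run configuration
#'
#' Reads a YAML configuration describing a full simulation run and resolves
#' it against the package defaults, so an empty or missing physical-constants
#' section reproduces the default muscle/PDMS parameter set. Unknown keys are
#' rejected (they are almost always typos), and the file's MD5 digest is
#' recorded for provenance.
#'
#' Recognised sections and keys (all optional):
#' \describe{
#'   \item{domain}{`Lx`, `Ly`, `Lz_tissue`, `h_pdms`, `dx` (um)}
#'   \item{layout}{either `windows:` a list of `{cx, cy, lx, ly}` maps, or
#'     `{count, pitch, window_length, window_width}` for a centred row; by
#'     default one 400 x 200 um window centred on the footprint}
#'   \item{tissue}{`D`, `k`, `M0`, `P50`, `P0`, `K` (um/s/mmHg units)}
#'   \item{membrane}{`D`, `k`, `thickness`}
#'   \item{protocol}{either `name: square_wave` or `durations:` +
#'     `fractions:`; plus `pressure`, `humidified`}
#'   \item{solver}{`dt`, `steady_tol`, `max_time`, `safety`, `record_dt`}
#'   \item{metrics}{`threshold`, `plane_z`}
#'   \item{probes}{list of `{x, y, z, name}` maps}
#'   \item{output}{`dir`, `vtk` (logical)}
#' }
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: fully constructed parameter
#'   objects plus `digest` and `raw`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  digest <- NA_character_
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    digest <- unname(tools::md5sum(path))
  }
  known <- c("domain", "layout", "tissue", "membrane", "protocol",
             "solver", "metrics", "probes", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("load_config: unknown section(s): ",
                        paste(bad, collapse = ", "))
  take <- function(section, ctor, known_keys = names(formals(ctor))) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), known_keys)
    if (length(bad)) stop("load_config: unknown key(s) in '", section,
                          "': ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  spec <- take("domain", domain_spec)
  layout <- resolve_layout(raw$layout, spec)
  tissue <- take("tissue", tissue_params)
  membrane <- take("membrane", membrane_params)
  protocol <- resolve_protocol(raw$protocol)
  settings <- take("solver", solver_settings)
  met <- raw$metrics
  if (is.null(met)) met <- list()
  bad <- setdiff(names(met), c("threshold", "plane_z"))
  if (length(bad)) stop("load_config: unknown key(s) in 'metrics': ",
                        paste(bad, collapse = ", "))
  criterion <- extent_criterion(if (is.null(met$threshold)) exp(-4)
                                else met$threshold)
  plane_z <- if (is.null(met$plane_z)) 75 else met$plane_z
  probes <- resolve_probes(raw$probes, spec)
  out <- raw$output
  if (is.null(out)) out <- list()
  bad <- setdiff(names(out), c("dir", "vtk"))
  if (length(bad)) stop("load_config: unknown key(s) in 'output': ",
                        paste(bad, collapse = ", "))
  structure(list(spec = spec, layout = layout, tissue = tissue,
                 membrane = membrane, protocol = protocol,
                 settings = settings, criterion = criterion,
                 plane_z = plane_z, probes = probes,
                 output_dir = if (is.null(out$dir)) "." else out$dir,
                 vtk = isTRUE(out$vtk),
                 digest = digest, raw = raw),
            class = "run_config")
}

resolve_layout <- function(lay, spec) {
  if (is.null(lay))
    return(window_layout(spec$Lx / 2, spec$Ly / 2, 400, 200))
  if (!is.null(lay$windows)) {
    w <- do.call(rbind, lapply(lay$windows, as.data.frame))
    return(window_layout(w$cx, w$cy, w$lx, w$ly))
  }
  known <- c("count", "pitch", "window_length", "window_width")
  bad <- setdiff(names(lay), known)
  if (length(bad)) stop("load_config: unknown key(s) in 'layout': ",
                        paste(bad, collapse = ", "))
  five_window_layout(pitch = lay$pitch,
                     window_length = if (is.null(lay$window_length)) 400
                                     else lay$window_length,
                     window_width = if (is.null(lay$window_width)) 200
                                    else lay$window_width,
                     count = if (is.null(lay$count)) 5 else lay$count,
                     center_x = spec$Lx / 2, center_y = spec$Ly / 2)
}

resolve_protocol <- function(pr) {
  if (is.null(pr)) return(square_wave_protocol())
  pressure <- if (is.null(pr$pressure)) 760 else pr$pressure
  humid <- isTRUE(pr$humidified)
  if (!is.null(pr$name)) {
    if (pr$name != "square_wave")
      stop("load_config: unknown named protocol '", pr$name, "'")
    return(square_wave_protocol(pressure, humid))
  }
  bad <- setdiff(names(pr), c("durations", "fractions", "pressure",
                              "humidified", "name"))
  if (length(bad)) stop("load_config: unknown key(s) in 'protocol': ",
                        paste(bad, collapse = ", "))
  gas_protocol(unlist(pr$durations), unlist(pr$fractions), pressure, humid)
}

resolve_probes <- function(pb, spec) {
  if (is.null(pb)) {
    # default: probes over the footprint centre at 25..100 um above the glass
    return(data.frame(x = spec$Lx / 2, y = spec$Ly / 2,
                      z = c(25, 50, 75, 100),
                      name = paste0("z", c(25, 50, 75, 100), "um")))
  }
  do.call(rbind, lapply(pb, function(p)
    data.frame(x = p$x, y = p$y, z = p$z,
               name = if (is.null(p$name))
                 sprintf("p_%g_%g_%g", p$x, p$y, p$z) else p$name)))
}

#' Serialise a resolved configuration back to YAML
#'
#' Writes the normalised configuration (every default made explicit) so a
#' run can be reproduced from its log alone. `load_config(dump_config(cfg))`
#' resolves to the same configuration.
#'
#' @param cfg A `run_config`.
#' @param path Output path; `NULL` returns the YAML text.
#' @return The YAML text, invisibly when written to a file.
#' @export
dump_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- list(
    domain = cfg$spec[c("Lx", "Ly", "Lz_tissue", "h_pdms", "dx")],
    layout = list(windows = lapply(seq_len(nrow(cfg$layout)), function(i)
      as.list(cfg$layout[i, c("cx", "cy", "lx", "ly")]))),
    tissue = unclass(cfg$tissue),
    membrane = unclass(cfg$membrane),
    protocol = list(durations = cfg$protocol$durations,
                    fractions = cfg$protocol$fractions,
                    pressure = cfg$protocol$pressure,
                    humidified = cfg$protocol$humidified),
    solver = unclass(cfg$settings),
    metrics = list(threshold = cfg$criterion$threshold, plane_z = cfg$plane_z),
    probes = lapply(seq_len(nrow(cfg$probes)), function(i)
      as.list(cfg$probes[i, ])),
    output = list(dir = cfg$output_dir, vtk = cfg$vtk))
  txt <- yaml::as.yaml(lst, precision = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a field as a legacy-ASCII VTK structured-points file
#'
#' Axis order: x fastest, then y, then z; origin at the domain corner on the
#' glass plane (z = 0). Readable by ParaView and other standard viewers.
#'
#' @param state A `field_state`.
#' @param grid A `sim_grid`.
#' @param path Output path (conventionally `.vtk`).
#' @param name Scalar field name in the file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, grid, path, name = "PO2_mmHg") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("oxywindow PO2 field at t = %g s", state$t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$spec$dx, grid$spec$dx,
                       grid$spec$dx),
               sprintf("POINT_DATA %d", grid$nx * grid$ny * grid$nz),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(state$P), digits = 9, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Write a section or probe trace as CSV
#'
#' Sections are written as a matrix with axis coordinates in the first row
#' and column; traces as plain column CSV with a unit-bearing header.
#'
#' @param x A section from [extract_section()] or a trace data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_output <- function(x, path) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$values)) {
    m <- cbind(x$axis1, x$values)
    m <- rbind(c(NA, x$axis2), m)
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, na = "")
  } else {
    df <- as.data.frame(x)
    names(df)[names(df) == "t"] <- "t_s"
    names(df) <- ifelse(names(df) == "t_s", "t_s",
                        paste0(names(df), "_mmHg"))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Run the solver verification suite
#'
#' Compares the production solver against every independent reference in the
#' package: the dense Newton steady solution on a small 3D grid, the
#' two-layer piecewise-linear profile, the linearised-consumption cosh
#' profile, the reaction-equilibrium fixed point, and the scalar-ODE limit
#' of a well-mixed (no-window) domain.
#'
#' @param quiet Suppress the printed table.
#' @return A data frame with columns `check`, `error`, `tol`, `pass`,
#'   invisibly when `quiet = FALSE`.
#' @export
verify_solver <- function(quiet = FALSE) {
  tp <- tissue_params(); mp <- membrane_params()
  rows <- list()
  add <- function(check, error, tol)
    rows[[length(rows) + 1]] <<- data.frame(check = check, error = error,
                                            tol = tol, pass = error < tol)

  # 1. dense Newton vs time-marched steady state, 10x10x10 grid
  spec <- domain_spec(Lx = 45, Ly = 45, Lz_tissue = 20, h_pdms = 25, dx = 5)
  g <- build_grid(spec, window_layout(22.5, 22.5, 20, 20))
  wpo2 <- percent_to_po2(0.02)
  newt <- dense_steady_solution(g, tp, mp, wpo2)
  tm <- run_to_steady_state(init_state(g, tp, window_po2 = wpo2), wpo2, g,
                            tp, mp, solver_settings(steady_tol = 1e-6,
                                                    max_time = 120))
  add("dense Newton vs time-marched steady (10^3 grid)",
      max(abs(tm$state$P - newt$P)), 1e-3)

  # 2. two-layer no-reaction profile vs closed form (1D column)
  spec1 <- domain_spec(Lx = 0, Ly = 0, Lz_tissue = 100, h_pdms = 25, dx = 2.5)
  g1 <- build_grid(spec1, window_layout(0, 0, 0, 0))
  inert <- tissue_params(D = tp$D, k = tp$k, M0 = 1e-300, K = 1e-300,
                         P0 = tp$P0, P50 = tp$P50)
  prof <- two_layer_steady_profile(
    list(thickness = 25, D = mp$D, k = mp$k),
    list(thickness = 100, D = tp$D, k = tp$k), 15.2, 41.6)
  r1 <- run_to_steady_state(init_state(g1, tp, value = 41.6,
                                       window_po2 = 15.2),
                            15.2, g1, inert, mp,
                            solver_settings(steady_tol = 1e-8,
                                            max_time = 600),
                            top_po2 = 41.6)
  add("two-layer linear profile vs closed form (1D)",
      max(abs(as.numeric(r1$state$P) - prof(g1$z))), 1e-4)

  # 3. linearised consumption vs cosh profile (single material, 1D)
  alpha <- tp$K / tp$P0
  lint <- tissue_params(D = tp$D, k = tp$k, M0 = 1e-300, K = tp$K,
                        P0 = tp$P0, P50 = tp$P50)
  spec2 <- domain_spec(Lx = 0, Ly = 0, Lz_tissue = 200, h_pdms = 0, dx = 0.5)
  g2 <- build_grid(spec2, window_layout(0, 0, 0, 0))
  Ps <- 10
  r2 <- run_to_steady_state(init_state(g2, tp, value = tp$P0,
                                       window_po2 = Ps),
                            Ps, g2, lint, mp,
                            solver_settings(steady_tol = 1e-8,
                                            max_time = 600))
  ref <- tp$P0 + linear_consumption_profile(Ps - tp$P0, alpha, 200, tp$D)(g2$z)
  add("linearised consumption vs cosh profile (1D)",
      max(abs(as.numeric(r2$state$P) - ref)), 1e-3)

  # 4. no-window domain relaxes to the reaction equilibrium
  g3 <- build_grid(domain_spec(Lx = 20, Ly = 20, Lz_tissue = 20,
                               h_pdms = 0, dx = 5))
  r3 <- run_to_steady_state(init_state(g3, tp, value = tp$P0), 0, g3, tp, mp,
                            solver_settings(steady_tol = 1e-7, max_time = 120))
  add("no-window relaxation to reaction equilibrium",
      max(abs(as.numeric(r3$state$P) - equilibrium_po2(tp))), 5e-2)

  out <- do.call(rbind, rows)
  if (!quiet) {
    cat("Solver verification:\n")
    for (i in seq_len(nrow(out)))
      cat(sprintf("  [%s] %-50s error %.3g (tol %g)\n",
                  if (out$pass[i]) "PASS" else "FAIL",
                  out$check[i], out$error[i], out$tol[i]))
    return(invisible(out))
  }
  out
}
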