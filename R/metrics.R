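#' Gradient-threshold criterion for perturbation extent
#'
#' The perturbation imposed by a window is considered to reach only as far as
#' the PO2 directional derivative stays at or above a threshold; beyond the
#' first point where |dP/ds| drops below it, the field is considered part of
#' the unperturbed plateau. The default threshold is `exp(-4)` (~0.0183)
#' mmHg/um.
#'
#' @param threshold Directional-derivative magnitude (mmHg/um).
#' @return An object of class `extent_criterion`.
#' @export
extent_criterion <- function(threshold = exp(-4)) {
  if (threshold <= 0) stop("extent_criterion: threshold must be positive")
  structure(list(threshold = threshold), class = "extent_criterion")
}

# centred first derivative along a vector of equally spaced samples;
# one-sided second-order differences at the ends
central_gradient <- function(v, dx) {
  n <- length(v)
  g <- numeric(n)
  if (n >= 3) {
    g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dx)
    g[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * dx)
    g[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * dx)
  } else if (n == 2) g[] <- (v[2] - v[1]) / dx
  g
}

# index of the single window rectangle to evaluate against (the layout's
# first window unless specified); extents are defined per window
ref_window <- function(grid, window = 1L) {
  if (nrow(grid$layout) < window)
    stop("grid layout has no window ", window)
  grid$layout[window, , drop = FALSE]
}

#' Penetration depth of a window challenge into the tissue
#'
#' Walks the vertical line through the window centroid and finds the largest
#' z at which the vertical derivative magnitude `|dP/dz|` (central
#' difference) still meets the [extent_criterion()] threshold. The depth is
#' reported from the tissue surface (z minus the membrane thickness); 0 if
#' the criterion never holds above the tissue surface.
#'
#' @param state A steady `field_state`.
#' @param grid A `sim_grid`.
#' @param criterion An [extent_criterion()].
#' @param window Index of the layout window to evaluate (default 1).
#' @return Depth from the tissue surface (um).
#' @export
penetration_depth <- function(state, grid, criterion = extent_criterion(),
                              window = 1L) {
  w <- ref_window(grid, window)
  ix <- nearest_index(w$cx, grid$x, "window centre x")
  iy <- nearest_index(w$cy, grid$y, "window centre y")
  v <- state$P[ix, iy, ]
  g <- abs(central_gradient(v, grid$spec$dx))
  in_tissue <- grid$z > grid$spec$h_pdms + 1e-9
  hit <- which(in_tissue & g >= criterion$threshold)
  if (!length(hit)) return(0)
  grid$z[max(hit)] - grid$spec$h_pdms
}

# march outward from a window edge along one axis in one z-plane and return
# the distance to the first node whose |directional derivative| falls below
# the threshold (distance measured from the edge-node centre)
march_extent <- function(line, start_idx, direction, dx, threshold) {
  g <- abs(central_gradient(line, dx))
  idx <- if (direction > 0) seq(start_idx, length(line)) else seq(start_idx, 1)
  below <- which(g[idx] < threshold)
  if (!length(below)) return((length(idx) - 1) * dx)  # never drops: full ray
  (below[1] - 1) * dx
}

#' Lateral extent of a window challenge beyond the window edge
#'
#' For each horizontal plane at or above the tissue surface, marches outward
#' from the midpoint of the window edge along the chosen axis (the long axis
#' is the window's longer side) and records the distance to the first node
#' where the in-plane directional derivative magnitude drops below the
#' [extent_criterion()] threshold. Both outward directions are marched and
#' the larger taken. Returns the maximum over planes, or the per-plane
#' profile.
#'
#' @param state A steady `field_state`.
#' @param grid A `sim_grid`.
#' @param axis `"long"` or `"short"`: which window axis to march along.
#' @param criterion An [extent_criterion()].
#' @param plane_z Optional single z (um, from the glass) restricting the
#'   evaluation to one plane.
#' @param per_plane Return a data frame (`z`, `extent`) instead of the max.
#' @param window Index of the layout window to evaluate.
#' @return Extent (um), or a data frame when `per_plane = TRUE`.
#' @export
lateral_extent <- function(state, grid, axis = c("long", "short"),
                           criterion = extent_criterion(), plane_z = NULL,
                           per_plane = FALSE, window = 1L) {
  axis <- match.arg(axis)
  w <- ref_window(grid, window)
  dx <- grid$spec$dx
  # the window's long axis is its longer side; marching axis follows it
  along_x <- if (w$lx >= w$ly) axis == "long" else axis == "short"
  if (is.null(plane_z)) {
    zsel <- which(grid$z >= grid$spec$h_pdms - 1e-9)
  } else {
    zsel <- vapply(plane_z, nearest_index, integer(1), axis_nodes = grid$z,
                   what = "plane z")
    if (any(grid$z[zsel] < grid$spec$h_pdms - 1e-9))
      stop("lateral_extent: plane_z lies inside the PDMS membrane")
  }
  thr <- criterion$threshold
  ext <- numeric(length(zsel))
  if (along_x) {
    iy <- nearest_index(w$cy, grid$y, "window centre y")
    ilo <- nearest_index(w$cx - w$lx / 2, grid$x, "window edge")
    ihi <- nearest_index(w$cx + w$lx / 2, grid$x, "window edge")
    for (j in seq_along(zsel)) {
      line <- state$P[, iy, zsel[j]]
      ext[j] <- max(march_extent(line, ihi, +1, dx, thr),
                    march_extent(line, ilo, -1, dx, thr))
    }
  } else {
    ix <- nearest_index(w$cx, grid$x, "window centre x")
    ilo <- nearest_index(w$cy - w$ly / 2, grid$y, "window edge")
    ihi <- nearest_index(w$cy + w$ly / 2, grid$y, "window edge")
    for (j in seq_along(zsel)) {
      line <- state$P[ix, , zsel[j]]
      ext[j] <- max(march_extent(line, ihi, +1, dx, thr),
                    march_extent(line, ilo, -1, dx, thr))
    }
  }
  if (per_plane) return(data.frame(z = grid$z[zsel], extent = ext))
  max(ext)
}

#' Affected-area dimensions at a horizontal plane
#'
#' The footprint of the perturbed region in the plane `plane_z` above the
#' glass: the window dimensions plus twice the lateral extent at that plane
#' along each axis.
#'
#' @param state A steady `field_state`.
#' @param grid A `sim_grid`.
#' @param plane_z Plane height above the glass (um); must lie in the tissue.
#' @param criterion An [extent_criterion()].
#' @param window Index of the layout window to evaluate.
#' @return Named numeric vector `c(long = , short = )` (um).
#' @export
affected_area <- function(state, grid, plane_z,
                          criterion = extent_criterion(), window = 1L) {
  w <- ref_window(grid, window)
  long_len <- max(w$lx, w$ly)
  short_len <- min(w$lx, w$ly)
  a <- lateral_extent(state, grid, "long", criterion, plane_z, window = window)
  b <- lateral_extent(state, grid, "short", criterion, plane_z, window = window)
  c(long = long_len + 2 * a, short = short_len + 2 * b)
}

#' Settling time of a probe trace
#'
#' First time after the start of the trace at which the probe stays within
#' `tol` of its final value for the remainder of the trace. Intended for a
#' single protocol segment following a step change.
#'
#' @param t Times (s).
#' @param p Probe PO2 values (mmHg), same length as `t`.
#' @param tol Settling band (mmHg), default 0.1.
#' @return Settling time (s, relative to `t[1]`); `Inf` (with a warning) if
#'   the trace never enters and stays in the band.
#' @export
settle_time <- function(t, p, tol = 0.1) {
  stopifnot(length(t) == length(p), length(t) >= 1)
  n <- length(t)
  dev <- abs(p - p[n])
  # last index that violates the band; settled from the next sample on
  bad <- which(dev >= tol)
  if (!length(bad)) return(0)
  s <- bad[length(bad)] + 1
  # the last sample trivially matches itself, so require the in-band tail to
  # cover a non-negligible stretch of the trace before calling it settled
  if (s > n || (t[n] - t[s]) < 0.05 * (t[n] - t[1])) {
    warning("settle_time: trace never settles within tol = ", tol,
            " mmHg (in-band tail too short to call steady)")
    return(Inf)
  }
  t[s] - t[1]
}

#' Extract a 2D section from the field
#'
#' Pulls a horizontal plane (`kind = "z-plane"`, coordinate = height above
#' the glass) or a vertical slice (`kind = "vertical-slice"`, coordinate = y;
#' an x-z section through the window long axis when y is the window centre)
#' with physical axis coordinates, ready for plotting or CSV export. The
#' nearest grid plane is used.
#'
#' @param state A `field_state`.
#' @param grid A `sim_grid`.
#' @param kind `"z-plane"` or `"vertical-slice"`.
#' @param coordinate Plane position (um).
#' @return A list: `values` (matrix), `axis1`, `axis2` (coordinate vectors,
#'   um), `kind`, `coordinate` (the grid-aligned value actually used).
#' @export
extract_section <- function(state, grid, kind = c("z-plane", "vertical-slice"),
                            coordinate) {
  kind <- match.arg(kind)
  if (kind == "z-plane") {
    iz <- nearest_index(coordinate, grid$z, "section z")
    list(values = state$P[, , iz], axis1 = grid$x, axis2 = grid$y,
         kind = kind, coordinate = grid$z[iz])
  } else {
    iy <- nearest_index(coordinate, grid$y, "section y")
    list(values = state$P[, iy, ], axis1 = grid$x, axis2 = grid$z,
         kind = kind, coordinate = grid$y[iy])
  }
}

#' Full perturbation-extent report
#'
#' Runs all extent metrics on a steady field and collects them with their
#' evaluation metadata (criterion threshold, evaluation loci, grid spacing)
#' into a list that serialises cleanly to JSON.
#'
#' @param state A steady `field_state`.
#' @param grid A `sim_grid`.
#' @param criterion An [extent_criterion()].
#' @param plane_z Plane (um above the glass) for the affected-area metric.
#' @param window Index of the layout window to evaluate.
#' @return A list with `depth_from_tissue_surface`, `lateral_long_axis`,
#'   `lateral_short_axis` (maxima over planes), `affected_area` at `plane_z`,
#'   and `meta`.
#' @export
extent_report <- function(state, grid, criterion = extent_criterion(),
                          plane_z = 75, window = 1L) {
  w <- ref_window(grid, window)
  area <- affected_area(state, grid, plane_z, criterion, window)
  list(
    depth_from_tissue_surface = penetration_depth(state, grid, criterion, window),
    lateral_long_axis = lateral_extent(state, grid, "long", criterion,
                                       window = window),
    lateral_short_axis = lateral_extent(state, grid, "short", criterion,
                                        window = window),
    affected_area = list(plane_z = plane_z,
                         long = unname(area["long"]),
                         short = unname(area["short"])),
    meta = list(
      threshold_mmHg_per_um = criterion$threshold,
      derivative = "central difference, magnitude",
      depth_locus = "vertical line through window centroid",
      lateral_locus = paste("axis-aligned rays from window edge midpoints,",
                            "both directions, maximum over tissue planes"),
      window = as.list(w),
      dx_um = grid$spec$dx))
}
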