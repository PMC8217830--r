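#' Domain specification for the two-region simulation block
#'
#' Describes the simulated volume: a PDMS slab of thickness `h_pdms` sitting
#' on the glass slide (the plane z = 0), with a block of tissue of height
#' `Lz_tissue` on top. z increases from the glass into the tissue, so the
#' tissue surface sits at z = `h_pdms`. The grid is vertex-centred and
#' isotropic with spacing `dx`; the PDMS/tissue interface must fall on a grid
#' plane, so `h_pdms` must be an integer multiple of `dx`.
#'
#' The defaults place every reported perturbation extent (~130 um depth,
#' ~120 um lateral) at least 150 um away from all zero-flux outer boundaries,
#' so the far field genuinely plateaus before the box ends.
#'
#' @param Lx,Ly Lateral extents of the footprint (um); 0 collapses an axis to
#'   a single node layer (1D/2D verification columns).
#' @param Lz_tissue Tissue height above the membrane (um).
#' @param h_pdms PDMS membrane thickness (um); 0 gives an all-tissue column
#'   (useful for one-material verification problems).
#' @param dx Isotropic grid spacing (um).
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(Lx = 1200, Ly = 1000, Lz_tissue = 300,
                        h_pdms = 25, dx = 5) {
  if (any(c(Lz_tissue, dx) <= 0) || h_pdms < 0 || Lx < 0 || Ly < 0)
    stop("domain_spec: Lz_tissue and dx must be positive, Lx/Ly/h_pdms non-negative")
  for (nm in c("h_pdms", "Lz_tissue")) {
    v <- get(nm)
    if (abs(v / dx - round(v / dx)) > 1e-9)
      stop("domain_spec: '", nm, "' (", v,
           " um) must be an integer multiple of dx (", dx,
           " um) so the material interface is grid-aligned")
  }
  structure(list(Lx = Lx, Ly = Ly, Lz_tissue = Lz_tissue,
                 h_pdms = h_pdms, dx = dx),
            class = "domain_spec")
}

#' Gas-exchange window layout on the glass plane
#'
#' A set of axis-aligned rectangular openings in the glass at z = 0 where the
#' chamber gas contacts the PDMS directly and the PO2 is clamped to the
#' chamber value. Everywhere else the glass is an oxygen barrier (zero flux).
#'
#' @param cx,cy Rectangle centres (um), vectorised.
#' @param lx,ly Rectangle side lengths along x and y (um).
#' @return An object of class `window_layout`: a data frame with columns
#'   `cx`, `cy`, `lx`, `ly`.
#' @examples
#' window_layout(600, 500, 400, 200)  # one 400 x 200 um window
#' @export
window_layout <- function(cx, cy, lx, ly) {
  df <- data.frame(cx = cx, cy = cy, lx = lx, ly = ly)
  if (nrow(df) > 0 && any(df$lx < 0 | df$ly < 0))
    stop("window_layout: window side lengths must be non-negative")
  if (nrow(df) > 1) {
    for (i in seq_len(nrow(df) - 1)) for (j in (i + 1):nrow(df)) {
      if (abs(df$cx[i] - df$cx[j]) < (df$lx[i] + df$lx[j]) / 2 &&
          abs(df$cy[i] - df$cy[j]) < (df$ly[i] + df$ly[j]) / 2)
        stop("window_layout: windows ", i, " and ", j, " overlap")
    }
  }
  structure(df, class = c("window_layout", "data.frame"))
}

#' Row of equally spaced exchange windows
#'
#' Builds `count` collinear windows along x, centred on the domain footprint,
#' emulating a slide patterned with several windows so the tissue can be
#' positioned over whichever is best aligned. The fabricated slides carry
#' five; the pitch is a design choice and must be supplied.
#'
#' @param pitch Centre-to-centre spacing along x (um).
#' @param window_length Window dimension along x (um).
#' @param window_width Window dimension along y (um).
#' @param count Number of windows (default 5).
#' @param center_x,center_y Centre of the whole row (um); defaults centre the
#'   row at the origin and are usually overridden with the domain centre.
#' @return A [window_layout()].
#' @export
five_window_layout <- function(pitch, window_length, window_width,
                               count = 5, center_x = 0, center_y = 0) {
  if (count < 1) stop("five_window_layout: count must be >= 1")
  if (count > 1 && pitch <= window_length)
    stop("five_window_layout: pitch (", pitch,
         " um) must exceed the window length (", window_length,
         " um) or adjacent windows overlap")
  offs <- (seq_len(count) - (count + 1) / 2) * pitch
  window_layout(center_x + offs, rep(center_y, count),
                rep(window_length, count), rep(window_width, count))
}

#' Build the simulation grid and boundary masks
#'
#' Discretises a [domain_spec()] into a vertex-centred grid, labels each
#' z-level as PDMS (0 <= z <= h_pdms) or tissue (z > h_pdms), and derives the
#' window mask: the z = 0 nodes whose (x, y) falls inside a closed layout
#' rectangle carry a fixed-PO2 (Dirichlet) condition; every other boundary
#' node of the box — the rest of the glass plane, the four lateral faces and
#' the top — is zero-flux.
#'
#' @param spec A [domain_spec()].
#' @param layout A [window_layout()]; may have zero rows (no window).
#' @return An object of class `sim_grid`: a list with node coordinate vectors
#'   `x`, `y`, `z` (um), counts `nx`, `ny`, `nz`, the number of PDMS z-levels
#'   `n_pdms` (levels `1..n_pdms` are membrane; 0 when `h_pdms = 0`), the
#'   logical `window_mask` (`nx` x `ny`, the z = 0 plane), and the originating
#'   `spec` and `layout`.
#' @examples
#' g <- build_grid(domain_spec(), window_layout(600, 500, 400, 200))
#' sum(g$window_mask)  # 81 x 41 nodes under a 400 x 200 window at dx = 5
#' @export
build_grid <- function(spec, layout = window_layout(numeric(0), numeric(0),
                                                    numeric(0), numeric(0))) {
  stopifnot(inherits(spec, "domain_spec"), inherits(layout, "window_layout"))
  dx <- spec$dx
  nx <- floor(spec$Lx / dx + 1e-9) + 1L
  ny <- floor(spec$Ly / dx + 1e-9) + 1L
  Lz <- spec$h_pdms + spec$Lz_tissue
  nz <- floor(Lz / dx + 1e-9) + 1L
  x <- (seq_len(nx) - 1L) * dx
  y <- (seq_len(ny) - 1L) * dx
  z <- (seq_len(nz) - 1L) * dx
  n_pdms <- as.integer(round(spec$h_pdms / dx)) + if (spec$h_pdms > 0) 1L else 0L

  mask <- matrix(FALSE, nx, ny)
  if (nrow(layout) > 0) {
    for (i in seq_len(nrow(layout))) {
      x0 <- layout$cx[i] - layout$lx[i] / 2; x1 <- layout$cx[i] + layout$lx[i] / 2
      y0 <- layout$cy[i] - layout$ly[i] / 2; y1 <- layout$cy[i] + layout$ly[i] / 2
      if (x0 < -1e-9 || y0 < -1e-9 || x1 > spec$Lx + 1e-9 || y1 > spec$Ly + 1e-9)
        stop("build_grid: window ", i, " extends outside the domain footprint")
      inx <- x >= x0 - 1e-9 & x <= x1 + 1e-9
      iny <- y >= y0 - 1e-9 & y <= y1 + 1e-9
      mask[inx, iny] <- TRUE
    }
  }
  structure(list(x = x, y = y, z = z, nx = nx, ny = ny, nz = nz,
                 n_pdms = n_pdms, window_mask = mask,
                 spec = spec, layout = layout),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Simulation grid: %d x %d x %d nodes (dx = %g um)\n",
              x$nx, x$ny, x$nz, s$dx))
  cat(sprintf("  footprint %g x %g um, PDMS %g um (%d z-levels), tissue %g um\n",
              s$Lx, s$Ly, s$h_pdms, x$n_pdms, s$Lz_tissue))
  cat(sprintf("  windows: %d, fixed-PO2 nodes on glass plane: %d of %d\n",
              nrow(x$layout), sum(x$window_mask), x$nx * x$ny))
  invisible(x)
}

# Nearest grid index along an axis; coordinate must lie inside the domain.
nearest_index <- function(coord, axis_nodes, what = "coordinate") {
  if (coord < min(axis_nodes) - 1e-9 || coord > max(axis_nodes) + 1e-9)
    stop("'", what, "' = ", coord, " um lies outside the domain")
  which.min(abs(axis_nodes - coord))
}
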