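#' Closed-form steady profile across two purely diffusive layers
#'
#' Steady 1D diffusion through two stacked layers with fixed PO2 at both
#' ends and no reaction. Continuity of P and of the flux `D*k*dP/dz` at the
#' interface makes the profile piecewise linear with interface value
#' `P_i = (c1*P_left + c2*P_right) / (c1 + c2)` where `c_j = D_j*k_j / L_j`.
#' Used to validate the solver's dissimilar-solubility interface stencil.
#'
#' @param layer1,layer2 Lists with `thickness` (um), `D` (um^2/s), `k`
#'   (solubility); layer 1 starts at z = 0.
#' @param P_left PO2 at z = 0 (mmHg).
#' @param P_right PO2 at z = total thickness (mmHg).
#' @return A function `P(z)` (vectorised, um -> mmHg) with the interface
#'   value attached as attribute `"interface_po2"`.
#' @export
two_layer_steady_profile <- function(layer1, layer2, P_left, P_right) {
  for (l in list(layer1, layer2))
    if (any(c(l$thickness, l$D, l$k) <= 0))
      stop("two_layer_steady_profile: layer properties must be positive")
  c1 <- layer1$D * layer1$k / layer1$thickness
  c2 <- layer2$D * layer2$k / layer2$thickness
  Pi <- (c1 * P_left + c2 * P_right) / (c1 + c2)
  L1 <- layer1$thickness; L <- L1 + layer2$thickness
  f <- function(z) {
    ifelse(z <= L1,
           P_left + (Pi - P_left) * z / L1,
           Pi + (P_right - Pi) * (z - L1) / (L - L1))
  }
  attr(f, "interface_po2") <- Pi
  f
}

#' Krogh-type penetration depth for zero-order consumption
#'
#' In the limit `P >> P50` (consumption saturated at `M0`) with no capillary
#' resupply, the classical slab solution below a surface held at `Ps` has P
#' and dP/dz vanishing together at depth `sqrt(2 D Ps / (M0/k))`. A useful
#' independent scale for how deep a window challenge can reach.
#'
#' @param Ps Surface PO2 (mmHg).
#' @param tissue A [tissue_params()].
#' @return Depth (um).
#' @examples
#' krogh_slab_depth(15, tissue_params())  # ~134 um
#' @export
krogh_slab_depth <- function(Ps, tissue = tissue_params()) {
  if (Ps < 0) stop("krogh_slab_depth: Ps must be non-negative")
  sqrt(2 * tissue$D * Ps / (tissue$M0 / tissue$k))
}

#' Closed-form profile for linearised consumption
#'
#' Steady 1D diffusion with consumption linear in P (`alpha * P`), fixed
#' `Ps` at z = 0 and zero flux at z = L:
#' `P(z) = Ps cosh((L - z)/l) / cosh(L/l)` with `l = sqrt(D/alpha)`.
#' The capillary source linearises to exactly this form around `P0` with
#' `alpha = K/P0`, so the production solver can be cross-checked against it
#' on a single-material column.
#'
#' @param Ps Surface value at z = 0 (mmHg).
#' @param alpha Linear consumption rate (1/s).
#' @param L Column height (um).
#' @param D Diffusivity (um^2/s).
#' @return A function `P(z)` (vectorised) with decay length attached as
#'   attribute `"decay_length"`.
#' @export
linear_consumption_profile <- function(Ps, alpha, L, D) {
  if (alpha <= 0 || L <= 0 || D <= 0)
    stop("linear_consumption_profile: alpha, L, D must be positive")
  l <- sqrt(D / alpha)
  f <- function(z) Ps * cosh((L - z) / l) / cosh(L / l)
  attr(f, "decay_length") <- l
  f
}

#' Dense Newton solution of the full nonlinear steady problem
#'
#' Solves the steady-state stencil equations of the two-region model
#' directly, by damped Newton iteration on a sparse assembly, on a small
#' grid (at most ~12 nodes per axis). The assembly is written independently
#' of the time-stepping kernel — plain R loops over nodes building a
#' triplet sparse matrix — so agreement with the time-marched steady state
#' is a genuine two-route check of the discretisation.
#'
#' @param grid A small `sim_grid` (refuses more than 2000 nodes).
#' @param tissue,membrane Material parameters.
#' @param window_po2 Window boundary PO2 (mmHg).
#' @param tol Residual infinity-norm tolerance (mmHg/s-equivalent units).
#' @param max_iter Newton iteration cap.
#' @return A `field_state` at the steady solution (`t = Inf`).
#' @export
dense_steady_solution <- function(grid, tissue = tissue_params(),
                                  membrane = membrane_params(), window_po2,
                                  tol = 1e-10, max_iter = 60) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  n <- nx * ny * nz
  if (n > 2000) stop("dense_steady_solution: grid too large (", n,
                     " nodes); this oracle is for verification grids only")
  dx2 <- grid$spec$dx^2
  npd <- grid$n_pdms
  Dt <- tissue$D; kt <- tissue$k; Dp <- membrane$D; kp <- membrane$k
  keff <- (kt + kp) / 2
  iz_int <- if (npd > 0 && npd < nz) npd else -1L  # interface z-level (1-based)
  lin <- function(ix, iy, iz) ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  # row coefficients (divided by the row node's solubility): faces carry the
  # pure material they traverse; the interface node balances its one-sided
  # fluxes over a composite half/half control volume
  lat_coef <- function(iz) {
    if (iz == iz_int) 0.5 * (Dt * kt + Dp * kp) / keff
    else if (iz <= npd) Dp else Dt
  }
  vert_coef <- function(iz_from, iz_to) {
    if (iz_from == iz_int) {
      if (iz_to > iz_from) Dt * kt / keff else Dp * kp / keff
    } else if (iz_from <= npd) Dp else Dt
  }
  react_scale <- function(iz) {
    if (iz == iz_int) 0.5 * kt / keff else if (iz <= npd) 0 else 1
  }
  # assemble the constant diffusion operator and identify fixed nodes
  fixed <- logical(n)
  if (any(grid$window_mask)) {
    wm <- which(grid$window_mask)  # linear over nx*ny at iz = 1
    fixed[wm] <- TRUE
  }
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    i <- lin(ix, iy, iz)
    if (fixed[i]) { ii <- c(ii, i); jj <- c(jj, i); vv <- c(vv, 1); next }
    # mirror-ghost zero flux: a one-sided face carries a doubled coefficient
    nb <- list()
    if (nx > 1) {
      m <- if (ix == 1 || ix == nx) 2 else 1
      if (ix > 1)  nb <- c(nb, list(c(lin(ix - 1, iy, iz), m * lat_coef(iz))))
      if (ix < nx) nb <- c(nb, list(c(lin(ix + 1, iy, iz), m * lat_coef(iz))))
    }
    if (ny > 1) {
      m <- if (iy == 1 || iy == ny) 2 else 1
      if (iy > 1)  nb <- c(nb, list(c(lin(ix, iy - 1, iz), m * lat_coef(iz))))
      if (iy < ny) nb <- c(nb, list(c(lin(ix, iy + 1, iz), m * lat_coef(iz))))
    }
    if (nz > 1) {
      m <- if (iz == 1 || iz == nz) 2 else 1
      if (iz > 1)  nb <- c(nb, list(c(lin(ix, iy, iz - 1),
                                      m * vert_coef(iz, iz - 1))))
      if (iz < nz) nb <- c(nb, list(c(lin(ix, iy, iz + 1),
                                      m * vert_coef(iz, iz + 1))))
    }
    diagc <- 0
    for (e in nb) {
      ii <- c(ii, i); jj <- c(jj, e[1]); vv <- c(vv, e[2] / dx2)
      diagc <- diagc - e[2] / dx2
    }
    ii <- c(ii, i); jj <- c(jj, i); vv <- c(vv, diagc)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  rsc <- rep(vapply(seq_len(nz), react_scale, numeric(1)), each = nx * ny)
  rsc[fixed] <- 0
  reac_node <- rsc > 0
  Mk <- tissue$M0 / tissue$k
  resid <- function(P) {
    r <- as.numeric(A %*% P)
    w <- rsc[reac_node]
    r[reac_node] <- r[reac_node] +
      w * (tissue$K * (1 - P[reac_node] / tissue$P0) -
             Mk * P[reac_node] / (P[reac_node] + tissue$P50))
    r[fixed] <- P[fixed] - window_po2
    r
  }
  P <- rep(equilibrium_po2(tissue), n)
  P[fixed] <- window_po2
  for (iter in seq_len(max_iter)) {
    r <- resid(P)
    if (max(abs(r)) < tol) break
    dreac <- numeric(n)
    dreac[reac_node] <- rsc[reac_node] *
      (-tissue$K / tissue$P0 -
         Mk * tissue$P50 / (P[reac_node] + tissue$P50)^2)
    J <- A + Matrix::Diagonal(n, x = dreac)
    step <- as.numeric(Matrix::solve(J, -r))
    # damped line search on the residual norm
    lambda <- 1
    r0 <- max(abs(r))
    repeat {
      Pn <- P + lambda * step
      if (max(abs(resid(Pn))) < r0 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    P <- Pn
    if (iter == max_iter && max(abs(resid(P))) >= tol)
      stop("dense_steady_solution: Newton failed to converge (residual ",
           signif(max(abs(resid(P))), 3), ")")
  }
  structure(list(P = array(P, dim = c(nx, ny, nz)), t = Inf),
            class = "field_state")
}
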