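# Shared fixtures. Everything is generated in code; the expensive reference
# simulation (the low-O2 challenge on the full default footprint) is computed
# once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

default_tp <- tissue_params()
default_mp <- membrane_params()

# A small, coarse two-region grid for fast 3D behavioural tests.
coarse_grid <- function(Lx = 600, Ly = 500, Lz = 150, dx = 12.5,
                        win_lx = 200, win_ly = 100,
                        cx = Lx / 2, cy = Ly / 2) {
  build_grid(domain_spec(Lx = Lx, Ly = Ly, Lz_tissue = Lz,
                         h_pdms = 25, dx = dx),
             window_layout(cx, cy, win_lx, win_ly))
}

# 1D all-tissue column (no membrane), whole glass plane as window.
column_grid <- function(L = 200, dx = 2, h_pdms = 0) {
  build_grid(domain_spec(Lx = 0, Ly = 0, Lz_tissue = L,
                         h_pdms = h_pdms, dx = dx),
             window_layout(0, 0, 0, 0))
}

# Reaction-free tissue: vanishing consumption and capillary exchange.
inert_tissue <- function(D = default_tp$D, k = default_tp$k) {
  tissue_params(D = D, k = k, M0 = 1e-300, K = 1e-300,
                P0 = default_tp$P0, P50 = default_tp$P50)
}

# The reference low-O2 challenge: full default footprint at dx = 6.25 um,
# 5% baseline steady state, instantaneous switch to 2% with centre-line
# probes at 25..100 um above the glass, then the 2% steady field.
low_o2_reference <- function() {
  if (!is.null(.cache$ref)) return(.cache$ref)
  tp <- default_tp; mp <- default_mp
  g <- build_grid(domain_spec(dx = 6.25),
                  window_layout(600, 500, 400, 200))
  po2_5 <- percent_to_po2(0.05)
  po2_2 <- percent_to_po2(0.02)
  base <- run_to_steady_state(init_state(g, tp, window_po2 = po2_5),
                              po2_5, g, tp, mp)
  probes <- data.frame(x = 600, y = 500, z = c(25, 50, 75, 100),
                       name = paste0("z", c(25, 50, 75, 100)))
  low <- run_to_steady_state(base$state, po2_2, g, tp, mp, probes = probes)
  .cache$ref <- list(grid = g, base = base, low = low)
  .cache$ref
}

# Solver verification table, computed once.
verification_table <- function() {
  if (is.null(.cache$verify)) .cache$verify <- verify_solver(quiet = TRUE)
  .cache$verify
}

# Synthetic field whose PO2 depends only on z as an exponential decay.
exp_depth_field <- function(grid, A, lambda) {
  P <- array(rep(A * exp(-grid$z / lambda), each = grid$nx * grid$ny),
             dim = c(grid$nx, grid$ny, grid$nz))
  structure(list(P = P, t = Inf), class = "field_state")
}
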