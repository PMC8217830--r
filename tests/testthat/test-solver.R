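test_that("stability bound follows the dx^2/(6 max D) law", {
  tp <- default_tp; mp <- default_mp
  expect_equal(stable_dt(domain_spec(dx = 5), tp, mp), 0.9 * 25 / (6 * 3400))
  expect_equal(stable_dt(domain_spec(dx = 2, h_pdms = 0), tp, mp),
               0.9 * 4 / (6 * 3400))
  expect_equal(stable_dt(domain_spec(dx = 2.5), tp, mp),
               stable_dt(domain_spec(dx = 5), tp, mp) / 4)
})

test_that("a single tissue node follows the semi-implicit update closed form", {
  g <- build_grid(domain_spec(Lx = 0, Ly = 0, Lz_tissue = 5, h_pdms = 0,
                              dx = 5))
  st <- init_state(g, default_tp, value = 0)
  s1 <- step_field(st, 1e-3, g, default_tp, default_mp, window_po2 = 0)
  # zero Laplacian: P+ = dt*K / (1 + dt*K/P0)
  expect_equal(s1$P[1, 1, 1], (1e-3 * 30) / (1 + 1e-3 * 30 / 48),
               tolerance = 1e-12)
})

test_that("the uniform reaction equilibrium is a fixed point of the update", {
  g <- build_grid(domain_spec(Lx = 50, Ly = 50, Lz_tissue = 50, h_pdms = 25,
                              dx = 5))  # no window
  eq <- equilibrium_po2(default_tp)
  st <- init_state(g, default_tp, value = eq)
  s <- step_field(st, stable_dt(g$spec), g, default_tp, default_mp,
                  window_po2 = 0, nsteps = 20)
  expect_lt(max(abs(s$P - eq)), 1e-12)
})

test_that("a reaction-free column with fixed ends relaxes to a line", {
  # single-material column with membrane properties everywhere: pure PDMS
  pdms_as_tissue <- tissue_params(D = default_mp$D, k = default_mp$k,
                                  M0 = 1e-300, K = 1e-300, P0 = 48, P50 = 0.5)
  g <- column_grid(L = 100, dx = 2.5)
  r <- run_to_steady_state(init_state(g, pdms_as_tissue, value = 30,
                                      window_po2 = 10),
                           10, g, pdms_as_tissue, default_mp,
                           solver_settings(steady_tol = 1e-9, max_time = 300),
                           top_po2 = 50)
  expect_true(r$converged)
  lin <- 10 + (50 - 10) * g$z / 100
  expect_lt(max(abs(as.numeric(r$state$P) - lin)), 1e-6)
})

test_that("an oversized time step is reported as an instability", {
  g <- coarse_grid()
  st <- init_state(g, default_tp, window_po2 = 15.2)
  dt_bad <- 10 * stable_dt(g$spec)
  expect_error(step_field(st, dt_bad, g, default_tp, default_mp,
                          window_po2 = 15.2, nsteps = 500),
               "instability")
})

test_that("steady states bracket the equilibrium (comparison principle)", {
  g <- coarse_grid()
  eq <- equilibrium_po2(default_tp)
  low <- run_to_steady_state(init_state(g, default_tp, window_po2 = 15.2),
                             15.2, g, default_tp, default_mp)
  expect_true(low$converged)
  expect_lte(max(low$state$P), eq + 1e-6)
  hi_po2 <- 150
  high <- run_to_steady_state(init_state(g, default_tp, window_po2 = hi_po2),
                              hi_po2, g, default_tp, default_mp)
  expect_true(high$converged)
  expect_gte(min(high$state$P), eq - 1e-6)
})

test_that("the centre-line profile decays monotonically to the plateau", {
  g <- coarse_grid()
  low <- run_to_steady_state(init_state(g, default_tp, window_po2 = 15.2),
                             15.2, g, default_tp, default_mp)
  ix <- which.min(abs(g$x - 300)); iy <- which.min(abs(g$y - 250))
  prof <- low$state$P[ix, iy, ]
  # strictly increasing with z until within a hair of the far-field plateau
  plateau <- max(prof)
  rising <- prof < plateau - 1e-3
  expect_true(all(diff(prof[rising]) > 0))
})

test_that("restarting from a steady state settles immediately", {
  g <- coarse_grid()
  low <- run_to_steady_state(init_state(g, default_tp, window_po2 = 15.2),
                             15.2, g, default_tp, default_mp)
  again <- run_to_steady_state(low$state, 15.2, g, default_tp, default_mp)
  expect_true(again$converged)
  dt <- stable_dt(g$spec)
  expect_lte(again$settle_time, 2 * dt)
})

test_that("a well-mixed no-window domain follows the scalar reaction ODE", {
  g <- build_grid(domain_spec(Lx = 10, Ly = 10, Lz_tissue = 10, h_pdms = 0,
                              dx = 5))
  dt <- 2e-6; Tend <- 0.2
  st <- init_state(g, default_tp, value = 48)
  s <- step_field(st, dt, g, default_tp, default_mp, window_po2 = 0,
                  nsteps = round(Tend / dt))
  # classic RK4 on dP/dt = reaction_rate(P), independent of the PDE kernel
  P <- 48; h <- 1e-4
  for (i in seq_len(round(Tend / h))) {
    k1 <- reaction_rate(P, default_tp)
    k2 <- reaction_rate(P + h / 2 * k1, default_tp)
    k3 <- reaction_rate(P + h / 2 * k2, default_tp)
    k4 <- reaction_rate(P + h * k3, default_tp)
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(abs(s$P - P)), 1e-6)
})

test_that("steady solutions converge at second order on the cosh column", {
  # linear-consumption column: exact solution known, so the order of the
  # spatial discretisation can be estimated from two resolutions
  tp <- default_tp
  lin <- tissue_params(D = tp$D, k = tp$k, M0 = 1e-300, K = tp$K,
                       P0 = tp$P0, P50 = tp$P50)
  Ps <- 10; L <- 200
  ref <- function(z) tp$P0 +
    linear_consumption_profile(Ps - tp$P0, tp$K / tp$P0, L, tp$D)(z)
  err <- sapply(c(2, 1), function(dx) {
    g <- column_grid(L = L, dx = dx)
    r <- run_to_steady_state(init_state(g, tp, value = tp$P0,
                                        window_po2 = Ps),
                             Ps, g, lin, default_mp,
                             solver_settings(steady_tol = 1e-9,
                                             max_time = 300))
    max(abs(as.numeric(r$state$P) - ref(g$z)))
  })
  order <- log2(err[1] / err[2])
  expect_gte(order, 1.7)
})

test_that("run_protocol steps through segments and plateaus within each", {
  g <- coarse_grid()
  tp <- default_tp; mp <- default_mp
  base <- run_to_steady_state(init_state(g, tp, window_po2 = 38), 38,
                              g, tp, mp)
  probes <- data.frame(x = 300, y = 250, z = c(50, 100),
                       name = c("z50", "z100"))
  pr <- square_wave_protocol()
  res <- run_protocol(base$state, pr, g, tp, mp, probes = probes,
                      settings = solver_settings(record_dt = 0.5))
  expect_true(all(res$segment_settled))
  expect_equal(res$state$t, base$state$t + 360)
  expect_equal(max(res$trace$t) - min(res$trace$t), 360, tolerance = 0.01)
  # probe PO2 tracks the imposed gas: lowest during 2%, highest during 12%
  seg <- findInterval(res$trace$t - min(res$trace$t), c(0, 60, 180, 300),
                      rightmost.closed = FALSE)
  m <- tapply(res$trace$z50, seg, function(x) x[length(x)])
  expect_gt(m[["2"]], m[["1"]])  # 12% end higher than 5% end
  expect_lt(m[["3"]], m[["1"]])  # 2% end lower than 5% end
})

test_that("a constant protocol reproduces the steady-state march", {
  g <- coarse_grid()
  tp <- default_tp; mp <- default_mp
  probes <- data.frame(x = 300, y = 250, z = 50, name = "p")
  st <- init_state(g, tp, window_po2 = 15.2)
  stt <- solver_settings(record_dt = 0.25)
  a <- run_to_steady_state(st, 15.2, g, tp, mp, settings = stt,
                           probes = probes)
  b <- run_protocol(st, gas_protocol(10, 0.02), g, tp, mp, probes = probes,
                    settings = stt)
  shared <- intersect(round(a$trace$t, 9), round(b$trace$t, 9))
  expect_gt(length(shared), 10)
  ia <- match(shared, round(a$trace$t, 9))
  ib <- match(shared, round(b$trace$t, 9))
  expect_equal(a$trace$p[ia], b$trace$p[ib], tolerance = 1e-12)
})
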