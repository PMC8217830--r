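test_that("penetration depth matches the closed form on exponential fields", {
  g <- build_grid(domain_spec(Lx = 20, Ly = 20, Lz_tissue = 300, h_pdms = 0,
                              dx = 2),
                  window_layout(10, 10, 20, 20))
  A <- 40; lambda <- 40
  fld <- exp_depth_field(g, A, lambda)
  crit <- extent_criterion()
  # |dP/dz| = (A/lambda) exp(-z/lambda) >= theta up to z* = lambda ln(A/(lambda theta))
  zstar <- lambda * log(A / (lambda * crit$threshold))
  expect_equal(penetration_depth(fld, g, crit), zstar, tolerance = 2 / zstar)
  # larger threshold, shallower depth
  expect_equal(penetration_depth(fld, g, extent_criterion(0.1)),
               lambda * log(A / (lambda * 0.1)), tolerance = 2 / 50)
})

test_that("uniform fields have zero extents and window-sized affected area", {
  g <- coarse_grid()
  fld <- init_state(g, default_tp, value = 41.6)
  expect_equal(penetration_depth(fld, g), 0)
  expect_equal(lateral_extent(fld, g, "long"), 0)
  expect_equal(lateral_extent(fld, g, "short"), 0)
  expect_equal(affected_area(fld, g, plane_z = 75),
               c(long = 200, short = 100))
})

test_that("lateral extent matches the closed form on an exponential ridge", {
  # field decaying exponentially outward from the long-axis window edges
  g <- build_grid(domain_spec(Lx = 1000, Ly = 400, Lz_tissue = 100,
                              h_pdms = 0, dx = 2.5),
                  window_layout(500, 200, 400, 200))
  B <- 30; ell <- 35
  edge_hi <- 500 + 200
  s <- pmax(0, pmax(g$x - edge_hi, (500 - 200) - g$x))
  prof <- B * exp(-s / ell)
  P <- array(rep(prof, times = g$ny * g$nz), dim = c(g$nx, g$ny, g$nz))
  fld <- structure(list(P = P, t = Inf), class = "field_state")
  crit <- extent_criterion()
  sstar <- ell * log(B / (ell * crit$threshold))
  expect_equal(lateral_extent(fld, g, "long", crit), sstar,
               tolerance = 2 * 2.5 / sstar)
  # the field is flat along y, so the short-axis extent is zero
  expect_equal(lateral_extent(fld, g, "short", crit), 0)
})

test_that("extent metrics never increase with the criterion threshold", {
  ref <- low_o2_reference()
  thr <- exp(seq(-6, -1, length.out = 8))
  depths <- sapply(thr, function(th)
    penetration_depth(ref$low$state, ref$grid, extent_criterion(th)))
  longs <- sapply(thr, function(th)
    lateral_extent(ref$low$state, ref$grid, "long", extent_criterion(th)))
  shorts <- sapply(thr, function(th)
    lateral_extent(ref$low$state, ref$grid, "short", extent_criterion(th)))
  expect_true(all(diff(depths) <= 0))
  expect_true(all(diff(longs) <= 0))
  expect_true(all(diff(shorts) <= 0))
})

test_that("extents are invariant under window translation on the grid", {
  tp <- default_tp; mp <- default_mp
  run_at <- function(cx, cy) {
    g <- build_grid(domain_spec(Lx = 700, Ly = 600, Lz_tissue = 150,
                                h_pdms = 25, dx = 12.5),
                    window_layout(cx, cy, 200, 100))
    r <- run_to_steady_state(init_state(g, tp, window_po2 = 15.2), 15.2,
                             g, tp, mp)
    c(depth = penetration_depth(r$state, g),
      long = lateral_extent(r$state, g, "long"),
      short = lateral_extent(r$state, g, "short"))
  }
  a <- run_at(350, 300)
  b <- run_at(375, 275)  # shifted by two grid cells each way
  expect_lte(max(abs(a - b)), 12.5)  # agree to within one grid cell
})

test_that("settle time has its closed form on exponential approaches", {
  t <- seq(0, 20, by = 0.01)
  tau <- 1.5; Delta <- 8; pf <- 30
  p <- pf + Delta * exp(-t / tau)
  st <- settle_time(t, p, tol = 0.1)
  expect_equal(st, tau * log(Delta / 0.1), tolerance = 0.02 / st)
  expect_equal(settle_time(t, rep(5, length(t))), 0)
  expect_warning(st2 <- settle_time(seq(0, 1, 0.01), seq(0, 1, 0.01),
                                    tol = 1e-6), "never settles")
  expect_true(is.infinite(st2))
})

test_that("sections extract planes with correct shape and round-trip", {
  g <- coarse_grid()
  fld <- init_state(g, default_tp)
  fld$P[] <- seq_along(fld$P)  # unique value per node
  zp <- extract_section(fld, g, "z-plane", 75)
  expect_equal(dim(zp$values), c(g$nx, g$ny))
  expect_equal(zp$coordinate, 75)
  iz <- which(g$z == 75)
  expect_identical(zp$values, fld$P[, , iz])
  vs <- extract_section(fld, g, "vertical-slice", 250)
  expect_equal(dim(vs$values), c(g$nx, g$nz))
  expect_identical(vs$values, fld$P[, which(g$y == 250), ])
  # nearest-plane snapping
  zp2 <- extract_section(fld, g, "z-plane", 73)
  expect_equal(zp2$coordinate, 75)
  expect_error(extract_section(fld, g, "z-plane", 1e4), "outside")
})

test_that("plane restriction and PDMS planes are policed", {
  ref <- low_o2_reference()
  expect_error(lateral_extent(ref$low$state, ref$grid, "long", plane_z = 10),
               "PDMS")
  e75 <- lateral_extent(ref$low$state, ref$grid, "long", plane_z = 75)
  emax <- lateral_extent(ref$low$state, ref$grid, "long")
  expect_lte(e75, emax)
})
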