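test_that("grid discretisation has the expected fencepost counts and masks", {
  g <- build_grid(domain_spec(Lx = 1200, Ly = 1000, Lz_tissue = 300,
                              h_pdms = 25, dx = 5),
                  window_layout(600, 500, 400, 200))
  expect_equal(c(g$nx, g$ny, g$nz), c(241, 201, 66))
  expect_equal(g$n_pdms, 6)  # z-levels 0,5,...,25 um are membrane
  # closed 400 x 200 rectangle at dx = 5: 81 x 41 nodes
  expect_equal(sum(g$window_mask), 81 * 41)
  expect_equal(range(g$x[rowSums(g$window_mask) > 0]), c(400, 800))
  expect_equal(range(g$y[colSums(g$window_mask) > 0]), c(400, 600))
})

test_that("degenerate layouts: empty mask and full-footprint window", {
  spec <- domain_spec(Lx = 100, Ly = 100, Lz_tissue = 50, h_pdms = 25, dx = 5)
  g0 <- build_grid(spec)
  expect_equal(sum(g0$window_mask), 0)
  gfull <- build_grid(spec, window_layout(50, 50, 100, 100))
  expect_true(all(gfull$window_mask))
})

test_that("invalid geometry is rejected with informative errors", {
  expect_error(domain_spec(h_pdms = 27, dx = 5), "integer multiple")
  expect_error(build_grid(domain_spec(Lx = 300, Ly = 300),
                          window_layout(100, 100, 400, 200)),
               "outside the domain")
  expect_error(window_layout(c(0, 100), c(0, 0), c(300, 300), c(50, 50)),
               "overlap")
})

test_that("five-window rows are disjoint, equally pitched and centred", {
  lay <- five_window_layout(pitch = 800, window_length = 400,
                            window_width = 200, center_x = 2000,
                            center_y = 500)
  expect_equal(nrow(lay), 5)
  expect_equal(diff(lay$cx), rep(800, 4))
  expect_equal(mean(lay$cx), 2000)
  expect_equal(unique(lay$cy), 500)
  expect_error(five_window_layout(pitch = 300, window_length = 400,
                                  window_width = 200), "overlap")
  one <- five_window_layout(pitch = 800, window_length = 400,
                            window_width = 200, count = 1,
                            center_x = 600, center_y = 500)
  expect_equal(as.data.frame(one), as.data.frame(window_layout(600, 500, 400, 200)))
})

test_that("grid construction is deterministic and nests under refinement", {
  spec <- domain_spec(Lx = 200, Ly = 200, Lz_tissue = 100, h_pdms = 25, dx = 5)
  lay <- window_layout(100, 100, 80, 40)
  g1 <- build_grid(spec, lay)
  g2 <- build_grid(spec, lay)
  expect_identical(g1$window_mask, g2$window_mask)
  expect_identical(g1$z, g2$z)
  fine <- build_grid(domain_spec(Lx = 200, Ly = 200, Lz_tissue = 100,
                                 h_pdms = 25, dx = 2.5), lay)
  expect_true(all(g1$x %in% fine$x))
  expect_true(all(g1$z %in% fine$z))
  # window nodes of the coarse grid remain window nodes on the fine grid
  cw <- which(g1$window_mask, arr.ind = TRUE)
  for (r in seq_len(nrow(cw))) {
    fx <- match(g1$x[cw[r, 1]], fine$x)
    fy <- match(g1$y[cw[r, 2]], fine$y)
    expect_true(fine$window_mask[fx, fy])
  }
})
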