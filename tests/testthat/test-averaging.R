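# A coarse averaged curve is computed once per parameter set and shared
# across the tests in this file.
.curve_cache <- new.env(parent = emptyenv())
get_curve <- function(m) {
  key <- paste0("m", m)
  if (is.null(.curve_cache[[key]])) {
    zr <- if (m == 0) c(-2.5, 3) else c(-2.5, 3.2)
    .curve_cache[[key]] <- averaged_curve("fastslow", epidyn_params(m = m),
                                          z_range = zr, n_z = 150)
  }
  .curve_cache[[key]]
}

test_that("cycle averages are bounded by the envelope and converged", {
  p <- epidyn_params(m = 0)
  z <- 2.0
  cs <- epidyn:::cycle_stats("sub1", z, p, dt = 0.005, t_transient = 200,
                             t_window = 300)
  expect_identical(cs$type, "cycle")
  expect_gt(cs$mean_x1, cs$min_x1)
  expect_lt(cs$mean_x1, cs$max_x1)
  # doubling the transient changes the mean by < 1e-4
  cs2 <- epidyn:::cycle_stats("sub1", z, p, dt = 0.005, t_transient = 400,
                              t_window = 300)
  expect_lt(abs(cs$mean_x1 - cs2$mean_x1), 1e-4)
  # just below the Hopf point the mean approaches the focus value
  cf <- sub1_closed_form_points(p)
  a <- average_x1(cf$z_H - 0.001, "fastslow", p)
  eqs <- find_equilibria("sub1", p, frozen = list(z_frozen = cf$z_H - 0.001))
  foc <- Filter(function(e) e$state[["x1"]] >= 0, eqs)[[1]]
  expect_lt(abs(a$mean - foc$state[["x1"]]), 1e-2)
})

test_that("the slow averaged nullcline is linear in x0 with slope -r*s", {
  p <- epidyn_params(m = 0)
  cur <- get_curve(0)
  zs <- cur$z[cur$type == "cycle"][c(10, 50, 100)]
  v1 <- slow_nullcline(zs, -1.6, "fastslow", p, cur)
  v2 <- slow_nullcline(zs, -1.1, "fastslow", p, cur)
  expect_equal(v2 - v1, rep(-p$r * p$s * 0.5, length(zs)), tolerance = 1e-12)
  # algebraic identity for z >= 0: <zdot> + r z = r s (<x1> - x0)
  zpos <- zs[zs >= 0]
  mean_x1 <- epidyn:::approx_curve(cur, zpos)
  expect_equal(slow_nullcline(zpos, -1.6, "fastslow", p, cur) + p$r * zpos,
               p$r * p$s * (mean_x1 + 1.6), tolerance = 1e-12)
})

test_that("periodic-orbit sets match the known m = 0 and m = 2 structure", {
  p0 <- epidyn_params(m = 0)
  cur0 <- get_curve(0)
  # simple stable zero at large x0
  o <- find_periodic_orbits(1, "fastslow", p0, cur0)
  expect_equal(nrow(o), 1L)
  expect_true(o$stable[1])
  expect_equal(o$label, "LC")
  # no roots beyond the SNPO
  o <- find_periodic_orbits(-2.8, "fastslow", p0, cur0)
  expect_equal(nrow(o), 0L)

  p2 <- epidyn_params(m = 2)
  cur2 <- get_curve(2)
  # single stable zero at x0 = -1.6
  o <- find_periodic_orbits(-1.6, "fastslow", p2, cur2)
  expect_equal(nrow(o), 1L)
  expect_true(o$stable[1])
  # three zeros (stable, saddle, stable) at x0 = -1.7, ordered LC < S < SLC
  o <- find_periodic_orbits(-1.7, "fastslow", p2, cur2)
  expect_equal(nrow(o), 3L)
  expect_equal(o$label, c("LC", "S", "SLC"))
  expect_equal(o$stable, c(TRUE, FALSE, TRUE))
  expect_true(all(diff(o$z) > 0))
})

test_that("stable averaged roots agree with direct fast-slow simulation", {
  p2 <- epidyn_params(m = 2, x0 = -1.7)
  cur2 <- get_curve(2)
  o <- find_periodic_orbits(-1.7, "fastslow", p2, cur2)
  lc <- o$z[o$label == "LC"]
  # start on the cycle at z* and verify z stays nearby
  eqf <- find_equilibria("sub1", p2, frozen = list(z_frozen = lc))
  foc <- Filter(function(e) e$state[["x1"]] >= 0, eqf)[[1]]
  tr <- integrate_deterministic(
    "fastslow", c(foc$state[["x1"]] + 0.5, foc$state[["y1"]], lc),
    500, 2e-4, p2, record_every = 1000L)
  zlate <- tr$states[tr$times > 100, "z"]
  expect_lt(max(abs(zlate - lc)), 0.1)
  expect_lt(abs(mean(zlate) - lc), 0.05)
})

test_that("the SLC window for m = 2 opens and closes with x0", {
  p2 <- epidyn_params(m = 2)
  cur2 <- get_curve(2)
  sw <- sweep_x0_orbits(c(-2.6, -2.2, -1.9, -1.7, -1.6), "fastslow", p2,
                        cur2)
  n_at <- function(x0) sw$nroots[sw$x0_grid == x0]
  expect_equal(n_at(-1.6), 1L)  # only LC
  expect_equal(n_at(-1.7), 3L)  # LC, S, SLC
  expect_equal(n_at(-1.9), 2L)  # SLC gone, LC and S remain
})
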