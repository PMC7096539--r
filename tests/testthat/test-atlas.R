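test_that("interspike intervals of a pure sinusoid are constant", {
  t <- seq(0, 100, by = 0.01)
  st <- cbind(x1 = sin(2 * pi * t / 3), y1 = 0, z = 3, x2 = 0, y2 = 0, g = 0)
  r <- isi(make_traj(t, st))
  expect_lt(r$cv, 1e-3)
  expect_equal(mean(r$intervals), 3, tolerance = 1e-3)
  # too few spikes errors
  st2 <- st[t <= 4, , drop = FALSE]
  expect_error(isi(make_traj(t[t <= 4], st2), transient = 0), "spikes")
})

test_that("ISI regularity separates periodic SLC from chaotic spiking", {
  slc <- integrate_deterministic(
    "full", c(0, -5, 3, 0, 0, 0.01), 2500, 0.01,
    epidyn_params(m = 1, x0 = -1.8, Iext2 = 0), record_every = 5L)
  expect_lt(isi(slc, transient = 0.5)$cv, 0.05)
  cha <- integrate_deterministic(
    "full", c(0, -5, 3, 0, 0, 0.01), 2500, 0.01,
    epidyn_params(m = 1, x0 = -1.6, Iext2 = 0.45), record_every = 5L)
  expect_gt(isi(cha, transient = 0.5)$cv, 0.2)
})

test_that("equilibrium regions reproduce the printed multisets", {
  r <- equilibrium_region(0, -0.9)
  expect_equal(r$n, 3L)
  expect_equal(r$classes, c("saddle", "stable_focus", "unstable_focus"))
  r <- equilibrium_region(0.5, -0.9)
  expect_equal(r$classes, c("saddle", "unstable_focus", "unstable_focus"))
  r <- equilibrium_region(0, -1.6)
  expect_equal(r$classes, "saddle")
})

test_that("orbit regions on the full model report the expected label sets", {
  p <- epidyn_params(m = 0.5)
  cur <- averaged_curve("full", p, z_range = c(-2.5, 3.4), n_z = 120)
  # saddle-equilibrium regime: LC coexists with the saddle orbit S
  r <- orbit_region(0.5, -1.6, p, cur)
  expect_setequal(r$set, c("LC", "S"))
  # large x0: only LC
  r <- orbit_region(0.5, 1, p, cur)
  expect_equal(r$set, "LC")
  # far below the SNPO: no periodic orbits
  r <- orbit_region(0.5, -3.5, p, cur)
  expect_length(r$set, 0L)
})

test_that("behaviour classification matches the canonical regimes", {
  expect_equal(classify_behavior(epidyn_params(m = 0, x0 = -2.5)),
               "NORMAL_STATE")
  expect_equal(classify_behavior(epidyn_params(m = 0, x0 = -0.9),
                                 duration = 6000),
               "NONOSCILLATORY")
  expect_equal(classify_behavior(epidyn_params(m = 1, x0 = -1.6)),
               "CHAOTIC")
  expect_equal(classify_behavior(epidyn_params(m = 1, x0 = -1.8, Iext2 = 0)),
               "SLC_PERIODIC")
  expect_equal(classify_behavior(epidyn_params(m = 0, x0 = -1.6,
                                               r = 0.0005)),
               "SLE_CIRCLE")
  expect_equal(classify_behavior(epidyn_params(m = -8, x0 = -1.6, Iext2 = 0,
                                               r = 0.0005)),
               "SWITCH_DB_NS")
  expect_equal(classify_behavior(epidyn_params(m = -8, x0 = -0.6, Iext2 = 0,
                                               r = 0.0005),
                                 init = c(-0.1, -6, 3.8, 0, 0, 0.01),
                                 duration = 3000),
               "DB")
  expect_equal(classify_behavior(epidyn_params(m = 0.5, r = 0.009),
                                 init = c(0, -5, 0.01, 0, 0, 0.01),
                                 duration = 1000),
               "LC_RSE")
  expect_equal(classify_behavior(epidyn_params(m = 0.5, r = 0.009,
                                               z_law = "original"),
                                 init = c(0, -5, 0.01, 0, 0, 0.01),
                                 duration = 2000),
               "DIVERGENT")
})

test_that("behaviour labels are stable under duration doubling", {
  p <- epidyn_params(m = 0, x0 = -1.6, r = 0.0005)
  expect_equal(classify_behavior(p, duration = 2500),
               classify_behavior(p, duration = 5000))
})

test_that("basins on either side of the saddle orbit reach SLE vs LC", {
  # m = 0.5 with the standard excitability: initial z above the saddle orbit
  # yields seizure-like cycling, below it the large limit cycle (separatrix
  # property of S)
  p <- epidyn_params(m = 0.5, r = 0.009)
  lab_hi <- classify_behavior(p, init = c(0, -5, 3, 0, 0, 0.01),
                              duration = 2000)
  lab_lo <- classify_behavior(p, init = c(0, -5, 0.01, 0, 0, 0.01),
                              duration = 2000)
  expect_equal(lab_lo, "LC_RSE")
  expect_true(startsWith(lab_hi, "SLE"))
})

test_that("atlas scan rows carry the per-point descriptors", {
  sc <- atlas_scan(m_grid = c(0, 0.5), x0_grid = c(-2.5, -1.6, -0.9))
  expect_equal(nrow(sc), 6L)
  expect_equal(sc$n_equilibria[sc$m == 0 & sc$x0 == -0.9], 3)
  expect_equal(sc$classes[sc$m == 0 & sc$x0 == -1.6], "saddle")
})
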