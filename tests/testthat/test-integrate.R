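test_that("the deterministic scheme shows 4th-order step convergence", {
  p <- epidyn_params()
  init <- c(0.2, -1)
  f1 <- integrate_deterministic("sub1", init, 100, 0.01, p,
                                list(z_frozen = 3.0), record_every = 10000L)
  f2 <- integrate_deterministic("sub1", init, 100, 0.005, p,
                                list(z_frozen = 3.0), record_every = 20000L)
  d <- max(abs(f1$states[nrow(f1$states), ] - f2$states[nrow(f2$states), ]))
  expect_lt(d, 1e-5)
})

test_that("the deterministic integrator matches deSolve's fixed-step RK4", {
  skip_if_not_installed("deSolve")
  p <- epidyn_params()
  frozen <- list(z_frozen = 3.0)
  f <- function(t, y, parms) list(as.numeric(model_rhs("sub1", y, p, frozen)))
  times <- seq(0, 10, by = 0.01)
  ref <- deSolve::rk4(c(0.2, -1), times, f, NULL)
  tr <- integrate_deterministic("sub1", c(0.2, -1), 10, 0.01, p, frozen)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] -
                      as.numeric(ref[nrow(ref), 2:3]))), 1e-10)
})

test_that("subsystem 2 at strong drive converges to a limit cycle", {
  p <- epidyn_params(Iext2 = 1)
  tr <- integrate_deterministic("sub2", c(1, 0), 400, 0.01, p)
  x2 <- tr$states[, "x2"]
  half <- x2[seq(length(x2) / 2, length(x2))]
  pk <- which(diff(sign(diff(half))) == -2) + 1
  expect_gt(length(pk), 5)
  amps <- half[pk]
  expect_lt(abs(amps[length(amps)] - amps[length(amps) - 1]), 1e-3)
})

test_that("the original z-law diverges where the modified law is bounded", {
  init <- c(0, -5, 0.01, 0, 0, 0.01)
  orig <- integrate_deterministic(
    "full", init, 2000, 0.01,
    epidyn_params(m = 0.5, r = 0.009, z_law = "original"),
    record_every = 100L)
  expect_true(orig$diverged)
  modif <- integrate_deterministic(
    "full", init, 2000, 0.01, epidyn_params(m = 0.5, r = 0.009),
    record_every = 100L)
  expect_false(modif$diverged)
  expect_true(all(abs(modif$states) < 1e5))
  # the bounded run is the large fast-slow limit cycle: x1 keeps oscillating
  late <- modif$states[modif$times > 1500, "x1"]
  expect_gt(diff(range(late)), 1)
})

test_that("zero-variance Euler-Maruyama equals forward Euler exactly", {
  p <- epidyn_params(Iext2 = 0.2)
  tr <- integrate_stochastic("sub2", c(0.3, 0.1), 1, 0.01, p,
                             noise_spec(variance = 0, seed = 5))
  y <- c(0.3, 0.1)
  for (i in 1:100) y <- y + 0.01 * as.numeric(model_rhs("sub2", y, p))
  expect_identical(unname(tr$states[nrow(tr$states), ]), y)
})

test_that("stochastic runs are reproducible from their seed", {
  a <- integrate_stochastic("full", c(0, -5, 3, 0, 0, 0.01), 50, 0.01,
                            epidyn_params(), noise_spec(seed = 99))
  b <- integrate_stochastic("full", c(0, -5, 3, 0, 0, 0.01), 50, 0.01,
                            epidyn_params(), noise_spec(seed = 99))
  expect_identical(a$states, b$states)
  c2 <- integrate_stochastic("full", c(0, -5, 3, 0, 0, 0.01), 50, 0.01,
                             epidyn_params(), noise_spec(seed = 100))
  expect_false(identical(a$states, c2$states))
})

test_that("seizure-like events recur in the standard stochastic run", {
  tr <- run_preset("fig1", seed = 7, record_every = 20L)
  psi <- observable(tr, "psi")
  w <- 200
  nb <- floor(length(psi) / w)
  v <- vapply(seq_len(nb), function(i)
    stats::var(psi[((i - 1) * w + 1):(i * w)]), 0)
  active <- v > 0.5
  expect_gte(sum(diff(active) != 0), 2)
})

test_that("drop_transient composes and preserves provenance", {
  p <- epidyn_params(Iext2 = 0.2)
  tr <- integrate_stochastic("sub2", c(0.3, 0.1), 10, 0.01, p,
                             noise_spec(seed = 3))
  expect_equal(drop_transient(tr, 0)$times, tr$times)
  half <- drop_transient(tr, 5)
  expect_equal(length(half$times), sum(tr$times >= 5))
  twice <- drop_transient(drop_transient(tr, 2), 3)
  once <- drop_transient(tr, 5)
  expect_identical(twice$states, once$states)
  expect_identical(half$seed, tr$seed)
  expect_error(drop_transient(tr, 10), "cut")
})

test_that("invalid integration requests error cleanly", {
  p <- epidyn_params()
  expect_error(integrate_deterministic("sub1", c(0, 0), c(5, 1), params = p,
                                       frozen = list(z_frozen = 1)),
               "span")
  expect_error(integrate_deterministic("sub1", c(0, 0, 0), 10, params = p,
                                       frozen = list(z_frozen = 1)),
               "length")
  expect_error(noise_spec(variance = -1), "negative")
})
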