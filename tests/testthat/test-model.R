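test_that("rhs reproduces hand-evaluated derivatives", {
  # subsystem 2 at (x2, y2) = (-0.25, 0) with zero drive:
  # x2dot = x2 - x2^3 = -0.25 + 0.015625, y2dot = f2(-0.25)/tau2 = 0
  d <- model_rhs("sub2", c(-0.25, 0), epidyn_params(Iext2 = 0))
  expect_equal(unname(d), c(-0.234375, 0))

  # subsystem 1 at the stable focus of z = 3.1 (m = 0) has zero derivative
  p <- epidyn_params()
  eqs <- find_equilibria("sub1", p, frozen = list(z_frozen = 3.1))
  for (e in eqs)
    expect_lt(max(abs(model_rhs("sub1", e$state, p,
                                list(z_frozen = 3.1)))), 1e-12)

  # full model at a located equilibrium: reduced-system residual ~ 0
  pf <- epidyn_params(m = 0.5, x0 = -1.6)
  ef <- find_equilibria("full", pf)
  expect_length(ef, 1L)
  expect_lt(ef[[1]]$residual, 1e-10)
})

test_that("the piecewise field is continuous across its seams", {
  p <- epidyn_params(m = 0.7)
  for (eps in c(1e-4, 1e-6, 1e-8)) {
    # f1 seam at x1 = 0 (both pieces vanish there)
    dm <- model_rhs("sub1", c(-eps, 1), p, list(z_frozen = 2.5))
    dp <- model_rhs("sub1", c(eps, 1), p, list(z_frozen = 2.5))
    expect_lt(max(abs(dm - dp)), 10 * eps)
    # f2 seam at x2 = -0.25
    dm <- model_rhs("sub2", c(-0.25 - eps, 0.3), p)
    dp <- model_rhs("sub2", c(-0.25 + eps, 0.3), p)
    expect_lt(max(abs(dm - dp)), 10 * eps * p$a2)
    # z-law seam at z = 0
    dm <- model_rhs("fastslow", c(0.5, -1, -eps), p)
    dp <- model_rhs("fastslow", c(0.5, -1, eps), p)
    expect_lt(max(abs(dm - dp)), 10 * eps)
  }
})

test_that("analytic Jacobians agree with central finite differences", {
  set.seed(11)
  p <- epidyn_params(m = 0.3)
  for (k in 1:25) {
    st <- random_offseam_state("sub1")
    z <- runif(1, -1, 5); if (abs(z) < 0.05) z <- z + 0.1
    J <- model_jacobian("sub1", st, p, list(z_frozen = z))
    Jn <- num_jacobian(function(x) model_rhs("sub1", x, p,
                                             list(z_frozen = z)), st)
    expect_lt(max(abs(J - Jn)), 1e-6 * (1 + max(abs(J))))

    st <- random_offseam_state("sub2")
    J <- model_jacobian("sub2", st, p)
    Jn <- num_jacobian(function(x) model_rhs("sub2", x, p), st)
    expect_lt(max(abs(J - Jn)), 1e-6 * (1 + max(abs(J))))

    st <- random_offseam_state("fastslow")
    J <- model_jacobian("fastslow", st, p)
    Jn <- num_jacobian(function(x) model_rhs("fastslow", x, p), st)
    expect_lt(max(abs(J - Jn)), 1e-6 * (1 + max(abs(J))))

    st <- random_offseam_state("full")
    J <- model_jacobian("full", st, p)
    Jn <- num_jacobian(function(x) epidyn:::rhs_full5(x, p), st)
    expect_lt(max(abs(J - Jn)), 1e-6 * (1 + max(abs(J))))
  }
})

test_that("the full Jacobian has the printed structure", {
  p <- epidyn_params()
  st <- c(0.5, -1, 2, -0.1, 0.2) # x1 >= 0, z >= 0, x2 >= -0.25
  J <- model_jacobian("full", st, p)
  # z-row for z >= 0: (r s, 0, -r, 0, 0)
  expect_equal(unname(J["z", ]), c(p$r * p$s, 0, -p$r, 0, 0))
  # x2-row has no x1 dependence under the printed-Jacobian g convention
  expect_identical(J["x2", "x1"], 0)
  # subsystem-2 trace at x2 = 0: 1 - 0 - 1/tau2 = 0.9
  J2 <- model_jacobian("sub2", c(0, 0.5), p)
  expect_equal(sum(diag(J2)), 0.9)
})

test_that("Jacobian evaluation on a seam requires a declared side", {
  p <- epidyn_params()
  expect_error(model_jacobian("sub1", c(0, 1), p, list(z_frozen = 2)),
               "seam")
  Jl <- model_jacobian("sub1", c(0, 1), p, list(z_frozen = 2),
                       side = c(x1 = -1))
  Jr <- model_jacobian("sub1", c(0, 1), p, list(z_frozen = 2),
                       side = c(x1 = 1))
  expect_equal(Jl[1, 1], 0)                      # cubic branch slope at 0
  expect_equal(Jr[1, 1], p$m + 0.6 * (2 - 4)^2)  # linear branch slope
})

test_that("observables are the advertised combinations", {
  st <- cbind(x1 = c(1, 2), y1 = 0, z = 3, x2 = c(1, -1), y2 = 0, g = 0)
  tr <- make_traj(c(0, 0.01), st)
  expect_equal(observable(tr, "psi"), c(0, -3))
  expect_equal(observable(tr, "psi1"), st[, "x1"])
  expect_equal(observable(tr, "psi2"), st[, "x2"])
  expect_error(observable(tr, "nope"))
})

test_that("seizure runs alternate low- and high-variance psi segments", {
  tr <- run_preset("fig1", seed = 7, record_every = 20L)
  psi <- observable(tr, "psi")
  w <- 200
  nb <- floor(length(psi) / w)
  v <- vapply(seq_len(nb), function(i)
    stats::var(psi[((i - 1) * w + 1):(i * w)]), 0)
  expect_gt(max(v) / min(v), 10)
})
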