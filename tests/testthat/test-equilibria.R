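test_that("stability classification follows the eigenvalue rules", {
  expect_equal(classify_stability(c(-1, -2)), "stable_node")
  expect_equal(classify_stability(complex(real = 0.5,
                                          imaginary = c(2, -2))),
               "unstable_focus")
  expect_equal(classify_stability(c(-0.1, 0.3)), "saddle")
  expect_equal(classify_stability(complex(real = -0.2,
                                          imaginary = c(1, -1))),
               "stable_focus")
  expect_equal(classify_stability(c(1, 2)), "unstable_node")
  expect_equal(classify_stability(c(1e-9, -1)), "marginal")
  expect_error(classify_stability(numeric(0)))
})

test_that("subsystem 1 at z = 3.1, m = 0 has the known three equilibria", {
  p <- epidyn_params()
  eqs <- find_equilibria("sub1", p, frozen = list(z_frozen = 3.1))
  expect_length(eqs, 3L)
  cls <- sort(vapply(eqs, function(e) e$class, ""))
  expect_equal(cls, c("saddle", "stable_focus", "stable_node"))
  # the x1 < 0 cubic factorises as (x+1)(x^2 + x - 1) at these parameters
  x1s <- sort(vapply(eqs, function(e) e$state[["x1"]], 0))
  expect_equal(x1s[1], -(1 + sqrt(5)) / 2, tolerance = 1e-10)
  expect_equal(x1s[2], -1, tolerance = 1e-10)
  # quadratic-branch discriminant: R = 0.6 * 0.81, delta+ = R^2 + 20
  R <- 0.6 * (3.1 - 4)^2
  expect_equal(x1s[3], (R + sqrt(R^2 + 20)) / 10, tolerance = 1e-10)
})

test_that("analytic and generic subsystem-1 solutions agree across z", {
  p <- epidyn_params(m = 1.2)
  for (z in c(-1, 0.5, 2.8, 3.5, 4.05)) {
    a <- sub1_equilibria_analytic(z, p)
    x1a <- sort(vapply(a, function(e) e$state[["x1"]], 0))
    # every root satisfies the equilibrium condition to machine precision
    for (e in a) expect_lt(e$residual, 1e-10)
    # and classification is consistent with a fresh eigen decomposition
    for (e in a) {
      J <- model_jacobian("sub1", e$state, p, list(z_frozen = z),
                          side = c(x1 = 1))
      expect_equal(classify_stability(eigen(J, only.values = TRUE)$values,
                                      p$real_tol, p$imag_tol), e$class)
    }
  }
})

test_that("full-model equilibrium counts and classes match the regimes", {
  cases <- list(
    list(m = 0,   x0 = -1.6, n = 1, cls = "saddle"),
    list(m = 0.5, x0 = -1.6, n = 1, cls = "saddle"),
    list(m = 0,   x0 = -0.9, n = 3,
         cls = c("saddle", "stable_focus", "unstable_focus")),
    list(m = 0.5, x0 = -0.9, n = 3,
         cls = c("saddle", "unstable_focus", "unstable_focus")))
  for (cs in cases) {
    eqs <- find_equilibria("full", epidyn_params(m = cs$m, x0 = cs$x0))
    expect_length(eqs, cs$n)
    expect_equal(sort(vapply(eqs, function(e) e$class, "")), sort(cs$cls))
    for (e in eqs) expect_lt(e$residual, 1e-10)
  }
})

test_that("closed-form bifurcation points have their analytic values", {
  p <- epidyn_params()
  cf <- sub1_closed_form_points(p)
  expect_equal(cf$z_SN1, p$Iext1 - 5 / 27)
  expect_equal(cf$z_SN2, 4.1)
  expect_equal(cf$z_H, 4 - sqrt(5 / 3))
  expect_equal(cf$x1_fold, -4 / 3)
  expect_equal(cf$p, 0)
  expect_equal(cf$q, -500 / 9)
  expect_equal(cf$w, (25 / 9) * 20 * (p$Iext1 - 3))
  # for m > 1 the Hopf point does not exist and z_SN2 comes from the quartic
  cf2 <- sub1_closed_form_points(epidyn_params(m = 2))
  expect_true(is.na(cf2$z_H))
  expect_gt(cf2$z_SN2, 4.1)
  expect_lt(cf2$z_SN2, cf2$z_SN_outer)
})

test_that("the Hopf threshold in m solves Tr(J) = 0 of the x1 >= 0 focus", {
  expect_equal(hopf_m_at_z(3.1), 0.514)
  expect_equal(hopf_m_at_z(0), -8.6)
  expect_equal(hopf_m_at_z(4), 1)
  # eigenvalue confirmation: the focus flips stability across m(H)
  p <- epidyn_params()
  z <- 3.1
  lead_re_at <- function(m) {
    pm <- epidyn_params(m = m)
    eqs <- find_equilibria("sub1", pm, frozen = list(z_frozen = z))
    foci <- Filter(function(e) e$state[["x1"]] >= 0, eqs)
    max(vapply(foci, function(e) max(Re(e$eigenvalues)), 0))
  }
  mh <- hopf_m_at_z(z)
  expect_lt(lead_re_at(mh - 1e-3), 0)
  expect_gt(lead_re_at(mh + 1e-3), 0)
})

test_that("the subsystem-2 SNIC drive and root-count flip are reproduced", {
  p <- epidyn_params()
  sn <- sub2_snic_point(p)
  expect_equal(sn$Iext2, 2 / (3 * sqrt(3)))
  expect_equal(sn$x2, -1 / sqrt(3))
  # equilibrium count flips from 3 to 1 across the fold
  n_at <- function(drive)
    length(find_equilibria("sub2", p,
                           frozen = list(external_input = drive)))
  expect_equal(n_at(sn$Iext2 - 1e-3), 3L)
  expect_equal(n_at(sn$Iext2 + 1e-3), 1L)
  # Det(J2) vanishes at x2* on the left branch
  J <- model_jacobian("sub2", c(sn$x2, 0), p)
  expect_lt(abs(det(J)), 1e-12)
})

test_that("stability tables hold at sampled branch points", {
  t2 <- stability_table_check("T2", epidyn_params(m = 0))
  expect_true(all(t2$ok, na.rm = TRUE))
  expect_false(anyNA(t2$ok))
  t3 <- stability_table_check("T3", epidyn_params(m = 0.5))
  expect_true(all(t3$ok, na.rm = TRUE))
  t4 <- stability_table_check("T4", epidyn_params(m = 2))
  expect_true(all(t4$ok, na.rm = TRUE))
  t5 <- stability_table_check("T5", epidyn_params(m = 0))
  expect_true(all(t5$ok, na.rm = TRUE))
  t6 <- stability_table_check("T6", epidyn_params())
  expect_true(all(t6$ok, na.rm = TRUE))
  expect_error(stability_table_check("T4", epidyn_params(m = 0)), "range")
})

test_that("fast-slow subsystem equilibria sit on the slow nullcline", {
  p <- epidyn_params(m = 0, x0 = -1.6)
  eqs <- find_equilibria("fastslow", p)
  expect_gte(length(eqs), 1L)
  for (e in eqs) {
    expect_lt(e$residual, 1e-10)
    st <- e$state
    z <- st[["z"]]
    lhs <- if (z < 0) z + 0.1 * z^7 else z
    expect_equal(lhs, p$s * (st[["x1"]] - p$x0), tolerance = 1e-8)
  }
})
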