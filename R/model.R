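#' Right-hand side of the Epileptor systems
#'
#' Evaluates the vector field of one of the model's dynamical systems at a
#' state. Systems and state layouts:
#' \describe{
#'   \item{`"full"`}{the full model, state `(x1, y1, z, x2, y2, g)`; the
#'     low-pass filtered activity `g` is carried as a sixth state obeying
#'     `dg/dt = x1 - gamma * g` (the ODE form of the convolution kernel).}
#'   \item{`"sub1"`}{subsystem 1 `(x1, y1)` with `z` frozen
#'     (pass `frozen = list(z_frozen = z)`); uses the x2-free branch of `f1`.}
#'   \item{`"sub2"`}{subsystem 2 `(x2, y2)`, uncoupled.}
#'   \item{`"fastslow"`}{the fast-slow subsystem `(x1, y1, z)`.}
#'   \item{`"fullfast"`}{the fast `(x1, y1, x2, y2)` part of the full model at
#'     frozen `z` (requires `z_frozen`); used for bifurcation diagrams.}
#' }
#'
#' The slow z-equation follows the modified law by default (`params$z_law`),
#' which adds a `-0.1 z^7` term for `z < 0`; the original linear law is
#' selected by `epidyn_params(z_law = "original")`.
#'
#' @param system One of `"full"`, `"sub1"`, `"sub2"`, `"fastslow"`,
#'   `"fullfast"`.
#' @param state Numeric state vector of the system's dimension.
#' @param params An [epidyn_params()] object.
#' @param frozen Optional list of frozen inputs: `z_frozen` (hold z constant;
#'   for `"full"` the z-derivative is returned as zero) and `external_input`
#'   (effective drive replacing `Iext2` for `"sub2"`).
#' @return The time derivative of `state`.
#' @examples
#' p <- epidyn_params()
#' model_rhs("sub2", c(-0.25, 0), epidyn_params(Iext2 = 0))
#' @export
model_rhs <- function(system, state, params, frozen = NULL) {
  system <- check_system(system)
  state <- check_state(system, state)
  zf <- frozen_z(frozen)
  freeze <- !is.na(zf)
  if (system %in% c("sub1", "fullfast") && !freeze)
    stop("system '", system, "' needs frozen$z_frozen")
  out <- .rhs_cpp(SYSTEMS[[system]], state, cpp_pars(params, frozen),
                  if (freeze) zf else 0, freeze)
  names(out) <- SYS_VARS[[system]]
  out
}

# E(x1, z): d(x1dot)/dx1 contribution of -f1 for the uncoupled branches.
E_sub1 <- function(x1, z, params, side_x1 = 0) {
  left <- x1 < 0 || (x1 == 0 && side_x1 < 0)
  if (left) -3 * params$a * x1^2 + 2 * params$b * x1
  else params$m + 0.6 * (z - 4)^2
}

on_seam <- function(v, seam) isTRUE(v == seam)

#' Analytic Jacobians of the Epileptor systems
#'
#' Returns the Jacobian matrix of [model_rhs()] at a state. For the full
#' model the Jacobian is the 5x5 matrix in the variables
#' `(x1, y1, z, x2, y2)`: under the default `g_convention = "omit"` the
#' `0.002 g` forcing of the x2-equation is not differentiated (the x2-row has
#' no x1-dependence), matching the model's printed Jacobian; under
#' `"stationary"` the quasi-static value `g* = x1 / gamma` is substituted,
#' adding `0.002 / gamma` to the `(x2, x1)` entry.
#'
#' The vector field is piecewise smooth with seams at `x1 = 0`, `x2 = -0.25`
#' and `z = 0`. Evaluating exactly on a seam requires declaring a side via
#' `side` (e.g. `side = c(x1 = -1)` for the left branch); both one-sided
#' derivatives of the field itself agree at the seam, but the Jacobian jumps.
#'
#' @inheritParams model_rhs
#' @param side Optional named vector with entries in `{-1, 1}` for `x1`,
#'   `x2`, `z`, selecting the branch when the state lies exactly on a seam.
#' @return A square numeric matrix with dimnames of the system variables
#'   (for `"full"`, the 5 variables `(x1, y1, z, x2, y2)`).
#' @export
model_jacobian <- function(system, state, params, frozen = NULL, side = NULL) {
  system <- check_system(system)
  zf <- frozen_z(frozen)
  side_of <- function(var) {
    s <- if (!is.null(side) && var %in% names(side)) side[[var]] else 0
    as.numeric(s)
  }
  need_side <- function(var, value, seam) {
    if (on_seam(value, seam) && side_of(var) == 0)
      stop("state lies on the ", var, " = ", seam,
           " seam; declare a side via side = c(", var, " = -1) or +1")
  }
  branch_right <- function(var, value, seam) {
    if (on_seam(value, seam)) side_of(var) > 0 else value > seam
  }

  if (system == "sub1") {
    if (is.na(zf)) stop("system 'sub1' needs frozen$z_frozen")
    state <- check_state(system, state)
    x1 <- state[1]
    need_side("x1", x1, 0)
    E <- if (branch_right("x1", x1, 0)) params$m + 0.6 * (zf - 4)^2
         else -3 * params$a * x1^2 + 2 * params$b * x1
    J <- matrix(c(E, 1, -2 * params$d * x1, -1), 2, 2, byrow = TRUE)
  } else if (system == "sub2") {
    state <- check_state(system, state)
    x2 <- state[1]
    need_side("x2", x2, -0.25)
    G2 <- if (branch_right("x2", x2, -0.25)) params$a2 / params$tau2 else 0
    J <- matrix(c(1 - 3 * x2^2, -1, G2, -1 / params$tau2), 2, 2, byrow = TRUE)
  } else if (system == "fastslow") {
    state <- check_state(system, state)
    x1 <- state[1]; z <- state[3]
    need_side("x1", x1, 0); need_side("z", z, 0)
    right1 <- branch_right("x1", x1, 0)
    E <- if (right1) params$m + 0.6 * (z - 4)^2
         else -3 * params$a * x1^2 + 2 * params$b * x1
    K <- if (right1) 1.2 * (z - 4) * x1 - 1 else -1
    L <- if (branch_right("z", z, 0)) -params$r
         else -params$r * (1 + 0.7 * z^6)
    J <- matrix(c(E, 1, K,
                  -2 * params$d * x1, -1, 0,
                  params$r * params$s, 0, L), 3, 3, byrow = TRUE)
  } else if (system == "fullfast") {
    if (is.na(zf)) stop("system 'fullfast' needs frozen$z_frozen")
    state <- check_state(system, state)
    x1 <- state[1]; x2 <- state[3]
    need_side("x1", x1, 0); need_side("x2", x2, -0.25)
    right1 <- branch_right("x1", x1, 0)
    A <- if (right1) params$m - x2 + 0.6 * (zf - 4)^2
         else -3 * params$a * x1^2 + 2 * params$b * x1
    B <- if (right1) -x1 else 0
    C2 <- if (branch_right("x2", x2, -0.25)) params$a2 / params$tau2 else 0
    J <- matrix(c(A, 1, B, 0,
                  -2 * params$d * x1, -1, 0, 0,
                  0, 0, 1 - 3 * x2^2, -1,
                  0, 0, C2, -1 / params$tau2), 4, 4, byrow = TRUE)
  } else { # full
    if (!length(state) %in% c(5L, 6L))
      stop("system 'full' expects a state of length 5 or 6")
    if (any(!is.finite(state))) stop("non-finite state")
    x1 <- state[1]; z <- state[3]; x2 <- state[4]
    need_side("x1", x1, 0); need_side("x2", x2, -0.25); need_side("z", z, 0)
    right1 <- branch_right("x1", x1, 0)
    A <- if (right1) params$m - x2 + 0.6 * (z - 4)^2
         else -3 * params$a * x1^2 + 2 * params$b * x1
    B <- if (right1) -x1 else 0
    Z1 <- if (right1) 1.2 * (z - 4) * x1 - 1 else -1
    Z2 <- if (branch_right("z", z, 0)) -params$r
          else params$r * (-1 - 0.7 * z^6)
    C2 <- if (branch_right("x2", x2, -0.25)) params$a2 / params$tau2 else 0
    Gx1 <- if (identical(params$g_convention, "stationary"))
      0.002 / params$gamma else 0
    J <- matrix(c(A, 1, Z1, B, 0,
                  -2 * params$d * x1, -1, 0, 0, 0,
                  params$r * params$s, 0, Z2, 0, 0,
                  Gx1, 0, -0.3, 1 - 3 * x2^2, -1,
                  0, 0, 0, C2, -1 / params$tau2), 5, 5, byrow = TRUE)
  }
  vars <- if (system == "full") c("x1", "y1", "z", "x2", "y2")
          else SYS_VARS[[system]]
  dimnames(J) <- list(vars, vars)
  J
}

# Reduced 5-variable vector field of the full model used for equilibrium
# algebra and as the finite-difference oracle for the 5x5 Jacobian.  The g
# forcing of the x2-equation is omitted or replaced by its stationary value
# according to params$g_convention.
rhs_full5 <- function(state, params) {
  x1 <- state[1]; y1 <- state[2]; z <- state[3]; x2 <- state[4]; y2 <- state[5]
  f1 <- if (x1 < 0) params$a * x1^3 - params$b * x1^2
        else -(params$m - x2 + 0.6 * (z - 4)^2) * x1
  f2 <- if (x2 < -0.25) 0 else params$a2 * (x2 + 0.25)
  gterm <- if (identical(params$g_convention, "stationary"))
    0.002 * x1 / params$gamma else 0
  zb <- params$s * (x1 - params$x0) - z
  if (z < 0 && !identical(params$z_law, "original")) zb <- zb - 0.1 * z^7
  c(y1 - f1 - z + params$Iext1,
    params$c - params$d * x1^2 - y1,
    params$r * zb,
    -y2 + x2 - x2^3 + params$Iext2 + gterm - 0.3 * (z - 3.5),
    (-y2 + f2) / params$tau2)
}

#' Scalar observables of a trajectory
#'
#' Returns the observable series used for time-series figures: `psi = -x1 + x2`
#' (whole-system proxy of the field potential), `psi1 = x1` (subsystem 1) and
#' `psi2 = x2` (subsystem 2).
#'
#' @param traj A trajectory from [integrate_deterministic()] or
#'   [integrate_stochastic()].
#' @param which One of `"psi"`, `"psi1"`, `"psi2"`.
#' @return A numeric vector, one value per recorded sample.
#' @export
observable <- function(traj, which = c("psi", "psi1", "psi2")) {
  which <- match.arg(which)
  st <- traj$states
  need <- switch(which, psi = c("x1", "x2"), psi1 = "x1", psi2 = "x2")
  if (!all(need %in% colnames(st)))
    stop("trajectory lacks required component(s): ",
         paste(setdiff(need, colnames(st)), collapse = ", "))
  switch(which,
         psi  = -st[, "x1"] + st[, "x2"],
         psi1 = st[, "x1"],
         psi2 = st[, "x2"])
}
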