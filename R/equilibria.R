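#' Classify stability from eigenvalues
#'
#' Node/focus is decided by imaginary parts exceeding `imag_tol`;
#' stable/unstable/saddle by the signs of the real parts with tolerance
#' `real_tol`. An eigenvalue with `|Re| < real_tol` indicates proximity to a
#' bifurcation and yields the class `"marginal"` rather than a definite label.
#' For systems of dimension > 2, equilibria with real parts of mixed sign are
#' saddles whenever a real (non-oscillatory) unstable direction exists; if the
#' unstable directions consist of complex pairs only, the class is
#' `"unstable_focus"` (the oscillatory instability the model's upper branches
#' exhibit).
#'
#' @param eigenvalues Complex (or numeric) vector of Jacobian eigenvalues.
#' @param real_tol,imag_tol Classification tolerances.
#' @return One of `"stable_node"`, `"stable_focus"`, `"saddle"`,
#'   `"unstable_node"`, `"unstable_focus"`, `"marginal"`.
#' @examples
#' classify_stability(c(-1, -2))
#' classify_stability(complex(real = 0.5, imaginary = c(2, -2)))
#' classify_stability(c(-0.1, 0.3))
#' @export
classify_stability <- function(eigenvalues, real_tol = 1e-7, imag_tol = 1e-7) {
  if (length(eigenvalues) == 0) stop("empty eigenvalue list")
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  if (any(abs(re) < real_tol)) return("marginal")
  focus_among <- function(idx) any(abs(im[idx]) > imag_tol)
  if (all(re < 0)) {
    if (focus_among(seq_along(re))) "stable_focus" else "stable_node"
  } else if (all(re > 0)) {
    if (focus_among(seq_along(re))) "unstable_focus" else "unstable_node"
  } else {
    unstable <- re > 0
    if (any(abs(im[unstable]) <= imag_tol)) "saddle"
    else "unstable_focus"
  }
}

new_equilibrium <- function(state, residual, eigenvalues, class) {
  structure(list(state = state, residual = residual,
                 eigenvalues = eigenvalues, class = class),
            class = "epidyn_equilibrium")
}

#' @export
print.epidyn_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> %s  residual=%.2e\n  state: %s\n", x$class,
              x$residual,
              paste(sprintf("%s=%.6g", names(x$state), x$state),
                    collapse = " ")))
  invisible(x)
}

eq_list <- function(eqs) structure(eqs, class = "epidyn_equilibria")

#' @export
print.epidyn_equilibria <- function(x, ...) {
  cat(sprintf("<%d equilibria>\n", length(x)))
  for (e in x) print(e)
  invisible(x)
}

#' @export
as.data.frame.epidyn_equilibria <- function(x, ...) {
  if (length(x) == 0) return(data.frame())
  st <- do.call(rbind, lapply(x, function(e) e$state))
  data.frame(st,
             residual = vapply(x, function(e) e$residual, 0),
             class = vapply(x, function(e) e$class, ""))
}

eq_classes <- function(eqs) vapply(eqs, function(e) e$class, "")

dedupe_eqs <- function(eqs, tol = 1e-8) {
  if (length(eqs) <= 1) return(eqs)
  keep <- list()
  for (e in eqs) {
    dup <- any(vapply(keep, function(k)
      max(abs(k$state - e$state)) < tol, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- e
  }
  keep
}

real_roots <- function(coefs, tol = 1e-8) {
  # coefs in increasing degree order, as polyroot()
  coefs <- coefs[seq_len(max(which(abs(coefs) > 0)))]
  if (length(coefs) < 2) return(numeric(0))
  r <- polyroot(coefs)
  scale <- max(1, abs(r))
  Re(r[abs(Im(r)) < tol * scale])
}

# Invert the slow nullcline: the z with zdot = 0 for a given x1.  Monotone in
# z (h(z) = z + 0.1 z^7 for z < 0, h(z) = z otherwise), hence unique.
zeta_slow <- function(x1, params) {
  v <- params$s * (x1 - params$x0)
  if (v >= 0 || identical(params$z_law, "original")) return(v)
  f <- function(z) z + 0.1 * z^7 - v
  lo <- -max(1, (10 * abs(v))^(1 / 7)) - 1
  stats::uniroot(f, c(lo, 0), tol = 1e-13)$root
}

classify_at <- function(system, state, params, frozen = NULL) {
  # nudge off seams for Jacobian evaluation
  side <- c(x1 = 1, x2 = 1, z = 1)
  J <- model_jacobian(system, state, params, frozen, side = side)
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev,
       class = classify_stability(ev, params$real_tol, params$imag_tol))
}

# ---- subsystem 1 ------------------------------------------------------------

#' Closed-form equilibria of subsystem 1 at frozen z
#'
#' Solves the per-branch polynomial equilibrium conditions exactly: the cubic
#' `c + (b - d) x1^2 - a x1^3 - z + Iext1 = 0` on `x1 < 0`, and the quadratic
#' `c - d x1^2 + (m + 0.6 (z - 4)^2) x1 - z + Iext1 = 0` on `x1 >= 0`
#' (roots `(R +- sqrt(delta+)) / (2 d)` with `R = m + 0.6 (z - 4)^2` and
#' `delta+ = R^2 + 4 d (c - z + Iext1)`). Roots failing their branch's sign
#' condition are discarded.
#'
#' @param z Frozen value of the slow variable.
#' @param params An [epidyn_params()] object.
#' @return An `epidyn_equilibria` list, each with state `(x1, y1)`,
#'   eigenvalues of the 2x2 Jacobian, and stability class.
#' @export
sub1_equilibria_analytic <- function(z, params = epidyn_params()) {
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  k <- cc - z + params$Iext1
  x1s <- numeric(0)
  # cubic branch: -a x^3 + (b - d) x^2 + 0 x + k = 0
  r <- real_roots(c(k, 0, b - d, -a))
  x1s <- c(x1s, r[r < 0])
  # quadratic branch: -d x^2 + R x + k = 0
  R <- params$m + 0.6 * (z - 4)^2
  dp <- R^2 + 4 * d * k
  if (dp >= 0) {
    q <- (R + c(-1, 1) * sqrt(dp)) / (2 * d)
    x1s <- c(x1s, q[q >= 0])
  }
  eqs <- lapply(x1s, function(x1) {
    st <- c(x1 = x1, y1 = cc - d * x1^2)
    res <- max(abs(model_rhs("sub1", st, params, list(z_frozen = z))))
    cl <- classify_at("sub1", st, params, list(z_frozen = z))
    new_equilibrium(st, res, cl$eigenvalues, cl$class)
  })
  eq_list(dedupe_eqs(eqs))
}

#' Closed-form bifurcation points of subsystem 1
#'
#' Evaluates the analytic fold and Hopf locations of subsystem 1 as functions
#' of the parameters:
#' \itemize{
#'   \item `z_SN1`: the fold of the `x1 < 0` branch, at
#'     `x1 = 2 (b - d) / (3 a)`; equals `Iext1 - 5/27` at default coefficients.
#'   \item `z_SN2`: the upper end of the lower existence window of the
#'     `x1 >= 0` branch: `c + Iext1` for `m <= 0`, else `min(X) + 4` with `X`
#'     a real root of the quartic `X^4 + p X^2 + q X + w = 0`
#'     (`X = z - 4`; the quartic is the discriminant condition `delta+ = 0`).
#'   \item `z_H`: the Hopf point of the `x1 >= 0` focus,
#'     `4 - sqrt((1 - m) / 0.6)`, real only for `m <= 1`.
#'   \item `z_SN_outer`: `max(X) + 4`, the fold beyond which the outer
#'     `x1 >= 0` branch pair reappears.
#'   \item `alpha`, `beta`, `gamma_table`: x1-breakpoints of the stability
#'     tables -- the upper quadratic root `(R + sqrt(delta+)) / (2 d)`
#'     evaluated at `z_H`, `z_SN2` and `z_SN_outer` respectively.
#' }
#'
#' @param params An [epidyn_params()] object.
#' @return A list with the fields above plus the quartic coefficients
#'   `p`, `q`, `w`, the fold abscissa `x1_fold = 2 (b - d) / (3 a)`, and
#'   helper functions `R_of_z`, `delta_plus` (discriminant of the `x1 >= 0`
#'   quadratic) and `delta_minus` (discriminant of the `x1 < 0` cubic).
#' @export
sub1_closed_form_points <- function(params = epidyn_params()) {
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  m <- params$m; I1 <- params$Iext1
  x1f <- 2 * (b - d) / (3 * a)
  z_SN1 <- cc + (b - d) * x1f^2 - a * x1f^3 + I1
  # quartic in X = z - 4 from delta+ = 0, scaled by 1/0.36
  p <- (1.2 * m) / 0.36
  q <- -(4 * d) / 0.36
  w <- (m^2 + 4 * d * (cc + I1 - 4)) / 0.36
  X <- real_roots(c(w, q, p, 0, 1), tol = 1e-7)
  z_SN2 <- if (m <= 0) cc + I1
           else if (length(X)) min(X) + 4 else NA_real_
  z_SN_outer <- if (length(X)) max(X) + 4 else NA_real_
  z_H <- if (m <= 1) 4 - sqrt((1 - m) / 0.6) else NA_real_
  R_of_z <- function(z) m + 0.6 * (z - 4)^2
  delta_plus <- function(z) R_of_z(z)^2 + 4 * d * (cc - z + I1)
  delta_minus <- function(z) {
    # discriminant of -a x^3 + (b-d) x^2 + (cc - z + I1)
    k <- cc - z + I1
    -4 * (b - d)^3 * k / a^3 - 27 * k^2 / a^2 # scaled cubic discriminant
  }
  xup <- function(z) {
    dp <- delta_plus(z)
    if (is.na(z) || dp < 0) return(NA_real_)
    (R_of_z(z) + sqrt(dp)) / (2 * d)
  }
  list(z_SN1 = z_SN1, z_SN2 = z_SN2, z_H = z_H, z_SN_outer = z_SN_outer,
       p = p, q = q, w = w, x1_fold = x1f,
       alpha = xup(z_H), beta = xup(z_SN2), gamma_table = xup(z_SN_outer),
       R_of_z = R_of_z, delta_plus = delta_plus, delta_minus = delta_minus)
}

#' Hopf threshold of subsystem 1 in m at fixed z
#'
#' The `x1 >= 0` focus of subsystem 1 changes stability where the trace of its
#' Jacobian vanishes: `Tr(J) = m + 0.6 (z - 4)^2 - 1 = 0`, i.e.
#' `m(H) = 1 - 0.6 (z - 4)^2`.
#'
#' @param z Frozen slow-variable value.
#' @param params An [epidyn_params()] object (only used for consistency of
#'   interface; the threshold depends on z alone).
#' @return The Hopf value of m.
#' @examples
#' hopf_m_at_z(3.1) # 0.514
#' hopf_m_at_z(0)   # -8.6
#' @export
hopf_m_at_z <- function(z, params = epidyn_params()) {
  1 - 0.6 * (z - 4)^2
}

# ---- subsystem 2 ------------------------------------------------------------

sub2_equilibria_at <- function(drive, params) {
  a2 <- params$a2
  x2s <- numeric(0)
  # x2 < -0.25 branch: -x^3 + x + drive = 0
  r <- real_roots(c(drive, 1, 0, -1))
  x2s <- c(x2s, r[r < -0.25])
  # x2 >= -0.25 branch: -x^3 + (1 - a2) x + (drive - 0.25 a2) = 0
  r <- real_roots(c(drive - 0.25 * a2, 1 - a2, 0, -1))
  x2s <- c(x2s, r[r >= -0.25])
  frozen <- list(external_input = drive)
  eqs <- lapply(x2s, function(x2) {
    f2 <- if (x2 < -0.25) 0 else a2 * (x2 + 0.25)
    st <- c(x2 = x2, y2 = f2)
    res <- max(abs(model_rhs("sub2", st, params, frozen)))
    cl <- classify_at("sub2", st, params)
    new_equilibrium(st, res, cl$eigenvalues, cl$class)
  })
  eq_list(dedupe_eqs(eqs))
}

#' SNIC point of subsystem 2
#'
#' The drive at which the stable node and saddle of subsystem 2 coalesce on an
#' invariant circle. On the `x2 < -0.25` branch `Det(J2) = -(1 - 3 x2^2)/tau2`
#' vanishes at `x2* = -1/sqrt(3)`; substituting into the equilibrium condition
#' `x2 - x2^3 + Iext2 = 0` gives `Iext2* = x2*^3 - x2* = 2 / (3 sqrt(3))
#' \eqn{\approx} 0.385`.
#'
#' @param params An [epidyn_params()] object (requires `a2 > 1`).
#' @return A list with `Iext2` (the SNIC drive) and `x2` (the coalescence
#'   point).
#' @examples
#' sub2_snic_point()$Iext2 # 0.3849
#' @export
sub2_snic_point <- function(params = epidyn_params()) {
  if (params$a2 <= 1) stop("SNIC condition requires a2 > 1")
  x2 <- -1 / sqrt(3)
  list(Iext2 = x2^3 - x2, x2 = x2)
}

# ---- frozen-z fast equations of the full model ------------------------------

# Real x2 roots of the subsystem-2 equilibrium condition at effective drive D.
sub2_roots_at <- function(D, params) {
  a2 <- params$a2
  r1 <- real_roots(c(D, 1, 0, -1))
  r2 <- real_roots(c(D - 0.25 * a2, 1 - a2, 0, -1))
  sort(c(r1[r1 < -0.25], r2[r2 >= -0.25]))
}

# x1 roots of the full-model x1-equation at frozen z and given x2.
full_x1_roots_at <- function(z, x2, params) {
  a <- params$a; b <- params$b; cc <- params$c; d <- params$d
  k <- cc - z + params$Iext1
  out <- numeric(0)
  r <- real_roots(c(k, 0, b - d, -a))
  out <- c(out, r[r < 0])
  R <- params$m - x2 + 0.6 * (z - 4)^2
  dp <- R^2 + 4 * d * k
  if (dp >= 0) {
    q <- (R + c(-1, 1) * sqrt(dp)) / (2 * d)
    out <- c(out, q[q >= 0])
  }
  out
}

fullfast_equilibria_at <- function(z, params) {
  D <- params$Iext2 - 0.3 * (z - 3.5)
  x2s <- sub2_roots_at(D, params)
  eqs <- list()
  for (x2 in x2s) {
    f2 <- if (x2 < -0.25) 0 else params$a2 * (x2 + 0.25)
    for (x1 in full_x1_roots_at(z, x2, params)) {
      st <- c(x1 = x1, y1 = params$c - params$d * x1^2, x2 = x2, y2 = f2)
      res <- max(abs(model_rhs("fullfast", st, params, list(z_frozen = z))))
      cl <- classify_at("fullfast", st, params, list(z_frozen = z))
      eqs[[length(eqs) + 1L]] <-
        new_equilibrium(st, res, cl$eigenvalues, cl$class)
    }
  }
  eq_list(dedupe_eqs(eqs))
}

# z beyond which the outer x1 >= 0 branch pair exists (upper root of the
# delta+ = 0 quartic), for effective slope parameter mp (m for subsystem 1,
# m - x2 for the full model).  +Inf when the quartic has no real roots.
z_outer_fold <- function(mp, params) {
  p <- (1.2 * mp) / 0.36
  q <- -(4 * params$d) / 0.36
  w <- (mp^2 + 4 * params$d * (params$c + params$Iext1 - 4)) / 0.36
  X <- real_roots(c(w, q, p, 0, 1), tol = 1e-7)
  if (length(X)) max(X) + 4 else Inf
}

# ---- fast-slow subsystem ----------------------------------------------------

fastslow_equilibria <- function(params, include_outer = FALSE) {
  # x1 < 0: cubic equilibrium condition with z on the slow nullcline
  res_neg <- function(x1) {
    z <- zeta_slow(x1, params)
    params$c - params$d * x1^2 -
      (params$a * x1^3 - params$b * x1^2) - z + params$Iext1
  }
  res_pos <- function(x1) {
    z <- zeta_slow(x1, params)
    params$c - params$d * x1^2 +
      (params$m + 0.6 * (z - 4)^2) * x1 - z + params$Iext1
  }
  x1s <- c(scan_roots(res_neg, seq(-4, -1e-6, length.out = 1200)),
           scan_roots(res_pos, seq(0, 3, length.out = 900)))
  if (!include_outer) {
    zo <- z_outer_fold(params$m, params)
    x1s <- x1s[!(x1s >= 0 & vapply(x1s, zeta_slow, 0, params = params) >=
                   zo - 1e-8)]
  }
  eqs <- lapply(x1s, function(x1) {
    z <- zeta_slow(x1, params)
    st <- c(x1 = x1, y1 = params$c - params$d * x1^2, z = z)
    res <- max(abs(model_rhs("fastslow", st, params)))
    cl <- classify_at("fastslow", st, params)
    new_equilibrium(st, res, cl$eigenvalues, cl$class)
  })
  eq_list(dedupe_eqs(eqs))
}

# Bracketed sign-change scan + uniroot refinement of a scalar function.
scan_roots <- function(f, grid, tol = 1e-12) {
  vals <- vapply(grid, f, 0)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    v1 <- vals[i]; v2 <- vals[i + 1]
    if (!is.finite(v1) || !is.finite(v2)) next
    if (v1 == 0) roots <- c(roots, grid[i])
    else if (v1 * v2 < 0)
      roots <- c(roots, stats::uniroot(f, grid[i + 0:1], tol = tol)$root)
  }
  if (length(vals) && vals[length(vals)] == 0)
    roots <- c(roots, grid[length(grid)])
  unique(roots)
}

# ---- full model -------------------------------------------------------------

full_equilibria <- function(params, include_outer = FALSE) {
  stationary <- identical(params$g_convention, "stationary")
  gterm <- function(x1) if (stationary) 0.002 * x1 / params$gamma else 0
  drive_at <- function(x1, z) params$Iext2 + gterm(x1) - 0.3 * (z - 3.5)

  pairs <- list()
  add_pair <- function(x1, x2) pairs[[length(pairs) + 1L]] <<- c(x1, x2)

  # x1 < 0: the x1-equation does not involve x2; solve 1-D, then attach every
  # x2 root of the subsystem-2 condition.
  res_neg <- function(x1) {
    z <- zeta_slow(x1, params)
    params$c - params$d * x1^2 -
      (params$a * x1^3 - params$b * x1^2) - z + params$Iext1
  }
  for (x1 in scan_roots(res_neg, seq(-4, -1e-6, length.out = 1600))) {
    z <- zeta_slow(x1, params)
    for (x2 in sub2_roots_at(drive_at(x1, z), params)) add_pair(x1, x2)
  }

  # x1 >= 0: the x1-equation couples to x2 through the f1 slope; track each
  # x2-root branch along an x1 grid and bisect its residual sign changes.
  grid <- seq(0, 3, length.out = 1200)
  prev <- NULL
  resid <- function(x1, x2) {
    z <- zeta_slow(x1, params)
    params$c - params$d * x1^2 +
      (params$m - x2 + 0.6 * (z - 4)^2) * x1 - z + params$Iext1
  }
  branch_info <- function(x1) {
    z <- zeta_slow(x1, params)
    x2s <- sub2_roots_at(drive_at(x1, z), params)
    list(x2 = x2s, res = vapply(x2s, function(x2) resid(x1, x2), 0))
  }
  refine_pos <- function(lo, hi, x2_guess) {
    f <- function(x1) {
      info <- branch_info(x1)
      if (!length(info$x2)) return(NA_real_)
      k <- which.min(abs(info$x2 - x2_guess))
      x2_guess <<- info$x2[k]
      info$res[k]
    }
    r <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root,
                  error = function(e) NA_real_)
    if (!is.na(r)) {
      info <- branch_info(r)
      k <- which.min(abs(info$x2 - x2_guess))
      add_pair(r, info$x2[k])
    }
  }
  for (i in seq_along(grid)) {
    cur <- branch_info(grid[i])
    if (!is.null(prev)) {
      if (length(cur$x2) == length(prev$x2) && length(cur$x2) > 0) {
        for (k in seq_along(cur$x2)) {
          if (is.finite(prev$res[k]) && is.finite(cur$res[k]) &&
              prev$res[k] * cur$res[k] < 0)
            refine_pos(grid[i - 1], grid[i], prev$x2[k])
        }
      } else if (length(cur$x2) != length(prev$x2)) {
        # root count changed inside the cell: refine on a local subgrid
        sub <- seq(grid[i - 1], grid[i], length.out = 24)
        sprev <- NULL
        for (x1 in sub) {
          scur <- branch_info(x1)
          if (!is.null(sprev) && length(scur$x2) == length(sprev$x2) &&
              length(scur$x2) > 0) {
            for (k in seq_along(scur$x2)) {
              if (sprev$res[k] * scur$res[k] < 0)
                refine_pos(x1 - diff(sub[1:2]), x1, sprev$x2[k])
            }
          }
          sprev <- scur
        }
      }
    }
    prev <- cur
  }

  # assemble, polish with damped Newton on the reduced 5-variable system
  eqs <- list()
  for (pr in pairs) {
    x1 <- pr[1]; x2 <- pr[2]
    z <- zeta_slow(x1, params)
    if (!include_outer && x1 >= 0 &&
        z >= z_outer_fold(params$m - x2, params) - 1e-8) next
    f2 <- if (x2 < -0.25) 0 else params$a2 * (x2 + 0.25)
    st <- c(x1 = x1, y1 = params$c - params$d * x1^2, z = z,
            x2 = x2, y2 = f2)
    st <- newton_polish_full(st, params)
    if (is.null(st)) next
    res <- max(abs(rhs_full5(st, params)))
    if (res > 1e-8) next
    cl <- classify_at("full", st, params)
    eqs[[length(eqs) + 1L]] <- new_equilibrium(st, res, cl$eigenvalues,
                                               cl$class)
  }
  eq_list(dedupe_eqs(eqs, tol = 1e-7))
}

newton_polish_full <- function(state, params, maxit = 25) {
  f <- rhs_full5(state, params)
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < 1e-12) break
    J <- tryCatch(
      model_jacobian("full", state, params, side = c(x1 = 1, x2 = 1, z = 1)),
      error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      cand <- state - lam * step
      fc <- rhs_full5(cand, params)
      if (max(abs(fc)) < max(abs(f)) || lam < 1e-4) break
      lam <- lam / 2
    }
    state <- cand; f <- fc
  }
  if (max(abs(f)) > 1e-8) return(NULL)
  names(state) <- c("x1", "y1", "z", "x2", "y2")
  state
}

#' Find equilibria of a model system
#'
#' Locates all real equilibria of the chosen system, classifies their
#' stability from the analytic Jacobian, and reports residuals. Subsystems 1
#' and 2 and the frozen-z fast equations are solved exactly per piecewise
#' branch (polynomial root extraction); the full model and the fast-slow
#' subsystem eliminate z through the slow nullcline and locate the remaining
#' roots by a bracketed scan with Newton polishing.
#'
#' For `system = "full"` with `frozen$z_frozen` set, only the fast
#' `(x1, y1, x2, y2)` equations are solved at that z (the procedure behind
#' the bifurcation diagrams); the `0.002 g` forcing is handled per
#' `params$g_convention`.
#'
#' For the full model and the fast-slow subsystem, equilibria on the outer
#' `x1 >= 0` branch (beyond the fold at `z = max(X) + 4`, which the Z-curve
#' analysis excludes) are dropped unless `include_outer = TRUE`.
#'
#' @inheritParams model_rhs
#' @param include_outer Keep outer-branch equilibria of the full model /
#'   fast-slow subsystem (default `FALSE`).
#' @return An `epidyn_equilibria` list (possibly empty), deduplicated within
#'   1e-8.
#' @examples
#' find_equilibria("sub1", epidyn_params(), frozen = list(z_frozen = 3.1))
#' @export
find_equilibria <- function(system, params = epidyn_params(), frozen = NULL,
                            include_outer = FALSE) {
  system <- check_system(system)
  zf <- frozen_z(frozen)
  switch(system,
    sub1 = {
      if (is.na(zf)) stop("sub1 equilibria need frozen$z_frozen")
      sub1_equilibria_analytic(zf, params)
    },
    sub2 = {
      drive <- if (!is.null(frozen$external_input))
        frozen$external_input else params$Iext2
      sub2_equilibria_at(drive, params)
    },
    fastslow = fastslow_equilibria(params, include_outer),
    fullfast = {
      if (is.na(zf)) stop("fullfast equilibria need frozen$z_frozen")
      fullfast_equilibria_at(zf, params)
    },
    full = {
      if (!is.na(zf)) fullfast_equilibria_at(zf, params)
      else full_equilibria(params, include_outer)
    })
}

#' Export equilibria as CSV
#'
#' @param eqs An `epidyn_equilibria` list.
#' @param path Output path.
#' @export
write_equilibria_csv <- function(eqs, path) {
  df <- as.data.frame(eqs)
  if (nrow(df)) {
    ev <- vapply(eqs, function(e)
      paste(format(e$eigenvalues, digits = 8), collapse = ";"), "")
    df$eigenvalues <- ev
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- stability tables -------------------------------------------------------

#' Verify the trace/determinant stability tables by sampling
#'
#' Samples the equilibrium branches of subsystem 1 (tables `"T2"`--`"T5"`) or
#' subsystem 2 (`"T6"`) inside each column interval of the corresponding
#' stability table and checks that the signs of the Jacobian trace and
#' determinant, and the implied class, match the table row. For `x1 >= 0`
#' samples, the branch value of z is recovered by inverting the equilibrium
#' condition (a quadratic in z) on the regime the table covers
#' (`z <= z(Det1)` for T2--T4, `z >= z(Det2)` for T5).
#'
#' @param regime One of `"T2"` (m <= 0), `"T3"` (0 < m <= 1), `"T4"` (m > 1),
#'   `"T5"` (outer branch, any m), `"T6"` (subsystem 2).
#' @param params An [epidyn_params()] object with `m` in the table's range.
#' @param n_per_interval Samples per column.
#' @return A data.frame with one row per sample: location, observed signs of
#'   `Det` and `Tr`, observed and expected class, and `ok`.
#' @export
stability_table_check <- function(regime, params = epidyn_params(),
                                  n_per_interval = 3) {
  regime <- match.arg(regime, c("T2", "T3", "T4", "T5", "T6"))
  cf <- sub1_closed_form_points(params)
  m <- params$m
  samp <- function(lo, hi) {
    if (!is.finite(lo)) lo <- hi - 1.5
    if (!is.finite(hi)) hi <- lo + 1.5
    seq(lo, hi, length.out = n_per_interval + 2)[-c(1, n_per_interval + 2)]
  }

  if (regime == "T6") {
    t2 <- params$tau2; a2 <- params$a2
    if (a2 <= 1) stop("table T6 requires a2 > 1")
    xD <- -1 / sqrt(3)
    xT1 <- -sqrt((1 - 1 / t2) / 3)
    xT2 <- sqrt((1 - 1 / t2) / 3)
    cols <- list(
      list(int = c(-Inf, xD),   det = 1,  tr = -1, cl = "stable"),
      list(int = c(xD, xT1),    det = -1, tr = -1, cl = "saddle"),
      list(int = c(xT1, -0.25), det = -1, tr = 1,  cl = "saddle"),
      list(int = c(-0.25, xT2), det = 1,  tr = 1,  cl = "unstable"),
      list(int = c(xT2, Inf),   det = 1,  tr = -1, cl = "stable"))
    rows <- lapply(cols, function(cl) {
      xs <- samp(cl$int[1], cl$int[2])
      do.call(rbind, lapply(xs, function(x2) {
        G2 <- if (x2 < -0.25) 0 else a2 / t2
        Tr <- 1 - 3 * x2^2 - 1 / t2
        Det <- G2 - (1 - 3 * x2^2) / t2
        obs <- if (Det < 0) "saddle" else if (Tr < 0) "stable" else "unstable"
        data.frame(location = x2, det_sign = sign(Det), tr_sign = sign(Tr),
                   class = obs, expected = cl$cl,
                   ok = sign(Det) == cl$det && sign(Tr) == cl$tr &&
                        obs == cl$cl)
      }))
    })
    out <- do.call(rbind, rows)
    attr(out, "table") <- regime
    return(out)
  }

  ok_m <- switch(regime,
                 T2 = m <= 0, T3 = m > 0 && m <= 1, T4 = m > 1, T5 = TRUE)
  if (!ok_m) stop("params$m = ", m, " outside the range of table ", regime)

  # z on the equilibrium branch for a given x1 >= 0, restricted to a regime.
  z_on_branch <- function(x1, outer) {
    A <- 0.6 * x1
    B <- -4.8 * x1 - 1
    C <- (9.6 + m) * x1 + params$c - params$d * x1^2 + params$Iext1
    disc <- B^2 - 4 * A * C
    if (x1 == 0 || disc < 0) return(NA_real_)
    zz <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    if (outer) {
      zz <- zz[zz >= cf$z_SN_outer - 1e-9]
      if (length(zz)) max(zz) else NA_real_
    } else {
      zz <- zz[zz <= cf$z_SN2 + 1e-9]
      if (length(zz)) min(zz) else NA_real_
    }
  }
  trdet <- function(x1, outer = FALSE) {
    if (x1 < 0) {
      E <- -3 * params$a * x1^2 + 2 * params$b * x1
    } else {
      z <- z_on_branch(x1, outer)
      if (is.na(z)) return(c(NA, NA))
      E <- m + 0.6 * (z - 4)^2
    }
    c(tr = E - 1, det = 2 * params$d * x1 - E)
  }

  x1f <- cf$x1_fold
  cols <- switch(regime,
    T2 = list(
      list(int = c(-Inf, x1f),    det = 1,  tr = -1, cl = "stable"),
      list(int = c(x1f, 0),       det = -1, tr = -1, cl = "saddle"),
      list(int = c(0, cf$alpha),  det = 1,  tr = -1, cl = "stable"),
      list(int = c(cf$alpha, Inf), det = 1, tr = 1, cl = "unstable")),
    T3 = list(
      list(int = c(-Inf, x1f),    det = 1,  tr = -1, cl = "stable"),
      list(int = c(x1f, 0),       det = -1, tr = -1, cl = "saddle"),
      list(int = c(0, cf$beta),   det = -1, tr = -1, cl = "saddle"),
      list(int = c(cf$beta, cf$alpha), det = 1, tr = -1, cl = "stable"),
      list(int = c(cf$alpha, cf$alpha + 0.3), det = 1, tr = 1,
           cl = "unstable")),
    T4 = list(
      list(int = c(-Inf, x1f),    det = 1,  tr = -1, cl = "stable"),
      list(int = c(x1f, 0),       det = -1, tr = -1, cl = "saddle"),
      list(int = c(0, cf$beta),   det = -1, tr = 1,  cl = "saddle"),
      list(int = c(cf$beta, cf$beta + 0.3), det = 1, tr = 1,
           cl = "unstable")),
    T5 = list(
      list(int = c(0, cf$gamma_table), det = -1, tr = 1, cl = "saddle"),
      list(int = c(cf$gamma_table, cf$gamma_table + 1), det = 1, tr = 1,
           cl = "unstable")))

  outer <- regime == "T5"
  rows <- lapply(cols, function(cl) {
    xs <- samp(cl$int[1], cl$int[2])
    do.call(rbind, lapply(xs, function(x1) {
      td <- trdet(x1, outer)
      if (any(is.na(td)))
        return(data.frame(location = x1, det_sign = NA, tr_sign = NA,
                          class = NA, expected = cl$cl, ok = NA))
      obs <- if (td["det"] < 0) "saddle"
             else if (td["tr"] < 0) "stable" else "unstable"
      data.frame(location = x1, det_sign = sign(td[["det"]]),
                 tr_sign = sign(td[["tr"]]), class = obs, expected = cl$cl,
                 ok = sign(td[["det"]]) == cl$det &&
                      sign(td[["tr"]]) == cl$tr && obs == cl$cl)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "table") <- regime
  out
}
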