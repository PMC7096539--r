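# ---- frozen-parameter attractor statistics ----------------------------------

# Integrate the frozen-z fast system ("sub1" or "fullfast") to its attractor
# and summarise it.  Returns type "cycle" (with max/min/mean x1, period) or
# "point" (with the settled state).  `init` continues from a previous
# attractor; otherwise integration starts near an unstable focus of the
# frozen-z equations (offset +0.1 in x1).
cycle_stats <- function(system, z, params, init = NULL,
                        t_transient = 150, t_window = 200, dt = 0.01,
                        amp_tol = 1e-2, max_total = 4000) {
  frozen <- list(z_frozen = z)
  if (is.null(init)) {
    eqs <- find_equilibria(system, params, frozen)
    cls <- eq_classes(eqs)
    pick <- which(cls == "unstable_focus")
    if (!length(pick)) pick <- which(cls %in% c("unstable_node", "marginal"))
    if (!length(pick)) return(list(type = "none", z = z))
    # prefer the focus with largest x1 (the Z-upper branch); the small
    # offset keeps near-Hopf cycle averages close to the focus value
    x1s <- vapply(eqs[pick], function(e) e$state[["x1"]], 0)
    st <- eqs[[pick[which.max(x1s)]]]$state
    init <- st
    init[["x1"]] <- init[["x1"]] + 0.01
    init <- as.numeric(init)
  }
  tr <- integrate_deterministic(system, init, t_transient, dt, params, frozen,
                                record_every = 10L)
  if (tr$diverged) return(list(type = "divergent", z = z))
  state <- tr$states[nrow(tr$states), ]
  window <- t_window
  repeat {
    tr <- integrate_deterministic(system, state, window, dt, params, frozen)
    if (tr$diverged) return(list(type = "divergent", z = z))
    x1 <- tr$states[, "x1"]
    state <- tr$states[nrow(tr$states), ]
    amp <- diff(range(x1))
    if (amp < amp_tol)
      return(list(type = "point", z = z, x1 = state[["x1"]],
                  state = state, amplitude = amp))
    mid <- (max(x1) + min(x1)) / 2
    up <- which(x1[-length(x1)] < mid & x1[-1] >= mid)
    if (length(up) >= 4) {
      tcross <- tr$times[up] +
        (mid - x1[up]) / (x1[up + 1] - x1[up]) * diff(tr$times[1:2])
      period <- mean(diff(tcross))
      i1 <- up[1]; i2 <- up[length(up)]
      x2rng <- if ("x2" %in% colnames(tr$states))
        range(tr$states[i1:i2, "x2"]) else c(NA_real_, NA_real_)
      return(list(type = "cycle", z = z,
                  max_x1 = max(x1[i1:i2]), min_x1 = min(x1[i1:i2]),
                  mean_x1 = mean(x1[i1:i2]), period = period,
                  min_x2 = x2rng[1], max_x2 = x2rng[2],
                  amplitude = diff(range(x1[i1:i2])), state = state))
    }
    if (window >= max_total)
      return(list(type = "slow", z = z, state = state,
                  amplitude = amp))
    window <- window * 2
  }
}

# ---- branch sweeps ----------------------------------------------------------

frozen_for <- function(system, v) {
  if (identical(system, "sub2")) list(external_input = v)
  else list(z_frozen = v)
}

count_equilibria_at <- function(system, v, params) {
  length(find_equilibria(system, params, frozen_for(system, v)))
}

# Leading real part among focus-type equilibria (restricted to the x1 >= 0
# upper branch where the system has an x1 coordinate).
lead_focus_re <- function(system, v, params) {
  eqs <- find_equilibria(system, params, frozen_for(system, v))
  foci <- Filter(function(e) {
    pos <- !("x1" %in% names(e$state)) || e$state[["x1"]] >= 0
    pos && any(abs(Im(e$eigenvalues)) > 1e-7)
  }, eqs)
  if (!length(foci)) return(NA_real_)
  max(vapply(foci, function(e) max(Re(e$eigenvalues)), 0))
}

#' Sweep equilibrium branches over a control-parameter grid
#'
#' Builds a bifurcation diagram by solving the frozen equilibrium equations
#' at every grid point and linking equilibria into branches of constant
#' stability class. The control parameter is z for `"sub1"`, `"fastslow"`'s
#' fast part and the frozen-z fast equations of the full model
#' (`system = "full"` or `"fullfast"`), and the drive `Iext2` for `"sub2"`.
#'
#' @param system `"sub1"`, `"full"`/`"fullfast"` or `"sub2"`.
#' @param range Control-parameter range, default `c(-2, 6)` for z sweeps and
#'   `c(-0.5, 1.5)` for `"sub2"`.
#' @param n_grid Number of grid points (default 801).
#' @param params An [epidyn_params()] object.
#' @return An object of class `epidyn_diagram`: a data.frame with columns
#'   `par` (control value), `value` (x1, or x2 for `"sub2"`), `class`,
#'   `branch`, plus the full state columns; attributes `system`, `control`,
#'   `params`.
#' @export
sweep_branches <- function(system, range = NULL, n_grid = 801,
                           params = epidyn_params()) {
  system <- check_system(if (identical(system, "full")) "fullfast" else system)
  if (!system %in% c("sub1", "fullfast", "sub2"))
    stop("sweep_branches supports sub1, full/fullfast and sub2")
  if (n_grid < 3) stop("n_grid must be >= 3")
  control <- if (system == "sub2") "Iext2" else "z"
  if (is.null(range)) range <- if (system == "sub2") c(-0.5, 1.5) else c(-2, 6)
  grid <- seq(range[1], range[2], length.out = n_grid)
  vcol <- if (system == "sub2") "x2" else "x1"

  rows <- vector("list", n_grid)
  for (i in seq_along(grid)) {
    frozen <- if (system == "sub2") list(external_input = grid[i])
              else list(z_frozen = grid[i])
    eqs <- find_equilibria(system, params, frozen)
    if (!length(eqs)) next
    st <- do.call(rbind, lapply(eqs, function(e) e$state))
    rows[[i]] <- data.frame(par = grid[i], value = st[, vcol], st,
                            class = eq_classes(eqs), row.names = NULL)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(par = numeric(0), value = numeric(0),
                                    class = character(0))

  # link equilibria across neighbouring grid points into branches
  df$branch <- NA_integer_
  nb <- 0L
  prev_idx <- integer(0); prev_val <- numeric(0); prev_cls <- character(0)
  match_tol <- 0.3
  for (g in unique(df$par)) {
    idx <- which(df$par == g)
    used_prev <- logical(length(prev_idx))
    for (j in idx) {
      cand <- which(!used_prev & prev_cls == df$class[j] &
                    abs(prev_val - df$value[j]) < match_tol)
      if (length(cand)) {
        k <- cand[which.min(abs(prev_val[cand] - df$value[j]))]
        df$branch[j] <- df$branch[prev_idx[k]]
        used_prev[k] <- TRUE
      } else {
        nb <- nb + 1L
        df$branch[j] <- nb
      }
    }
    prev_idx <- idx; prev_val <- df$value[idx]; prev_cls <- df$class[idx]
  }
  structure(df, system = system, control = control, params = params,
            n_grid = n_grid, range = range, class = c("epidyn_diagram",
                                                      "data.frame"))
}

#' Limit-cycle envelope of the frozen-z fast equations
#'
#' At each z of the grid, integrates the fast system from near its unstable
#' focus (continuing from the previous attractor where possible), drops the
#' transient, and records the cycle's extrema, mean and period. Ends of the
#' cycle branch are tagged `HOPF` (amplitude below `amp_tol`), `SNIC` or
#' `HOMOCLINIC` (finite amplitude; distinguished by whether a node-saddle
#' pair is born on the cycle at the termination), or `GRID_EDGE`.
#'
#' @param system `"sub1"` or `"full"`/`"fullfast"`.
#' @param z_grid Numeric grid of z values (ascending).
#' @param params An [epidyn_params()] object.
#' @param amp_tol Amplitude below which the attractor counts as a point.
#' @param period_cap Periods beyond this are treated as diverging
#'   (homoclinic/SNIC proximity).
#' @return A data.frame `z, max_x1, min_x1, mean_x1, period, has_cycle`, with
#'   attributes `termination` (tags at the lower/upper ends of the cycle
#'   range) and, when resolvable, `z_end` refinements.
#' @export
cycle_envelope <- function(system, z_grid, params = epidyn_params(),
                           amp_tol = 1e-2, period_cap = 2000) {
  system <- if (identical(system, "full")) "fullfast" else system
  z_grid <- sort(z_grid)
  out <- data.frame(z = z_grid, max_x1 = NA_real_, min_x1 = NA_real_,
                    mean_x1 = NA_real_, period = NA_real_,
                    min_x2 = NA_real_, max_x2 = NA_real_, has_cycle = FALSE)
  stats_at <- vector("list", length(z_grid))
  init <- NULL
  for (i in seq_along(z_grid)) {
    cs <- cycle_stats(system, z_grid[i], params, init = init,
                      amp_tol = amp_tol)
    stats_at[[i]] <- cs
    if (identical(cs$type, "cycle")) {
      out$max_x1[i] <- cs$max_x1; out$min_x1[i] <- cs$min_x1
      out$mean_x1[i] <- cs$mean_x1; out$period[i] <- cs$period
      out$min_x2[i] <- cs$min_x2 %||% NA_real_
      out$max_x2[i] <- cs$max_x2 %||% NA_real_
      out$has_cycle[i] <- TRUE
      init <- cs$state
    } else {
      init <- NULL
    }
  }
  idx <- which(out$has_cycle)
  term <- c(lower = "GRID_EDGE", upper = "GRID_EDGE")
  if (length(idx)) {
    lo <- min(idx); hi <- max(idx)
    if (lo > 1) term["lower"] <- termination_tag(system, stats_at[[lo]],
                                                 out$z[lo - 1], params,
                                                 amp_tol)
    if (hi < nrow(out)) term["upper"] <- termination_tag(system,
                                                         stats_at[[hi]],
                                                         out$z[hi + 1],
                                                         params, amp_tol)
  }
  attr(out, "termination") <- term
  attr(out, "system") <- system
  out
}

# Classify how a cycle ends between z_in (where `cyc` describes the cycle)
# and z_out (no cycle): amplitude collapse -> HOPF; otherwise SNIC if an
# equilibrium pair is born inside the cycle's band across the boundary
# (compared in the (x1, x2) plane -- for the full fast equations the
# coalescence happens along x2), else HOMOCLINIC.
termination_tag <- function(system, cyc, z_out, params, amp_tol) {
  amp <- cyc$max_x1 - cyc$min_x1
  z_in <- cyc$z
  eq_in <- find_equilibria(system, params, list(z_frozen = z_in))
  eq_out <- find_equilibria(system, params, list(z_frozen = z_out))
  loc <- function(e) {
    st <- e$state
    c(st[["x1"]], if ("x2" %in% names(st)) st[["x2"]] else 0)
  }
  if (length(eq_out) >= length(eq_in) + 2) {
    old <- lapply(eq_in, loc)
    born <- Filter(function(e) {
      v <- loc(e)
      !length(old) || min(vapply(old, function(o)
        max(abs(o - v)), 0)) > 0.05
    }, eq_out)
    in_band <- vapply(born, function(e) {
      v <- loc(e)
      ok1 <- v[1] > cyc$min_x1 - 0.1 && v[1] < cyc$max_x1 + 0.1
      ok2 <- if (is.finite(cyc$min_x2 %||% NA))
        v[2] > cyc$min_x2 - 0.1 && v[2] < cyc$max_x2 + 0.1 else TRUE
      ok1 && ok2
    }, logical(1))
    if (any(in_band)) {
      # confirm the cycle dies at the fold itself: refine the fold location
      # and probe for a surviving cycle just beyond it (a homoclinic death
      # can share the window with an unrelated fold)
      z_c <- bisect_count_change(system, z_in, z_out, params)
      probe <- z_c + min(1e-3, (z_out - z_c) / 2)
      cs <- cycle_stats(system, probe, params, amp_tol = amp_tol)
      if (!identical(cs$type, "cycle")) return("SNIC")
    }
  }
  if (amp < 20 * amp_tol) return("HOPF")
  # Hopf can also show as a stability flip without amplitude collapse if the
  # grid is coarse; check for a focus stability change
  if (focus_flip_between(system, z_in, z_out, params)) return("HOPF")
  "HOMOCLINIC"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

focus_flip_between <- function(system, z1, z2, params) {
  r1 <- lead_focus_re(system, z1, params)
  r2 <- lead_focus_re(system, z2, params)
  isTRUE(r1 > 0 && r2 < 0) || isTRUE(r1 < 0 && r2 > 0)
}

# ---- bifurcation detection --------------------------------------------------

#' Detect bifurcation points in a swept diagram
#'
#' Saddle-node points are located where the equilibrium count changes between
#' neighbouring grid values (refined by bisection on the exact per-branch
#' solver); Hopf points where a focus changes stability along a branch
#' (refined by bisection on the leading real part). Cycle terminations are
#' copied from an envelope when one is supplied.
#'
#' @param diagram An `epidyn_diagram` from [sweep_branches()].
#' @param envelope Optional result of [cycle_envelope()] on the same system.
#' @return A data.frame with columns `type` (`"SN"`, `"HOPF"`, `"HOMOCLINIC"`,
#'   `"SNIC"`) and `par` (refined location); empty if no bifurcations.
#' @export
detect_bifurcations <- function(diagram, envelope = NULL) {
  system <- attr(diagram, "system")
  params <- attr(diagram, "params")
  grid <- unique(diagram$par)
  grid <- sort(grid)
  pts <- data.frame(type = character(0), par = numeric(0))
  if (length(grid) >= 2) {
    counts <- vapply(grid, function(v)
      sum(diagram$par == v), 0L)
    for (i in seq_len(length(grid) - 1)) {
      if (counts[i] != counts[i + 1]) {
        loc <- bisect_count_change(system, grid[i], grid[i + 1], params)
        pts <- rbind(pts, data.frame(type = "SN", par = loc))
      }
    }
    # Hopf: stability flip of a focus along neighbouring grid points
    for (i in seq_len(length(grid) - 1)) {
      if (focus_flip_between(system, grid[i], grid[i + 1], params)) {
        loc <- bisect_focus_flip(system, grid[i], grid[i + 1], params)
        pts <- rbind(pts, data.frame(type = "HOPF", par = loc))
      }
    }
  }
  if (!is.null(envelope)) {
    term <- attr(envelope, "termination")
    idx <- which(envelope$has_cycle)
    if (length(idx)) {
      if (term[["lower"]] %in% c("SNIC", "HOMOCLINIC", "HOPF"))
        pts <- rbind(pts, data.frame(type = term[["lower"]],
                                     par = envelope$z[min(idx)]))
      if (term[["upper"]] %in% c("SNIC", "HOMOCLINIC", "HOPF"))
        pts <- rbind(pts, data.frame(type = term[["upper"]],
                                     par = envelope$z[max(idx)]))
    }
  }
  pts[order(pts$par), , drop = FALSE]
}

bisect_count_change <- function(system, lo, hi, params, iter = 45) {
  n_lo <- count_equilibria_at(system, lo, params)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (count_equilibria_at(system, mid, params) == n_lo) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

bisect_focus_flip <- function(system, lo, hi, params, iter = 40) {
  s_lo <- sign(lead_focus_re(system, lo, params))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    s_mid <- sign(lead_focus_re(system, mid, params))
    if (is.na(s_mid) || s_mid == s_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# ---- seizure-class identification -------------------------------------------

#' Classify the seizure-like-event bifurcation pair at a parameter point
#'
#' Determines, for the full model at the given parameters, how transitions
#' between the normal and ictal states occur: onset is always the fold (SN1)
#' of the lower branch; the offset type is identified by continuing the
#' frozen-z fast attractor upward in z from just below SN1 (emulating the
#' post-onset ictal evolution) and observing how the fast oscillation
#' terminates -- amplitude collapse (`"HOPF"`), finite-amplitude death with a
#' node-saddle pair born on the cycle (`"CIRCLE"`, i.e. SNIC), finite-
#' amplitude death at a pre-existing saddle (`"HOMOCLINIC"`), or no fast
#' oscillation at all (`"FOLD"`, the point-point switch; flagged as
#' depolarization block when the upper equilibria are stable nodes).
#'
#' The regime admits a seizure-like event only when the full model's
#' equilibrium set consists of saddles; otherwise a `"no SLE"` result is
#' returned with the equilibrium classes.
#'
#' @param params An [epidyn_params()] object (set `m`, `Iext2`, `x0`).
#' @param n_rungs Number of continuation steps between SN1 and the offset.
#' @param dz0 Offset below SN1 at which the post-onset attractor is sampled.
#' @return A list with `sle` (logical), `onset` (`"SN"`), `onset_z`,
#'   `offset_type` (`"HOMOCLINIC"`, `"CIRCLE"`, `"HOPF"`, `"FOLD"`),
#'   `cycle_end_z` (termination of the fast oscillation, if any),
#'   `offset_z` (return to the lower branch), `bistable` (the `[SN1, offset]`
#'   interval), `db` (logical: upper branch is a stable-node / depolarization
#'   block state), and `equilibrium_classes`.
#' @export
classify_sle <- function(params = epidyn_params(), n_rungs = 120, dz0 = 0.02) {
  eqs <- find_equilibria("full", params)
  cls <- eq_classes(eqs)
  if (!length(cls) || any(cls != "saddle")) {
    return(list(sle = FALSE, reason = "equilibrium set is not all saddles",
                equilibrium_classes = cls))
  }
  # Onset fold of the lower (normal-state) branch: the x1 < 0 equilibrium
  # equations of the full model do not involve x2, so the fold is the
  # subsystem-1 closed form z(SN1).
  sn1 <- sub1_closed_form_points(params)$z_SN1

  # state of the lower-branch node just above SN1 (the pre-onset state)
  eq_above <- find_equilibria("fullfast", params, list(z_frozen = sn1 + dz0))
  low <- Filter(function(e) e$state[["x1"]] < -0.5, eq_above)
  if (!length(low))
    return(list(sle = FALSE, reason = "no lower-branch state at SN1",
                equilibrium_classes = cls))
  x1s <- vapply(low, function(e) e$state[["x1"]], 0)
  init <- as.numeric(low[[which.min(x1s)]]$state)

  z_top <- sn1 + 3
  zs <- seq(sn1 - dz0, z_top, length.out = n_rungs)
  rung <- vector("list", length(zs))
  state <- init
  cycle_seen <- FALSE
  cycle_end_i <- NA_integer_
  offset_i <- NA_integer_
  for (i in seq_along(zs)) {
    cs <- cycle_stats("fullfast", zs[i], params, init = state)
    rung[[i]] <- cs
    if (identical(cs$type, "cycle")) {
      cycle_seen <- TRUE
      state <- cs$state
    } else if (identical(cs$type, "point")) {
      state <- cs$state
      if (cycle_seen && is.na(cycle_end_i)) cycle_end_i <- i
      if (cs$x1 < -0.5 && i > 1) { offset_i <- i; break }
      if (cs$x1 < -0.5 && i == 1)
        return(list(sle = FALSE,
                    reason = "post-onset attractor is the lower branch",
                    equilibrium_classes = cls))
    } else {
      break
    }
  }
  if (is.na(offset_i))
    return(list(sle = FALSE, reason = "no return to the lower branch",
                equilibrium_classes = cls))
  offset_z <- zs[offset_i]

  upper_pts <- Filter(function(r) identical(r$type, "point") &&
                        r$x1 >= -0.5, rung[!vapply(rung, is.null,
                                                   logical(1))])
  db <- FALSE
  if (length(upper_pts)) {
    # nearest equilibrium to the upper plateau: node => depolarization block
    r0 <- upper_pts[[1]]
    eqs_u <- find_equilibria("fullfast", params, list(z_frozen = r0$z))
    if (length(eqs_u)) {
      d <- vapply(eqs_u, function(e) abs(e$state[["x1"]] - r0$x1), 0)
      db <- eqs_u[[which.min(d)]]$class == "stable_node"
    }
  }

  if (!cycle_seen) {
    offset_type <- "FOLD"
    cycle_end_z <- NA_real_
  } else {
    i_last <- if (is.na(cycle_end_i)) offset_i - 1 else cycle_end_i - 1
    # i_last is the last cycle rung; termination lies in (zs[i_last], zs[i_last+1]]
    tag <- termination_tag("fullfast", rung[[i_last]], zs[i_last + 1],
                           params, amp_tol = 1e-2)
    offset_type <- switch(tag, SNIC = "CIRCLE", HOMOCLINIC = "HOMOCLINIC",
                          HOPF = "HOPF")
    cycle_end_z <- zs[i_last]
  }
  list(sle = TRUE, onset = "SN", onset_z = sn1, offset_type = offset_type,
       cycle_end_z = cycle_end_z, offset_z = offset_z,
       bistable = c(sn1, offset_z), db = db, equilibrium_classes = cls)
}

#' Export a diagram and bifurcation points
#'
#' @param diagram An `epidyn_diagram`.
#' @param points Optional data.frame from [detect_bifurcations()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_diagram <- function(diagram, points = NULL, csv_path = NULL,
                          json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(diagram), csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(points))
    jsonlite::write_json(points, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
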