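#' Equilibrium region descriptor at a parameter point
#'
#' Determines the full model's equilibrium multiset at `(m, x0)` (classes and
#' count), the raw material of the equilibrium parameter-space atlas.
#'
#' @param m,x0 Parameter values.
#' @param params Base [epidyn_params()] (its `m`, `x0` are overridden).
#' @return A list with `n`, `classes` (sorted), and `equilibria`.
#' @export
equilibrium_region <- function(m, x0, params = epidyn_params()) {
  params$m <- m; params$x0 <- x0
  eqs <- find_equilibria("full", params)
  list(n = length(eqs), classes = sort(eq_classes(eqs)), equilibria = eqs)
}

#' Periodic-orbit region descriptor at a parameter point
#'
#' Delegates to the averaging machinery on the full model and reports which
#' of the orbit labels `LC`, `S`, `SLC` are present at `(m, x0)`.
#'
#' @inheritParams equilibrium_region
#' @param curve Optional precomputed [averaged_curve()] for this `m`
#'   (reused across x0 values).
#' @return A list with `set` (character subset of `c("LC", "S", "SLC")`) and
#'   `orbits` (the full orbit data.frame).
#' @export
orbit_region <- function(m, x0, params = epidyn_params(), curve = NULL) {
  params$m <- m
  if (is.null(curve)) curve <- averaged_curve("full", params)
  orb <- find_periodic_orbits(x0, "full", params, curve)
  list(set = unique(orb$label), orbits = orb)
}

#' Scan the (m, x0) plane
#'
#' Per-point classification over a parameter grid: equilibrium multisets and
#' (optionally) periodic-orbit sets. Defaults cover the plane the model's
#' behaviour atlases span.
#'
#' @param m_grid,x0_grid Parameter grids (defaults 41 points over
#'   `[-16, 2]` and `[-3, 1]`).
#' @param params Base parameters.
#' @param orbits Also compute orbit sets (one averaged curve per m; slower).
#' @return A data.frame with one row per grid point: `m`, `x0`,
#'   `n_equilibria`, `classes` (comma-separated), and `orbit_set` if
#'   requested.
#' @export
atlas_scan <- function(m_grid = seq(-16, 2, length.out = 41),
                       x0_grid = seq(-3, 1, length.out = 41),
                       params = epidyn_params(), orbits = FALSE) {
  rows <- list()
  for (m in m_grid) {
    curve <- if (orbits) {
      pm <- params; pm$m <- m
      averaged_curve("full", pm)
    } else NULL
    for (x0 in x0_grid) {
      er <- equilibrium_region(m, x0, params)
      row <- data.frame(m = m, x0 = x0, n_equilibria = er$n,
                        classes = paste(er$classes, collapse = ","))
      if (orbits) {
        or <- orbit_region(m, x0, params, curve)
        row$orbit_set <- paste(sort(or$set), collapse = ",")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Interspike intervals and their regularity
#'
#' Detects spikes as upward threshold crossings of a trajectory component
#' (after transient removal) and returns the interspike intervals and their
#' coefficient of variation, the model's chaos diagnostic.
#'
#' @param traj An `epidyn_trajectory`.
#' @param component State column to analyse (default `"x1"`).
#' @param threshold Crossing level; default the mid-range of the component
#'   over the analysed segment.
#' @param transient Fraction of the span discarded first (default 0.25).
#' @return A list with `spike_times`, `intervals`, and `cv`
#'   (sd/mean of the intervals).
#' @export
isi <- function(traj, component = "x1", threshold = NULL, transient = 0.25) {
  stopifnot(inherits(traj, "epidyn_trajectory"))
  tr <- if (transient > 0) drop_transient(traj, transient, fraction = TRUE)
        else traj
  x <- tr$states[, component]
  if (is.null(threshold)) threshold <- (max(x) + min(x)) / 2
  up <- which(x[-length(x)] < threshold & x[-1] >= threshold)
  if (length(up) < 3) stop("fewer than 3 spikes detected")
  dtv <- diff(tr$times)[1]
  st <- tr$times[up] + (threshold - x[up]) / (x[up + 1] - x[up]) * dtv
  iv <- diff(st)
  list(spike_times = st, intervals = iv, cv = stats::sd(iv) / mean(iv))
}

#' Rule-based behaviour classification of a deterministic run
#'
#' Integrates the full model and assigns one label from the closed behaviour
#' vocabulary, using the stationary segment's z-plateau structure and
#' amplitude statistics:
#' \itemize{
#'   \item a steady state maps to `NORMAL_STATE` (lower branch),
#'     `DB` (upper branch, node) or `NONOSCILLATORY` (upper branch, focus);
#'   \item alternation between the lower branch and an upper oscillatory
#'     state maps to the `SLE_*` labels, sub-typed by [classify_sle()]
#'     (`SLE_HOMOCLINIC`, `SLE_CIRCLE`, `SLE_HOPF`); alternation with a
#'     quiet upper plateau maps to `SWITCH_DB_NS` / `SWITCH_NONOSC_NS`;
#'   \item sustained oscillation with a wide z excursion is the large
#'     fast-slow limit cycle `LC_RSE`; with a narrow z band it is
#'     `SLC_PERIODIC`, or `CHAOTIC` when the interspike intervals are
#'     irregular (CV above `cv_cutoff`);
#'   \item an overflow is `DIVERGENT`.
#' }
#'
#' Thresholds are exposed as arguments; they are classifier settings, not
#' model parameters.
#'
#' @param params An [epidyn_params()] object.
#' @param init Initial state (6 components); default the standard seizure
#'   initial condition `[0, -5, 3, 0, 0, 0.01]`.
#' @param duration Integration length (time units).
#' @param dt Integration step.
#' @param steady_tol x1 range below which the state counts as steady.
#' @param upper_split x1 level separating lower and upper branches.
#' @param z_wide z excursion beyond which a sustained oscillation counts as
#'   the large limit cycle.
#' @param cv_cutoff ISI coefficient-of-variation above which a spiking
#'   regime counts as chaotic.
#' @return A character label.
#' @export
classify_behavior <- function(params = epidyn_params(),
                              init = c(0, -5, 3, 0, 0, 0.01),
                              duration = 2500, dt = 0.01,
                              steady_tol = 0.05, upper_split = -0.5,
                              z_wide = 0.3, cv_cutoff = 0.2) {
  tr <- integrate_deterministic("full", init, duration, dt, params,
                                record_every = 5L)
  if (tr$diverged) return("DIVERGENT")
  st <- drop_transient(tr, 0.5, fraction = TRUE)
  x1 <- st$states[, "x1"]
  z <- st$states[, "z"]
  n <- length(x1)

  # steady state: x1 settled over the final fifth of the run
  tail_rng <- diff(range(x1[floor(0.8 * n):n]))
  if (tail_rng < steady_tol) {
    if (x1[n] < upper_split) return("NORMAL_STATE")
    eqs <- find_equilibria("fullfast", params, list(z_frozen = z[n]))
    if (length(eqs)) {
      d <- vapply(eqs, function(e) abs(e$state[["x1"]] - x1[n]), 0)
      if (eqs[[which.min(d)]]$class == "stable_node") return("DB")
    }
    return("NONOSCILLATORY")
  }

  # quiet-run structure: moving-window x1 ranges
  dt_rec <- diff(st$times[1:2])
  w <- max(2L, round(10 / dt_rec))          # 10-time-unit windows
  nw <- floor(n / w)
  wrng <- vapply(seq_len(nw), function(i)
    diff(range(x1[((i - 1) * w + 1):(i * w)])), 0)
  quiet <- wrng < 4 * steady_tol
  runs <- rle(quiet)
  longest_quiet <- if (any(runs$values))
    max(runs$lengths[runs$values]) * 10 else 0

  if (longest_quiet >= 30 && diff(range(z)) > z_wide) {
    # episodic regime: long quiescent interludes alternate with an upper
    # state, carried by a wide slow-variable excursion
    upper <- x1 > upper_split
    amp_up <- if (any(upper)) diff(range(x1[upper])) else 0
    r <- classify_sle(params)
    if (!r$sle) return("CHAOTIC")
    if (amp_up > 10 * steady_tol) {
      switch(r$offset_type,
             HOMOCLINIC = "SLE_HOMOCLINIC", CIRCLE = "SLE_CIRCLE",
             HOPF = "SLE_HOPF",
             FOLD = if (r$db) "SWITCH_DB_NS" else "SWITCH_NONOSC_NS")
    } else {
      if (r$db) "SWITCH_DB_NS" else "SWITCH_NONOSC_NS"
    }
  } else {
    # sustained oscillation without normal-state interludes
    if (diff(range(z)) > z_wide) return("LC_RSE")
    cv <- tryCatch(isi(tr, transient = 0.5)$cv, error = function(e) NA)
    if (is.finite(cv) && cv <= cv_cutoff) "SLC_PERIODIC"
    else if (is.finite(cv)) "CHAOTIC"
    else "NONOSCILLATORY"
  }
}
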