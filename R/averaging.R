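# ---- averaged fast activity -------------------------------------------------

#' Average x1 along the frozen-z fast attractor
#'
#' Computes `<x1>(z)`: the time average of x1 over one (or more) periods of
#' the stable limit cycle of the frozen-z fast system, after transient
#' removal; where the attractor reached is a point, its x1 value is returned
#' with period `NA`.
#'
#' @param z Frozen slow-variable value.
#' @param system `"fastslow"` (fast part: subsystem 1) or `"full"` (fast
#'   part: the frozen-z x1-y1-x2-y2 equations).
#' @param params An [epidyn_params()] object.
#' @param ... Passed to the attractor integrator (`t_transient`, `t_window`,
#'   `amp_tol`, ...).
#' @return A list with `mean`, `period` (`NA` for a point attractor) and
#'   `type` (`"cycle"`, `"point"`, or `"none"` when no attractor was found).
#' @export
average_x1 <- function(z, system = c("fastslow", "full"),
                       params = epidyn_params(), ...) {
  system <- match.arg(system)
  fast <- if (system == "fastslow") "sub1" else "fullfast"
  cs <- cycle_stats(fast, z, params, dt = 0.005, t_transient = 200,
                    t_window = 300, ...)
  if (identical(cs$type, "cycle"))
    list(mean = cs$mean_x1, period = cs$period, type = "cycle")
  else if (identical(cs$type, "point"))
    list(mean = cs$x1, period = NA_real_, type = "point")
  else list(mean = NA_real_, period = NA_real_, type = cs$type)
}

#' Averaged fast-activity curve over a z grid
#'
#' Builds the `<x1>(z)` curve by continuing the frozen-z fast attractor over
#' an ascending z grid (each step restarts from the previous attractor).
#' The validity mask records where a stable cycle was found; the curve
#' terminates where the cycle dies (Hopf, homoclinic or SNIC).
#'
#' @inheritParams average_x1
#' @param z_range Range of z covered (default `c(-2.5, 4)`; the
#'   large limit cycle of the slow-fast system can sit slightly below
#'   z = -2).
#' @param n_z Number of grid points (default 400).
#' @return A data.frame `z, mean_x1, period, type` with attribute `system`;
#'   `type` is `"cycle"`, `"point"` or `"none"` per grid point.
#' @export
averaged_curve <- function(system = c("fastslow", "full"),
                           params = epidyn_params(),
                           z_range = c(-2.5, 4), n_z = 400, dt = 0.005,
                           t_transient = 200, t_window = 300) {
  system <- match.arg(system)
  fast <- if (system == "fastslow") "sub1" else "fullfast"
  zs <- seq(z_range[1], z_range[2], length.out = n_z)
  out <- data.frame(z = zs, mean_x1 = NA_real_, period = NA_real_,
                    type = "none", stringsAsFactors = FALSE)
  init <- NULL
  ended <- FALSE
  for (i in seq_along(zs)) {
    if (ended) break
    cs <- cycle_stats(fast, zs[i], params, init = init, dt = dt,
                      t_transient = t_transient, t_window = t_window)
    if (identical(cs$type, "cycle")) {
      out$mean_x1[i] <- cs$mean_x1; out$period[i] <- cs$period
      out$type[i] <- "cycle"
      init <- cs$state
    } else if (identical(cs$type, "point")) {
      out$mean_x1[i] <- cs$x1; out$type[i] <- "point"
      # once the continued cycle has died, the oscillatory branch is over
      if (!is.null(init)) ended <- TRUE
      init <- NULL
    } else {
      init <- NULL
    }
  }
  structure(out, system = system, params = params)
}

#' Slow averaged nullcline
#'
#' Evaluates `<zdot>(z; x0) = r (s (<x1> - x0) - z - 0.1 z^7 [z < 0])` on the
#' cycle-valid part of an averaged curve. Its zeros are the periodic orbits
#' of the slow-fast system; a zero is stable when `d<zdot>/dz < 0`.
#'
#' @param z_grid z values (must be contained in the curve's grid when `curve`
#'   is supplied).
#' @param x0 Excitability value at which to evaluate.
#' @inheritParams average_x1
#' @param curve Optional precomputed [averaged_curve()] (computed on
#'   `z_grid` otherwise).
#' @return Numeric vector of `<zdot>` values (`NA` where the curve is not
#'   cycle-valid).
#' @export
slow_nullcline <- function(z_grid, x0, system = c("fastslow", "full"),
                           params = epidyn_params(), curve = NULL) {
  system <- match.arg(system)
  if (is.null(curve))
    curve <- averaged_curve(system, params, range(z_grid), length(z_grid))
  mean_x1 <- approx_curve(curve, z_grid)
  zterm <- ifelse(z_grid < 0 & !identical(params$z_law, "original"),
                  z_grid + 0.1 * z_grid^7, z_grid)
  params$r * (params$s * (mean_x1 - x0) - zterm)
}

approx_curve <- function(curve, z) {
  ok <- curve$type == "cycle" & is.finite(curve$mean_x1)
  if (sum(ok) < 2) return(rep(NA_real_, length(z)))
  stats::approx(curve$z[ok], curve$mean_x1[ok], xout = z, rule = 1)$y
}

#' Locate periodic orbits of the slow-fast system by averaging
#'
#' Finds the zeros of the slow averaged nullcline on the cycle branch,
#' determines their stability from the sign of `d<zdot>/dz` (central
#' difference, one grid cell), and labels them: the lowest-z stable root is
#' the large-amplitude limit cycle `LC`, a stable root above a saddle is the
#' small-amplitude cycle `SLC`, and unstable roots are saddle orbits `S`.
#'
#' @param x0 Excitability value.
#' @inheritParams slow_nullcline
#' @return An object of class `epidyn_orbits`: data.frame `z, label,
#'   stable, slope`, with attributes `x0`, `m`, `system`.
#' @export
find_periodic_orbits <- function(x0, system = c("fastslow", "full"),
                                 params = epidyn_params(), curve = NULL) {
  system <- match.arg(system)
  if (is.null(curve)) curve <- averaged_curve(system, params)
  ok <- which(curve$type == "cycle" & is.finite(curve$mean_x1))
  res <- data.frame(z = numeric(0), label = character(0),
                    stable = logical(0), slope = numeric(0))
  if (length(ok) >= 2) {
    zs <- curve$z[ok]
    p2 <- params; p2$x0 <- x0
    vals <- slow_nullcline(zs, x0, system, params, curve)
    h <- diff(zs[1:2])
    fz <- function(z) slow_nullcline(z, x0, system, params, curve)
    for (i in seq_len(length(zs) - 1)) {
      if (!is.finite(vals[i]) || !is.finite(vals[i + 1])) next
      if (vals[i] == 0 || vals[i] * vals[i + 1] < 0) {
        root <- tryCatch(stats::uniroot(fz, zs[i + 0:1], tol = 1e-4)$root,
                         error = function(e) NA_real_)
        if (is.na(root)) next
        slope <- (fz(min(root + h, zs[length(zs)])) -
                  fz(max(root - h, zs[1]))) / (2 * h)
        res <- rbind(res, data.frame(z = root, label = NA_character_,
                                     stable = slope < 0, slope = slope))
      }
    }
  }
  if (nrow(res)) {
    res <- res[order(res$z), , drop = FALSE]
    stable_idx <- which(res$stable)
    lab <- rep("S", nrow(res))
    if (length(stable_idx)) {
      lab[stable_idx[1]] <- "LC"
      if (length(stable_idx) > 1) lab[stable_idx[-1]] <- "SLC"
    }
    res$label <- lab
    rownames(res) <- NULL
  }
  structure(res, x0 = x0, m = params$m, system = system, curve = curve,
            class = c("epidyn_orbits", "data.frame"))
}

#' Sweep periodic orbits over x0 and locate the SNPO
#'
#' Computes the periodic-orbit set for each x0 of a grid (the averaged curve
#' is computed once; the nullcline depends on x0 only through the additive
#' term `-r s x0`), and locates saddle-node-of-periodic-orbit (SNPO)
#' bifurcations by bisection on x0 where a stable/saddle root pair coalesces.
#'
#' @param x0_grid Numeric grid of x0 values.
#' @inheritParams find_periodic_orbits
#' @param snpo_tol Bisection tolerance on x0.
#' @return A list with `orbits` (data.frame `x0, z, label, stable`) and
#'   `snpo` (numeric vector of SNPO x0 locations, possibly empty).
#' @export
sweep_x0_orbits <- function(x0_grid, system = c("fastslow", "full"),
                            params = epidyn_params(), curve = NULL,
                            snpo_tol = 1e-3) {
  system <- match.arg(system)
  if (is.null(curve)) curve <- averaged_curve(system, params)
  x0_grid <- sort(x0_grid)
  sets <- lapply(x0_grid, function(x0)
    find_periodic_orbits(x0, system, params, curve))
  orbits <- do.call(rbind, lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!nrow(s)) return(NULL)
    data.frame(x0 = x0_grid[i], z = s$z, label = s$label, stable = s$stable)
  }))
  nroots <- vapply(sets, nrow, 0L)
  snpo <- numeric(0)
  for (i in seq_len(length(x0_grid) - 1)) {
    # a pair coalescence changes the root count by 2; count changes of 1 are
    # zeros entering/leaving through the ends of the cycle branch
    if (abs(nroots[i] - nroots[i + 1]) >= 2) {
      lo <- x0_grid[i]; hi <- x0_grid[i + 1]
      n_lo <- nroots[i]
      while (hi - lo > snpo_tol) {
        mid <- (lo + hi) / 2
        n_mid <- nrow(find_periodic_orbits(mid, system, params, curve))
        if (n_mid == n_lo) lo <- mid else hi <- mid
      }
      snpo <- c(snpo, (lo + hi) / 2)
    }
  }
  list(orbits = orbits, snpo = snpo, x0_grid = x0_grid, nroots = nroots)
}

#' Export an orbit diagram as CSV / SNPO points as JSON
#'
#' @param sweep Result of [sweep_x0_orbits()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_orbits <- function(sweep, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path) && !is.null(sweep$orbits))
    utils::write.csv(sweep$orbits, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(snpo = sweep$snpo), json_path,
                         auto_unbox = FALSE, digits = NA)
  invisible(NULL)
}
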