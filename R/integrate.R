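new_trajectory <- function(system, res, params, seed = NULL, noise = NULL) {
  n <- as.integer(res$n_recorded)
  states <- res$states[seq_len(n), , drop = FALSE]
  colnames(states) <- SYS_VARS[[system]]
  structure(list(times = res$times[seq_len(n)], states = states,
                 system = system, params = params, dt = res$dt,
                 seed = seed, noise = noise,
                 diverged = isTRUE(res$diverged),
                 truncated_at = if (isTRUE(res$diverged)) n else NA_integer_),
            class = "epidyn_trajectory")
}

#' @export
print.epidyn_trajectory <- function(x, ...) {
  cat(sprintf("<epidyn_trajectory> system=%s n=%d t=[%g, %g] dt=%g%s%s\n",
              x$system, length(x$times), x$times[1],
              x$times[length(x$times)], x$dt,
              if (!is.null(x$seed)) sprintf(" seed=%d", x$seed) else "",
              if (x$diverged) " [DIVERGED, truncated]" else ""))
  invisible(x)
}

#' @export
as.data.frame.epidyn_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states)
}

#' Deterministic integration (fixed-step classical Runge-Kutta)
#'
#' Integrates one of the model systems with the classical 4th-order
#' Runge-Kutta scheme at a fixed step no larger than `dt_max` (default 0.01,
#' the model's standard maximal time step). If the state norm exceeds the
#' overflow guard the trajectory is truncated and flagged (`$diverged`)
#' rather than raising; this reproduces the divergence of the original
#' z-law without crashing.
#'
#' @inheritParams model_rhs
#' @param init Initial state vector.
#' @param duration Length of the integration (time units), or a vector
#'   `c(t0, t1)`.
#' @param dt_max Maximal step size; the actual step divides the span evenly.
#' @param record_every Record every k-th step (thins the output).
#' @param guard Overflow guard: any component exceeding this magnitude marks
#'   divergence.
#' @return An `epidyn_trajectory`: list with `times`, `states` (matrix with
#'   named columns), `system`, `params`, `dt`, `diverged`.
#' @examples
#' p <- epidyn_params()
#' tr <- integrate_deterministic("sub2", c(1, 0), 100,
#'                               params = epidyn_params(Iext2 = 1))
#' range(tr$states[, "x2"])
#' @export
integrate_deterministic <- function(system, init, duration, dt_max = 0.01,
                                    params = epidyn_params(), frozen = NULL,
                                    record_every = 1L, guard = 1e6) {
  system <- check_system(system)
  init <- check_state(system, init)
  span <- if (length(duration) == 2) duration else c(0, duration)
  if (span[2] <= span[1]) stop("invalid time span")
  if (dt_max <= 0) stop("dt_max must be > 0")
  d0 <- model_rhs(system, init, params, frozen)
  if (any(!is.finite(d0))) stop("NaN in rhs at the initial state")
  zf <- frozen_z(frozen)
  res <- .rk4_cpp(SYSTEMS[[system]], init, span[1], span[2], dt_max,
                  cpp_pars(params, frozen),
                  if (is.na(zf)) 0 else zf, !is.na(zf),
                  as.integer(record_every), guard)
  new_trajectory(system, res, params)
}

#' Noise specification for stochastic runs
#'
#' @param variance Variance of the additive Gaussian white noise
#'   (default 0.0025, the model's standard value). Zero variance reduces
#'   the scheme to deterministic forward Euler.
#' @param components Names of the state components receiving noise
#'   (default the fast activity variables `x1` and `x2` where present).
#' @param seed Optional integer seed recorded with the trajectory.
#' @return An object of class `epidyn_noise`.
#' @export
noise_spec <- function(variance = 0.0025, components = c("x1", "x2"),
                       seed = NULL) {
  if (variance < 0) stop("negative variance")
  structure(list(variance = variance, components = components, seed = seed),
            class = "epidyn_noise")
}

#' Stochastic integration (Euler-Maruyama)
#'
#' Euler-Maruyama scheme with additive Gaussian white noise of the given
#' variance added to the configured components (increments
#' `sqrt(dt) * N(0, variance)`). Identical seeds yield identical
#' trajectories; with zero variance the result equals a deterministic
#' forward-Euler run.
#'
#' @inheritParams integrate_deterministic
#' @param dt Step size.
#' @param noise A [noise_spec()].
#' @return An `epidyn_trajectory` carrying the seed actually used.
#' @export
integrate_stochastic <- function(system, init, duration, dt = 0.01,
                                 params = epidyn_params(), noise = noise_spec(),
                                 frozen = NULL, record_every = 1L,
                                 guard = 1e6) {
  system <- check_system(system)
  init <- check_state(system, init)
  stopifnot(inherits(noise, "epidyn_noise"))
  span <- if (length(duration) == 2) duration else c(0, duration)
  if (span[2] <= span[1]) stop("invalid time span")
  vars <- SYS_VARS[[system]]
  sd_vec <- numeric(length(vars))
  idx <- match(intersect(noise$components, vars), vars)
  sd_vec[idx] <- sqrt(noise$variance)
  seed <- noise$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  zf <- frozen_z(frozen)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  res <- .em_cpp(SYSTEMS[[system]], init, span[1], span[2], dt,
                 cpp_pars(params, frozen), sd_vec,
                 if (is.na(zf)) 0 else zf, !is.na(zf),
                 as.integer(record_every), guard)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  new_trajectory(system, res, params, seed = seed, noise = noise)
}

#' Remove the initial transient from a trajectory
#'
#' @param traj An `epidyn_trajectory`.
#' @param cut Either an absolute time span to drop from the start, or (if
#'   `fraction = TRUE`) a fraction of the span.
#' @param fraction Interpret `cut` as a fraction of the time span.
#' @return The trajectory suffix with provenance preserved.
#' @export
drop_transient <- function(traj, cut, fraction = FALSE) {
  stopifnot(inherits(traj, "epidyn_trajectory"))
  span <- traj$times[length(traj$times)] - traj$times[1]
  tcut <- if (fraction) traj$times[1] + cut * span else traj$times[1] + cut
  if (cut < 0) stop("cut must be >= 0")
  if (tcut >= traj$times[length(traj$times)]) stop("cut >= span")
  keep <- traj$times >= tcut
  out <- traj
  out$times <- traj$times[keep]
  out$states <- traj$states[keep, , drop = FALSE]
  out
}

#' Export a trajectory to CSV
#'
#' Writes columns `t` plus the system's state variables, preceded by a
#' provenance header (`#`-prefixed: system, dt, seed, parameter snapshot).
#'
#' @param traj An `epidyn_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "epidyn_trajectory"))
  p <- traj$params
  num <- vapply(p, is.numeric, logical(1))
  hdr <- c(sprintf("# epidyn trajectory: system=%s dt=%g seed=%s diverged=%s",
                   traj$system, traj$dt,
                   if (is.null(traj$seed)) "NA" else traj$seed,
                   traj$diverged),
           paste0("# params: ",
                  paste(sprintf("%s=%g", names(p)[num], unlist(p[num])),
                        collapse = " ")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(traj), con, row.names = FALSE)
  invisible(path)
}
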