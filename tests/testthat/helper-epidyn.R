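# Central-difference Jacobian of a vector field, the oracle for the analytic
# Jacobians.
num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# Random states kept away from the piecewise seams (x1 = 0, x2 = -0.25,
# z = 0).
random_offseam_state <- function(system) {
  away <- function(v, seam) if (abs(v - seam) < 0.05) v + 0.1 else v
  switch(system,
    sub1 = c(away(runif(1, -2, 2), 0), runif(1, -6, 2)),
    sub2 = c(away(runif(1, -1.5, 1.5), -0.25), runif(1, -1, 2)),
    fastslow = c(away(runif(1, -2, 2), 0), runif(1, -6, 2),
                 away(runif(1, -2, 5), 0)),
    full = c(away(runif(1, -2, 2), 0), runif(1, -6, 2),
             away(runif(1, -2, 5), 0), away(runif(1, -1.5, 1.5), -0.25),
             runif(1, -1, 2))
  )
}

# Minimal trajectory object for observable/ISI tests on synthetic series.
make_traj <- function(times, states) {
  structure(list(times = times, states = states, system = "full",
                 params = epidyn_params(), dt = diff(times[1:2]),
                 seed = NULL, noise = NULL, diverged = FALSE,
                 truncated_at = NA_integer_),
            class = "epidyn_trajectory")
}
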