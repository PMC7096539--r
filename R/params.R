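#' Epileptor parameter set
#'
#' Build a validated parameter set for the Epileptor model and its subsystems.
#' Defaults are the model's standard values: subsystem 1 `a = 1`, `b = 3`,
#' `c = 1`, `d = 5`, `Iext1 = 3.1`, `m = 0`; subsystem 2 `a2 = 6`, `tau2 = 10`,
#' `Iext2 = 0.45`, `gamma = 0.01`; slow dynamics `r = 0.00035`, `s = 4`,
#' `x0 = -1.6`.
#'
#' @param a,b,c,d Subsystem-1 cubic/parabolic nullcline coefficients
#'   (dimensionless).
#' @param Iext1 External drive of subsystem 1.
#' @param m Ictal control parameter (slope of the linear part of the
#'   x1-nullcline for `x1 >= 0`).
#' @param a2 Slope of the piecewise-linear subsystem-2 feedback `f2`.
#' @param tau2 Subsystem-2 time constant (must be >= 1).
#' @param Iext2 External drive of subsystem 2.
#' @param gamma Rate of the low-pass filter generating `g` from `x1`
#'   (`dg/dt = x1 - gamma * g`).
#' @param r Slow-variable rate (small; sets the seizure timescale).
#' @param s Slow-variable gain on `x1 - x0`.
#' @param x0 Excitability parameter; shifts the z-nullcline.
#' @param z_law `"modified"` (default; the z-equation gains a `-0.1 z^7` term
#'   for `z < 0`, which bounds the large limit cycle) or `"original"`
#'   (linear relaxation for all z; trajectories started below the saddle
#'   orbit diverge).
#' @param g_convention How the filtered variable `g` enters equilibrium and
#'   Jacobian computations: `"omit"` (default; the `0.002 g` forcing is dropped
#'   from the algebraic system, matching the model's printed 5x5 Jacobian) or
#'   `"stationary"` (substitute the fixed point `g* = x1 / gamma`).
#' @param real_tol,imag_tol Tolerances used when classifying eigenvalues
#'   (see [classify_stability()]).
#'
#' @return An object of class `epidyn_params` (a named list).
#' @examples
#' p <- epidyn_params(m = 0.5)
#' p$Iext1
#' @export
epidyn_params <- function(a = 1, b = 3, c = 1, d = 5, Iext1 = 3.1, m = 0,
                          a2 = 6, tau2 = 10, Iext2 = 0.45, gamma = 0.01,
                          r = 0.00035, s = 4, x0 = -1.6,
                          z_law = c("modified", "original"),
                          g_convention = c("omit", "stationary"),
                          real_tol = 1e-7, imag_tol = 1e-7) {
  z_law <- match.arg(z_law)
  g_convention <- match.arg(g_convention)
  num <- list(a = a, b = b, c = c, d = d, Iext1 = Iext1, m = m, a2 = a2,
              tau2 = tau2, Iext2 = Iext2, gamma = gamma, r = r, s = s, x0 = x0)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (tau2 < 1) stop("tau2 must be >= 1")
  if (r <= 0) stop("r must be > 0")
  if (s <= 0) stop("s must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(c(num, list(z_law = z_law, g_convention = g_convention,
                        real_tol = real_tol, imag_tol = imag_tol)),
            class = "epidyn_params")
}

#' @export
print.epidyn_params <- function(x, ...) {
  cat("<epidyn_params>\n")
  cat(sprintf("  subsystem 1: a=%g b=%g c=%g d=%g Iext1=%g m=%g\n",
              x$a, x$b, x$c, x$d, x$Iext1, x$m))
  cat(sprintf("  subsystem 2: a2=%g tau2=%g Iext2=%g gamma=%g\n",
              x$a2, x$tau2, x$Iext2, x$gamma))
  cat(sprintf("  slow z:      r=%g s=%g x0=%g  [%s law]\n",
              x$r, x$s, x$x0, x$z_law))
  cat(sprintf("  conventions: g=%s  real_tol=%g imag_tol=%g\n",
              x$g_convention, x$real_tol, x$imag_tol))
  invisible(x)
}

#' Serialize / restore a parameter set as plain key=value text
#'
#' @param params An [epidyn_params()] object.
#' @param path File path; for `read_params`, a file written by `write_params`.
#' @return `read_params` returns an `epidyn_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "epidyn_params"))
  num <- vapply(params, function(v) is.numeric(v), logical(1))
  lines <- c(
    sprintf("%s = %.17g", names(params)[num], unlist(params[num])),
    sprintf("%s = %s", names(params)[!num], unlist(params[!num]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- stats::setNames(as.list(vals), keys)
  numkeys <- setdiff(keys, c("z_law", "g_convention"))
  args[numkeys] <- lapply(args[numkeys], as.numeric)
  do.call(epidyn_params, args)
}

# ---- internal: system ids ---------------------------------------------------

SYSTEMS <- c(full = 1L, sub1 = 2L, sub2 = 3L, fastslow = 4L, fullfast = 5L)
SYS_DIM <- c(full = 6L, sub1 = 2L, sub2 = 2L, fastslow = 3L, fullfast = 4L)
SYS_VARS <- list(
  full     = c("x1", "y1", "z", "x2", "y2", "g"),
  sub1     = c("x1", "y1"),
  sub2     = c("x2", "y2"),
  fastslow = c("x1", "y1", "z"),
  fullfast = c("x1", "y1", "x2", "y2")
)

check_system <- function(system) {
  system <- match.arg(system, names(SYSTEMS))
  system
}

check_state <- function(system, state) {
  d <- SYS_DIM[[system]]
  if (length(state) != d)
    stop(sprintf("system '%s' expects a state of length %d, got %d",
                 system, d, length(state)))
  if (any(!is.finite(state))) stop("non-finite state")
  as.numeric(state)
}

# Pack params (+ frozen inputs) for the C++ layer.
cpp_pars <- function(params, frozen = NULL) {
  list(a = params$a, b = params$b, c = params$c, d = params$d,
       Iext1 = params$Iext1, m = params$m, a2 = params$a2, tau2 = params$tau2,
       Iext2 = params$Iext2, gamma = params$gamma, r = params$r, s = params$s,
       x0 = params$x0,
       z_law = if (identical(params$z_law, "original")) 1L else 0L,
       sub2_drive = if (!is.null(frozen$external_input))
         as.numeric(frozen$external_input) else NA_real_)
}

frozen_z <- function(frozen) {
  if (!is.null(frozen$z_frozen)) as.numeric(frozen$z_frozen) else NA_real_
}
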