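preset_entry <- function(system = "full", m = 0, x0 = -1.6, Iext2 = 0.45,
                         r = 0.00035, z_law = "modified",
                         init = c(0, -5, 3, 0, 0, 0.01),
                         t_span = c(0, 2000), dt = 0.01,
                         noise_variance = 0, caption = "") {
  list(system = system, m = m, x0 = x0, Iext2 = Iext2, r = r, z_law = z_law,
       init = init, t_span = t_span, dt = dt,
       noise_variance = noise_variance, caption = caption)
}

# Figure-caption run configurations.  Values are taken verbatim from the
# figure captions; the caption excerpt they trace to is stored alongside.
PRESETS <- list(
  fig1 = preset_entry(
    m = 0, x0 = -1.6, r = 0.00035, init = c(0, -5, 3, 0, 0, 0.01),
    t_span = c(0, 4000), noise_variance = 0.0025,
    caption = paste("Main parameters values: m = 0, x0 = -1.6, and",
                    "r = 0.00035. Initial conditions are [0 -5 3 0 0 0.01].",
                    "(stochastic, Euler-Maruyama)")),
  fig2c = preset_entry(
    m = 0, x0 = -2.5, noise_variance = 0.0025, t_span = c(0, 4000),
    caption = "m = 0 and x0 = -2.5: normal activity (stochastic)"),
  fig2d = preset_entry(
    m = 0, x0 = -0.9, noise_variance = 0.0025, t_span = c(0, 4000),
    caption = "m = 0 and x0 = -0.9: nonoscillatory state (stochastic)"),
  fig2e = preset_entry(
    m = 0.5, x0 = -0.9, noise_variance = 0.0025, t_span = c(0, 4000),
    caption = "m = 0.5 and x0 = -0.9: periodic solution (stochastic)"),
  fig4_sle = preset_entry(
    m = 0.5, x0 = -1.6, r = 0.0007,
    caption = "m = 0.5, Iext2 = 0.45; r = 0.0007 for SLEs"),
  fig4_lc = preset_entry(
    m = 0.5, x0 = -1.6, r = 0.003, init = c(0, -5, 0.01, 0, 0, 0.01),
    caption = "m = 0.5, Iext2 = 0.45; r = 0.003 for LC"),
  fig5_right = preset_entry(
    m = 0, x0 = -1.6, r = 0.0006, init = c(0, -5, 2.5, 0, 0, 0.01),
    t_span = c(0, 1337),
    caption = paste("For the right trajectory, r = 0.0006,",
                    "I.C = [0 -5 2.5 0 0 0.01] and Ts = [0 1337].")),
  fig5_left = preset_entry(
    m = 0, x0 = -1.6, r = 0.001, init = c(0, -5, 1, 0, 0, 0.01),
    t_span = c(0, 1000),
    caption = paste("For the left trajectory, r = 0.001,",
                    "I.C = [0 -5 1 0 0 0.01], and Ts = [0 1000].")),
  fig6 = preset_entry(
    m = 0, x0 = -1.6, Iext2 = 0, r = 0.0005,
    init = c(0, -5, 2.5, 0, 0, 0.01), t_span = c(0, 1540),
    caption = paste("m = 0, Iext2 = 0; r = 0.0005,",
                    "I.C = [0 -5 2.5 0 0 0.01] and Ts = [0:0.001:1540].")),
  fig7 = preset_entry(
    m = -0.5, x0 = -1.6, Iext2 = 0, r = 0.0007,
    init = c(0, -5, 2.65, 0, 0, 0.01), t_span = c(0, 1028),
    caption = paste("m = -0.5, Iext2 = 0; r = 0.0007,",
                    "I.C = [0 -5 2.65 0 0 0.01] and Ts = [0:0.001:1028].")),
  fig8 = preset_entry(
    m = -1, x0 = -1.6, Iext2 = 0, r = 0.0008,
    init = c(0.5, -5, 2, 0, 0, 0.01), t_span = c(0, 1400),
    caption = paste("m = -1, Iext2 = 0; r = 0.0008,",
                    "I.C = [0.5 -5 2 0 0 0.01] and Ts = [0:0.001:1400].")),
  fig9c = preset_entry(
    m = 0.5, x0 = -1.6, r = 0.009, z_law = "original",
    init = c(0, -5, 0.01, 0, 0, 0.01), t_span = c(0, 2000),
    caption = paste("Original (linear) z-equation; trajectory from below",
                    "the separatrix diverges with time. r = 0.009 for (i2).")),
  fig9d = preset_entry(
    m = 0.5, x0 = -1.6, r = 0.009,
    init = c(0, -5, 0.01, 0, 0, 0.01), t_span = c(0, 2000),
    caption = paste("Modified z-equation; the same initial condition yields",
                    "the fast-slow limit cycle LC. r = 0.009 for (i2).")),
  fig10 = preset_entry(
    m = 0.5, x0 = -0.9, r = 0.0035, init = c(0, -5, 3, 0, 0, 0.01),
    t_span = c(0, 1000),
    caption = paste("m = 0.5, Iext2 = 0.45, r = 0.0035,",
                    "I.C = [0 -5 3 0 0 0.01] and Ts = [0 1000].")),
  fig13a = preset_entry(
    m = 1, x0 = -1.8, Iext2 = 0, r = 0.0007,
    caption = "Saddle equilibrium (m = 1, x0 = -1.8) with Iext2 = 0, r = 0.0007."),
  fig13b = preset_entry(
    m = -2, x0 = 0, Iext2 = 0, r = 0.0007,
    caption = "Unstable focus (m = -2, x0 = 0) with Iext2 = 0, r = 0.0007."),
  fig14 = preset_entry(
    m = -8, x0 = -1.6, Iext2 = 0, r = 0.0005,
    caption = "Parameters are: m = -8, Iext2 = 0, r = 0.0005."),
  fig15 = preset_entry(
    m = -8, x0 = -1.6, Iext2 = 0.45, r = 0.0005,
    init = c(0, -5, 2.7, 0, 0, 0.01), t_span = c(0, 1600),
    caption = paste("m = -8, x0 = -1.6, Iext2 = 0.45, r = 0.0005,",
                    "I.C = [0 -5 2.7 0 0 0.01], and Ts = [0:0.001:1600].")),
  fig37a = preset_entry(
    m = 1, x0 = -1.6,
    caption = "Chaotic spiking for m = 1, x0 = -1.6 (Iext2 = 0.45)."),
  fig37b = preset_entry(
    m = 1.5, x0 = -1.9,
    caption = paste("Chaotic transition between ictal and normal states",
                    "for m = 1.5, x0 = -1.9.")),
  fig45a = preset_entry(
    system = "fastslow", m = 0, x0 = -1.6, r = 0.002,
    init = c(0, -5, 3), t_span = c(0, 2000),
    caption = paste("Fast-slow subsystem, initial conditions [0 -5 3],",
                    "r = 0.002; m = 0, x0 = -1.6."))
)

#' Figure-preset registry
#'
#' `list_presets()` lists the registered figure run configurations;
#' `load_preset()` returns one as a run config: the parameter set, system id,
#' initial condition, time span, step, noise variance, and the caption
#' excerpt its values trace to.
#'
#' @param id Preset id, e.g. `"fig1"`, `"fig6"`, `"fig14"`.
#' @return For `load_preset`, a list with `params` (an [epidyn_params()]),
#'   `system`, `init`, `t_span`, `dt`, `noise_variance`, `caption`.
#' @examples
#' load_preset("fig1")$params$r
#' @export
load_preset <- function(id) {
  if (!id %in% names(PRESETS)) stop("unknown preset id: ", id)
  e <- PRESETS[[id]]
  list(id = id,
       params = epidyn_params(m = e$m, x0 = e$x0, Iext2 = e$Iext2, r = e$r,
                              z_law = e$z_law),
       system = e$system, init = e$init, t_span = e$t_span, dt = e$dt,
       noise_variance = e$noise_variance, caption = e$caption)
}

#' @rdname load_preset
#' @export
list_presets <- function() names(PRESETS)

#' Run a preset
#'
#' Integrates the system of a registered preset with its caption-faithful
#' configuration (deterministic, or Euler-Maruyama when the preset's noise
#' variance is positive).
#'
#' @inheritParams load_preset
#' @param seed Seed for stochastic presets.
#' @param ... Overrides passed to the integrator (e.g. `record_every`).
#' @return An `epidyn_trajectory`.
#' @export
run_preset <- function(id, seed = 1L, ...) {
  cfg <- load_preset(id)
  if (cfg$noise_variance > 0)
    integrate_stochastic(cfg$system, cfg$init, cfg$t_span, cfg$dt,
                         cfg$params, noise_spec(cfg$noise_variance,
                                                seed = seed), ...)
  else
    integrate_deterministic(cfg$system, cfg$init, cfg$t_span, cfg$dt,
                            cfg$params, ...)
}

#' Serialize / restore a run config as plain key=value text
#'
#' @param config A run config from [load_preset()] (or of the same shape).
#' @param path File path.
#' @return `read_run_config` returns the restored config (identical to the
#'   serialized one up to numeric formatting).
#' @export
write_run_config <- function(config, path) {
  p <- config$params
  num <- vapply(p, is.numeric, logical(1))
  lines <- c(
    sprintf("id = %s", config$id %||% ""),
    sprintf("system = %s", config$system),
    sprintf("init = %s", paste(format(config$init, digits = 17),
                               collapse = ",")),
    sprintf("t_span = %s", paste(format(config$t_span, digits = 17),
                                 collapse = ",")),
    sprintf("dt = %.17g", config$dt),
    sprintf("noise_variance = %.17g", config$noise_variance),
    sprintf("caption = %s", config$caption),
    sprintf("param.%s = %.17g", names(p)[num], unlist(p[num])),
    sprintf("param.%s = %s", names(p)[!num], unlist(p[!num]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pos <- regexpr("=", lines, fixed = TRUE)
  keys <- trimws(substr(lines, 1, pos - 1))
  vals <- trimws(substr(lines, pos + 1, nchar(lines)))
  kv <- stats::setNames(as.list(vals), keys)
  pk <- startsWith(keys, "param.")
  pargs <- stats::setNames(kv[pk], sub("^param\\.", "", keys[pk]))
  numk <- setdiff(names(pargs), c("z_law", "g_convention"))
  pargs[numk] <- lapply(pargs[numk], as.numeric)
  list(id = kv$id,
       params = do.call(epidyn_params, pargs),
       system = kv$system,
       init = as.numeric(strsplit(kv$init, ",")[[1]]),
       t_span = as.numeric(strsplit(kv$t_span, ",")[[1]]),
       dt = as.numeric(kv$dt),
       noise_variance = as.numeric(kv$noise_variance),
       caption = kv$caption)
}
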