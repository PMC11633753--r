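# Odor-evoked receptor conductance waveform: g(t) = m * (a + b - c).
#
# The three piecewise components describe the onset/duration of the odor
# stimulus (a), the decay after stimulus offset (b) and the slow adaptation
# during the steady-state phase (c). Two parameter sets are shipped, one for
# a weak and one for a strong odor concentration; the dimensionless scaling
# factor m maps the raw fitted amplitudes onto target peak receptor currents
# (see calibrate_m()).

.waveform_env <- new.env(parent = emptyenv())

#' Receptor-waveform parameter sets
#'
#' Loads the piecewise conductance parameters for one stimulus intensity from
#' the versioned YAML table shipped with the package.
#'
#' @param intensity `"weak"` or `"strong"`.
#' @param file Optional path to an alternative parameter YAML.
#' @return A named list of class `piecewise_params` with components
#'   `A_amp`, `A_half`, `A_slope` (onset sigmoid), `B_amp`, `B_shift`,
#'   `B_slope`, `B_window` (offset decay) and `C_base`, `C_offset`, `C_amp`,
#'   `C_tau`, `C_onset` (steady-state adaptation). Times are in ms.
#' @export
waveform_params <- function(intensity = c("weak", "strong"), file = NULL) {
  intensity <- match.arg(intensity)
  if (is.null(file)) {
    if (is.null(.waveform_env$table)) {
      path <- system.file("extdata", "waveform_params.yaml", package = "glomflow")
      .waveform_env$table <- yaml::read_yaml(path)
    }
    tab <- .waveform_env$table
  } else {
    tab <- yaml::read_yaml(file)
  }
  p <- lapply(tab[[intensity]], as.numeric)
  validate_piecewise_params(p)
  structure(c(p, list(intensity = intensity)), class = "piecewise_params")
}

validate_piecewise_params <- function(p) {
  needed <- c("A_amp", "A_half", "A_slope", "B_amp", "B_shift", "B_slope",
              "B_window", "C_base", "C_offset", "C_amp", "C_tau", "C_onset")
  missing <- setdiff(needed, names(p))
  if (length(missing))
    stop("waveform parameter set is missing: ", paste(missing, collapse = ", "))
  if (p$A_slope <= 0 || p$B_slope <= 0 || p$C_tau <= 0)
    stop("waveform slopes and time constants must be positive")
  if (p$B_window <= 0) stop("B_window must be positive")
  if (p$C_base - p$C_offset < 0 || p$A_amp < p$C_base - p$C_offset)
    stop("require A_amp >= C_base - C_offset >= 0")
  invisible(p)
}

#' Stimulus specification for the receptor waveform
#'
#' @param t0 Odor onset (ms).
#' @param td Stimulus duration (ms), positive.
#' @param intensity `"weak"` or `"strong"`.
#' @param tx Duration multiplier (>= 1) by which the receptor-current
#'   envelope outlasts the odor stimulus; fixed at 1 for weak stimuli and
#'   drawn per neuron for strong stimuli (see [sample_tx()]).
#' @param m Dimensionless scaling factor applied to `a + b - c`
#'   (see [calibrate_m()]).
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(t0 = 0, td = 3000, intensity = c("weak", "strong"),
                          tx = 1, m = 1) {
  intensity <- match.arg(intensity)
  if (td <= 0) stop("td must be positive")
  if (tx < 1) stop("tx must be >= 1")
  if (m <= 0) stop("m must be positive")
  structure(list(t0 = t0, td = td, intensity = intensity, tx = tx, m = m),
            class = "stimulus_spec")
}

#' Stochastic duration-multiplier rule
#'
#' The receptor current outlasts the odor stimulus by a factor tx. Weak
#' stimuli use tx = 1 exactly; strong stimuli draw
#' `base + N(noise_mean, noise_sd)` per neuron, clipped below at 1 so the
#' envelope never ends before the stimulus does.
#'
#' @param weak_value,strong_base,strong_noise_mean,strong_noise_sd Rule
#'   constants; defaults are the study values (1, 1.65, 0.2, 0.25).
#' @return List of class `tx_rule`.
#' @export
tx_rule <- function(weak_value = 1, strong_base = 1.65,
                    strong_noise_mean = 0.2, strong_noise_sd = 0.25) {
  structure(list(weak_value = weak_value, strong_base = strong_base,
                 strong_noise_mean = strong_noise_mean,
                 strong_noise_sd = strong_noise_sd),
            class = "tx_rule")
}

#' Sample duration multipliers
#'
#' @param intensity `"weak"` or `"strong"`.
#' @param n Number of draws (one per neuron).
#' @param rule A [tx_rule()].
#' @return Numeric vector of length `n`; uses R's RNG (seed with
#'   [set.seed()] for reproducibility).
#' @export
sample_tx <- function(intensity = c("weak", "strong"), n = 1, rule = tx_rule()) {
  intensity <- match.arg(intensity)
  if (intensity == "weak") return(rep(rule$weak_value, n))
  pmax(1, rule$strong_base +
         rnorm(n, mean = rule$strong_noise_mean, sd = rule$strong_noise_sd))
}

#' Receptor conductance components
#'
#' Piecewise components of the odor-evoked receptor conductance, evaluated at
#' times `t` (ms). `component_a` is the onset/duration sigmoid, active on
#' `(t0, t0 + td*tx)`; `component_b` the post-offset decay, active on
#' `(t_off, t_off + B_window)` where `t_off = t0 + td*tx`; `component_c` the
#' steady-state adaptation, active on `(t0 + C_onset, t_off)` and rising
#' monotonically toward `C_base - C_offset`.
#'
#' @param t Numeric vector of times (ms).
#' @param spec A [stimulus_spec()].
#' @param params A [waveform_params()] set (defaults to the set matching
#'   `spec$intensity`).
#' @return Conductance values (raw units, unscaled by `m`), zero outside the
#'   component's window.
#' @export
component_a <- function(t, spec, params = waveform_params(spec$intensity)) {
  t_off <- spec$t0 + spec$td * spec$tx
  out <- numeric(length(t))
  in_win <- t > spec$t0 & t < t_off
  out[in_win] <- params$A_amp /
    (1 + exp((params$A_half + spec$t0 - t[in_win]) / params$A_slope))
  out
}

#' @rdname component_a
#' @export
component_b <- function(t, spec, params = waveform_params(spec$intensity)) {
  t_off <- spec$t0 + spec$td * spec$tx
  out <- numeric(length(t))
  in_win <- t > t_off & t < t_off + params$B_window
  out[in_win] <- params$B_amp /
    (1 + exp((t[in_win] - t_off - params$B_shift) / params$B_slope))
  out
}

#' @rdname component_a
#' @export
component_c <- function(t, spec, params = waveform_params(spec$intensity)) {
  t_off <- spec$t0 + spec$td * spec$tx
  out <- numeric(length(t))
  in_win <- t > spec$t0 + params$C_onset & t < t_off
  out[in_win] <- params$C_base -
    (params$C_offset +
       params$C_amp * exp(-(t[in_win] - spec$t0 - params$C_onset) / params$C_tau))
  out
}

#' Odor-evoked receptor conductance g(t) = m (a + b - c)
#'
#' Combines the three piecewise components, scales by `spec$m` and floors
#' the result at zero (the adaptation component can marginally exceed the
#' onset component near its window onset).
#'
#' @inheritParams component_a
#' @return Conductance values, same length as `t`, >= 0.
#' @export
receptor_conductance <- function(t, spec,
                                 params = waveform_params(spec$intensity)) {
  g <- component_a(t, spec, params) + component_b(t, spec, params) -
    component_c(t, spec, params)
  spec$m * pmax(g, 0)
}

#' Tabulate a receptor waveform
#'
#' Convenience wrapper producing a data frame of the components and the
#' combined conductance on a regular time grid, suitable for writing to CSV.
#'
#' @inheritParams component_a
#' @param t_max End of the grid (ms); defaults to the end of the b window.
#' @param dt Grid step (ms).
#' @return A data frame with columns `t`, `a`, `b`, `c`, `g`.
#' @export
waveform_table <- function(spec, params = waveform_params(spec$intensity),
                           t_max = NULL, dt = 1) {
  if (is.null(t_max))
    t_max <- spec$t0 + spec$td * spec$tx + params$B_window
  t <- seq(spec$t0, t_max, by = dt)
  data.frame(t = t,
             a = component_a(t, spec, params),
             b = component_b(t, spec, params),
             c = component_c(t, spec, params),
             g = receptor_conductance(t, spec, params))
}
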