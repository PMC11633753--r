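# Population readouts: peristimulus time histogram of the simulated ORN
# population and its convolution with a GCaMP6f kernel, the forward model
# linking spike rates to the calcium signal a glomerulus would report.

#' Peristimulus time histogram
#'
#' Mean firing rate across neurons in fixed-width bins.
#'
#' @param spike_trains List of per-neuron spike-time vectors (ms), or a
#'   `population_result`.
#' @param bin_ms Bin width (ms); default 50.
#' @param window Length-2 numeric, start/end of the histogram window (ms).
#'   Defaults to `c(0, max spike time)` rounded up to a whole bin.
#' @return List of class `psth`: `edges` (ms), `mid` (bin centres, ms),
#'   `rate_hz` (mean rate per bin across neurons), `bin_ms`, `n_neurons`.
#' @export
psth <- function(spike_trains, bin_ms = 50, window = NULL) {
  if (inherits(spike_trains, "population_result")) {
    if (is.null(window)) window <- c(0, spike_trains$duration_ms)
    spike_trains <- spike_trains$spikes
  }
  if (!length(spike_trains)) stop("need at least one neuron")
  n_neurons <- length(spike_trains)
  all_sp <- unlist(spike_trains, use.names = FALSE)
  if (is.null(window))
    window <- c(0, if (length(all_sp)) max(all_sp) else bin_ms)
  n_bins <- max(1L, ceiling((window[2] - window[1]) / bin_ms))
  edges <- window[1] + bin_ms * (0:n_bins)
  sel <- all_sp >= edges[1] & all_sp < edges[n_bins + 1]
  counts <- tabulate(findInterval(all_sp[sel], edges), nbins = n_bins)
  structure(list(edges = edges, mid = edges[-1] - bin_ms / 2,
                 rate_hz = counts / (n_neurons * bin_ms / 1000),
                 bin_ms = bin_ms, n_neurons = n_neurons),
            class = "psth")
}

#' GCaMP6f kernel
#'
#' Kernel representing GCaMP6f kinetics, `k(t) = g * (t / 0.001) *
#' exp(-(t + 0.15) / 0.15)` with `t` in seconds. `k(0) = 0`, a single
#' interior maximum at `t = 0.15` s, truncated at `t_max` (> 13 decay
#' constants by default). The scale `g` is free in the model; by default it
#' is chosen so the kernel peak equals 1.
#'
#' @param dt_s Sample interval in seconds (use the PSTH bin width).
#' @param t_max_s Truncation time (s).
#' @param scale Scale `g`; `NULL` (default) normalizes the peak to 1.
#' @return List of class `gcamp_kernel`: `t_s`, `k`, `dt_s`.
#' @export
gcamp_kernel <- function(dt_s = 0.05, t_max_s = 2, scale = NULL) {
  t <- seq(0, t_max_s, by = dt_s)
  k <- (t / 0.001) * exp(-(t + 0.15) / 0.15)
  if (is.null(scale)) scale <- 1 / max(k)
  structure(list(t_s = t, k = scale * k, dt_s = dt_s), class = "gcamp_kernel")
}

#' Convolve a PSTH with the GCaMP6f kernel
#'
#' Discrete causal convolution of the population rate with the indicator
#' kernel; linear in the input rate, and the output at time t depends only
#' on rates at times <= t.
#'
#' @param x A [psth()] object (or numeric rate vector).
#' @param kernel A [gcamp_kernel()] sampled at the PSTH bin width; built
#'   automatically when `x` is a `psth`.
#' @param bin_s Sample interval (s) when `x` is a bare numeric vector.
#' @return List of class `calcium_proxy`: `t_s`, `signal` (a.u.), `dt_s`.
#' @export
gcamp_convolve <- function(x, kernel = NULL, bin_s = NULL) {
  if (inherits(x, "psth")) {
    rate <- x$rate_hz
    dt_s <- x$bin_ms / 1000
    t0 <- x$edges[1] / 1000
  } else {
    rate <- as.numeric(x)
    dt_s <- if (is.null(bin_s)) 0.05 else bin_s
    t0 <- 0
  }
  if (is.null(kernel)) kernel <- gcamp_kernel(dt_s = dt_s)
  if (abs(kernel$dt_s - dt_s) > 1e-12)
    stop("kernel must be sampled at the PSTH bin width")
  n <- length(rate)
  full <- convolve(rate, rev(kernel$k), type = "open") * dt_s
  structure(list(t_s = t0 + dt_s * (seq_len(n) - 0.5), signal = full[seq_len(n)],
                 dt_s = dt_s), class = "calcium_proxy")
}

#' Baseline-relative calcium proxy
#'
#' Subtracts the mean signal over a pre-stimulus baseline window, enabling
#' below-baseline (negative) excursions during depolarizing block.
#'
#' @param proxy A [gcamp_convolve()] result.
#' @param baseline_s Length-2 numeric, baseline window (s); must precede the
#'   stimulus.
#' @return The proxy with `signal` baseline-subtracted and the baseline mean
#'   stored as `baseline`.
#' @export
baseline_relative <- function(proxy, baseline_s) {
  sel <- proxy$t_s >= baseline_s[1] & proxy$t_s < baseline_s[2]
  if (!any(sel)) stop("baseline window contains no samples")
  b <- mean(proxy$signal[sel])
  proxy$signal <- proxy$signal - b
  proxy$baseline <- b
  proxy
}
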