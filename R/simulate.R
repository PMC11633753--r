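# Single-cell and population simulation of the ORN model: fixed-step
# implicit integration of the Hodgkin-Huxley cable chain with per-step
# Gaussian noise current in the end bulb and the receptor conductance as a
# point process on the end-bulb tip.

#' End-bulb noise specification
#'
#' Gaussian current noise injected into the end-bulb compartment each
#' integration step, mimicking spontaneous Nav channel openings that drive
#' basal firing. The default SD of 14 pA (0.014 nA) drawn every 0.025-ms
#' step, on top of a 0.5 pA mean, produces spontaneous axonal firing at
#' ~7 Hz in the default cell. The per-step SD is rescaled by
#' `sqrt(ref_dt_ms / dt)` when integrating at a different step so the noise
#' process (spectral density) is independent of the discretisation.
#'
#' @param mean_pA Mean current (pA); default 0.5.
#' @param sd_pA Per-step standard deviation (pA) at the reference step;
#'   default 14.
#' @param ref_dt_ms Reference integration step (ms) at which `sd_pA` is
#'   defined.
#' @param site Injection site, one of the morphology section names.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(mean_pA = 0.5, sd_pA = 14, ref_dt_ms = 0.025,
                       site = "end_bulb") {
  if (sd_pA < 0) stop("noise sd must be >= 0")
  structure(list(mean_pA = mean_pA, sd_pA = sd_pA, ref_dt_ms = ref_dt_ms,
                 site = site),
            class = "noise_spec")
}

noise_sd_step <- function(noise, dt) {
  ref <- if (is.null(noise$ref_dt_ms)) dt else noise$ref_dt_ms
  noise$sd_pA * sqrt(ref / dt)
}

#' Simulation configuration
#'
#' @param dt Integration step (ms), must be <= 0.05.
#' @param seed Integer seed; every stochastic element (per-step noise,
#'   per-neuron tx draws) derives its stream from it.
#' @param spike_threshold Axonal spike detection threshold (mV).
#' @param refractory_ms Detection lockout after a counted spike (ms).
#' @param spike_site Section whose distal node is monitored for spikes.
#' @param record_sites Character vector of sites to record voltage from
#'   (`"soma"`, `"axon_tip"`, `"end_bulb"`), or `NULL` for none.
#' @param record_dt Recording interval (ms); coarser than `dt` to bound
#'   memory in long runs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(dt = 0.025, seed = 1, spike_threshold = -20,
                       refractory_ms = 2, spike_site = "axon_tip",
                       record_sites = c("soma", "axon_tip"), record_dt = 1) {
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms")
  if (record_dt < dt) record_dt <- dt
  structure(list(dt = dt, seed = as.integer(seed),
                 spike_threshold = spike_threshold,
                 refractory_ms = refractory_ms, spike_site = spike_site,
                 record_sites = record_sites, record_dt = record_dt),
            class = "sim_config")
}

site_node <- function(cell, site) {
  switch(site,
         soma = cell$idx$soma_node,
         axon_tip = cell$idx$axon_tip,
         end_bulb = cell$idx$end_bulb_tip,
         stop("unknown site '", site, "'"))
}

# Deterministic per-neuron seed stream for the C++ RNG.
derive_seed <- function(seed, k) {
  (as.double(seed) %% 2^31) * 1000003 + as.double(k)
}

# Run set.seed() code without clobbering the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

run_chain <- function(cell, v_init, gating_init, n_steps, dt,
                      syn_g = numeric(0), syn_node = 0L, e_syn = 0,
                      noise_node = 0L, noise_mean_nA = 0, noise_sd_nA = 0,
                      inj_node = 0L, inj_nA = numeric(0),
                      spike_node = -1L, spike_thresh = -20, refractory = 2,
                      record_nodes = integer(0), record_every = 0L,
                      seed = 1) {
  .hh_integrate_cpp(v_init, cell$cap_nF, cell$gna_uS, cell$gk_uS,
                    cell$gpas_uS, cell$mem$e_na, cell$mem$e_k, cell$mem$epas,
                    cell$g_axial_uS, dt, as.double(n_steps),
                    syn_g, as.integer(syn_node - 1L), e_syn,
                    as.integer(noise_node - 1L), noise_mean_nA, noise_sd_nA,
                    as.integer(inj_node - 1L), inj_nA,
                    as.integer(spike_node - 1L), spike_thresh, refractory,
                    as.integer(record_nodes - 1L), as.integer(record_every),
                    as.double(seed), numeric(0))
}

#' Resting state of a cell
#'
#' Integrates the cell with no input until it settles, returning the
#' steady-state voltages and gating variables used to initialise
#' simulations.
#'
#' @param cell An [build_cell()] object.
#' @param settle_ms Settling time (ms).
#' @param dt Integration step (ms).
#' @return List with `v` (per-node mV), `gating`, and `v_soma`.
#' @export
rest_state <- function(cell, settle_ms = 1000, dt = 0.025) {
  res <- run_chain(cell, v_init = rep(-65, cell$n_nodes),
                   gating_init = numeric(0),
                   n_steps = round(settle_ms / dt), dt = dt)
  list(v = res$v_final, gating = res$gating_final,
       v_soma = res$v_final[cell$idx$soma_node])
}

#' Simulate a single ORN
#'
#' Advances the Hodgkin-Huxley cable chain with fixed step `cfg$dt` from the
#' resting state, applying the receptor conductance (point process on the
#' end-bulb tip, current `g(t) * (V - e_syn)`) and per-step Gaussian noise.
#' Deterministic given `cfg$seed`.
#'
#' @param cell An [build_cell()] object.
#' @param duration_ms Simulated time (ms).
#' @param stim A [stimulus_spec()] with calibrated `m`, or `NULL` for no
#'   odor stimulus.
#' @param noise A [noise_spec()], or `NULL` to disable noise.
#' @param cfg A [sim_config()].
#' @param init Optional initial state from [rest_state()] (computed if
#'   missing).
#' @param params Waveform parameters for `stim` (default: shipped set for
#'   `stim$intensity`).
#' @return List of class `sim_result`: `spikes` (ms), `v` (matrix time x
#'   site, mV), `v_time` (ms), `conductance` (uS at `v_time`), plus the
#'   configuration used.
#' @export
simulate_orn <- function(cell, duration_ms, stim = NULL, noise = noise_spec(),
                         cfg = sim_config(), init = NULL, params = NULL) {
  if (is.null(init)) init <- rest_state(cell, dt = cfg$dt)
  n_steps <- round(duration_ms / cfg$dt)
  syn_g <- numeric(0)
  if (!is.null(stim)) {
    if (is.null(params)) params <- waveform_params(stim$intensity)
    t_grid <- (seq_len(n_steps) - 1) * cfg$dt
    syn_g <- receptor_conductance(t_grid, stim, params)
  }
  record_nodes <- if (is.null(cfg$record_sites)) integer(0) else
    vapply(cfg$record_sites, site_node, integer(1), cell = cell)
  record_every <- max(1L, as.integer(round(cfg$record_dt / cfg$dt)))
  noise_node <- if (is.null(noise)) 1L else site_node(cell, noise$site)
  res <- run_chain(cell, v_init = init$v, gating_init = init$gating,
                   n_steps = n_steps, dt = cfg$dt,
                   syn_g = syn_g, syn_node = cell$idx$end_bulb_tip,
                   e_syn = cell$mem$e_syn,
                   noise_node = noise_node,
                   noise_mean_nA = if (is.null(noise)) 0 else noise$mean_pA * 1e-3,
                   noise_sd_nA = if (is.null(noise)) 0 else noise_sd_step(noise, cfg$dt) * 1e-3,
                   spike_node = site_node(cell, cfg$spike_site),
                   spike_thresh = cfg$spike_threshold,
                   refractory = cfg$refractory_ms,
                   record_nodes = record_nodes, record_every = record_every,
                   seed = derive_seed(cfg$seed, 0))
  v_time <- seq(0, by = cfg$record_dt,
                length.out = if (length(record_nodes)) nrow(res$v) else 0)
  cond <- if (length(syn_g) && length(v_time))
    syn_g[pmin(length(syn_g), round(v_time / cfg$dt) + 1)] else numeric(0)
  structure(list(spikes = as.numeric(res$spikes),
                 v = if (length(record_nodes)) {
                   colnames(res$v) <- cfg$record_sites
                   res$v
                 } else NULL,
                 v_time = v_time, conductance = cond,
                 duration_ms = duration_ms, stim = stim, cfg = cfg),
            class = "sim_result")
}

#' Simulate a population of ORNs
#'
#' Runs `n_neurons` statistically independent model neurons. Heterogeneity
#' across the population comes from the per-neuron noise stream and, for
#' strong stimuli, a per-neuron duration multiplier tx drawn once per neuron
#' (see [sample_tx()]); all other parameters are identical.
#'
#' @inheritParams simulate_orn
#' @param n_neurons Number of neurons.
#' @param rule A [tx_rule()] used to draw per-neuron tx when
#'   `stim$intensity == "strong"`.
#' @param record_first Record voltage traces for the first neuron only
#'   (default `TRUE`; the rest record spikes only).
#' @return List of class `population_result`: `spikes` (list of per-neuron
#'   spike-time vectors, ms), `tx` (per-neuron multipliers), `example` (the
#'   first neuron's `sim_result`, if recorded), `n_neurons`, `duration_ms`.
#' @export
simulate_population <- function(cell, duration_ms, stim = NULL,
                                n_neurons = 500, noise = noise_spec(),
                                cfg = sim_config(), rule = tx_rule(),
                                params = NULL, record_first = TRUE) {
  init <- rest_state(cell, dt = cfg$dt)
  n_steps <- round(duration_ms / cfg$dt)
  tx <- if (!is.null(stim))
    with_seed_(cfg$seed, sample_tx(stim$intensity, n_neurons, rule))
  else rep(NA_real_, n_neurons)
  if (!is.null(stim) && is.null(params)) params <- waveform_params(stim$intensity)
  record_nodes <- if (record_first && !is.null(cfg$record_sites))
    vapply(cfg$record_sites, site_node, integer(1), cell = cell) else integer(0)
  record_every <- max(1L, as.integer(round(cfg$record_dt / cfg$dt)))
  noise_node <- if (is.null(noise)) 1L else site_node(cell, noise$site)
  t_grid <- (seq_len(n_steps) - 1) * cfg$dt
  spikes <- vector("list", n_neurons)
  example <- NULL
  for (i in seq_len(n_neurons)) {
    syn_g <- numeric(0)
    if (!is.null(stim)) {
      spec_i <- stim
      spec_i$tx <- tx[i]
      syn_g <- receptor_conductance(t_grid, spec_i, params)
    }
    rn <- if (i == 1) record_nodes else integer(0)
    res <- run_chain(cell, v_init = init$v, gating_init = init$gating,
                     n_steps = n_steps, dt = cfg$dt,
                     syn_g = syn_g, syn_node = cell$idx$end_bulb_tip,
                     e_syn = cell$mem$e_syn,
                     noise_node = noise_node,
                     noise_mean_nA = if (is.null(noise)) 0 else noise$mean_pA * 1e-3,
                     noise_sd_nA = if (is.null(noise)) 0 else noise_sd_step(noise, cfg$dt) * 1e-3,
                     spike_node = site_node(cell, cfg$spike_site),
                     spike_thresh = cfg$spike_threshold,
                     refractory = cfg$refractory_ms,
                     record_nodes = rn, record_every = record_every,
                     seed = derive_seed(cfg$seed, i))
    spikes[[i]] <- as.numeric(res$spikes)
    if (i == 1 && length(rn)) {
      v_time <- seq(0, by = cfg$record_dt, length.out = nrow(res$v))
      colnames(res$v) <- cfg$record_sites
      cond <- if (length(syn_g))
        syn_g[pmin(length(syn_g), round(v_time / cfg$dt) + 1)] else numeric(0)
      example <- structure(list(spikes = spikes[[1]], v = res$v,
                                v_time = v_time, conductance = cond,
                                duration_ms = duration_ms, stim = stim,
                                cfg = cfg), class = "sim_result")
    }
  }
  structure(list(spikes = spikes, tx = tx, example = example,
                 n_neurons = n_neurons, duration_ms = duration_ms,
                 stim = stim, cfg = cfg),
            class = "population_result")
}

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a threshold with a refractory lockout, the same rule
#' the integrator applies online. Shrinking spikelets that stay below the
#' threshold during depolarizing block are not counted.
#'
#' @param v Voltage trace (mV).
#' @param t Time stamps (ms), same length as `v`.
#' @param threshold Crossing threshold (mV).
#' @param refractory_ms Lockout after each counted spike (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(v, t, threshold = -20, refractory_ms = 2) {
  stopifnot(length(v) == length(t))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  times <- t[up]
  keep <- numeric(0)
  last <- -Inf
  for (ti in times) {
    if (ti - last >= refractory_ms) {
      keep <- c(keep, ti)
      last <- ti
    }
  }
  keep
}

#' Somatic input resistance
#'
#' Measures steady-state input resistance with a small subthreshold somatic
#' current step at rest (noise off): settle, step, and report the
#' steady-state voltage deflection over the injected current.
#'
#' @param cell An [build_cell()] object.
#' @param step_pA Step amplitude (pA); magnitude must be <= 1.
#' @param settle_ms,step_ms Settling time and step duration (ms).
#' @param dt Integration step (ms).
#' @return Input resistance in gigaohms.
#' @export
input_resistance <- function(cell, step_pA = -1, settle_ms = 2000,
                             step_ms = 2000, dt = 0.025) {
  if (abs(step_pA) > 1) stop("use a step of at most 1 pA")
  init <- rest_state(cell, settle_ms = settle_ms, dt = dt)
  v0 <- init$v_soma
  soma <- cell$idx$soma_node
  res <- run_chain(cell, v_init = init$v, gating_init = init$gating,
                   n_steps = round(step_ms / dt), dt = dt,
                   inj_node = soma, inj_nA = step_pA * 1e-3,
                   spike_node = soma, spike_thresh = -20, refractory = 2,
                   record_nodes = soma,
                   record_every = max(1L, as.integer(round(1 / dt))))
  if (length(res$spikes))
    stop("current step triggered spikes; input resistance undefined")
  v_tail <- mean(tail(res$v[, 1], 100))
  (v_tail - v0) / step_pA  # mV / pA = GOhm
}

#' Spontaneous firing rate
#'
#' Mean axonal spike rate with end-bulb noise and no odor stimulus.
#'
#' @param cell An [build_cell()] object.
#' @param noise A [noise_spec()].
#' @param duration_s Simulated time per neuron (s).
#' @param n_neurons Number of independent neurons averaged.
#' @param cfg A [sim_config()]; voltage recording is disabled internally.
#' @return List with `rate_hz` (population mean), `per_neuron` (Hz).
#' @export
spontaneous_rate <- function(cell, noise = noise_spec(), duration_s = 30,
                             n_neurons = 20, cfg = sim_config()) {
  cfg$record_sites <- NULL
  pop <- simulate_population(cell, duration_ms = duration_s * 1000,
                             stim = NULL, n_neurons = n_neurons,
                             noise = noise, cfg = cfg, record_first = FALSE)
  per <- vapply(pop$spikes, length, numeric(1)) / duration_s
  list(rate_hz = mean(per), per_neuron = per)
}

#' Calibrate the waveform scaling factor m
#'
#' Chooses `m` so that the peak receptor current, measured with the membrane
#' held at its resting potential, equals the target (13 pA for the weak and
#' 96 pA for the strong stimulus). Under voltage clamp the peak current is
#' `m * max(a + b - c) * |V_rest - e_syn|`, so the calibration is exact.
#'
#' @param cell An [build_cell()] object.
#' @param intensity `"weak"` or `"strong"`.
#' @param target_pA Target peak current magnitude (pA); defaults to 13
#'   (weak) or 96 (strong).
#' @param td_ms,tx Stimulus duration and duration multiplier used to locate
#'   the waveform peak (the peak lies early in the stimulus, so these have
#'   no practical influence for td >= ~1 s).
#' @return List with `m`, `peak_pA` (achieved, = target), `v_rest` (mV) and
#'   `g_max` (raw waveform peak).
#' @export
calibrate_m <- function(cell, intensity = c("weak", "strong"),
                        target_pA = NULL, td_ms = 3000, tx = 1) {
  intensity <- match.arg(intensity)
  if (is.null(target_pA)) target_pA <- if (intensity == "weak") 13 else 96
  params <- waveform_params(intensity)
  spec <- stimulus_spec(t0 = 0, td = td_ms, intensity = intensity, tx = tx, m = 1)
  t_grid <- seq(0, td_ms * tx + params$B_window, by = 0.25)
  g_max <- max(receptor_conductance(t_grid, spec, params))
  if (g_max <= 0) stop("waveform peak is nonpositive; calibration failed")
  v_rest <- rest_state(cell)$v_soma
  drive <- abs(v_rest - cell$mem$e_syn)          # mV
  m <- (target_pA * 1e-3) / (g_max * drive)      # nA / (uS * mV)
  list(m = m, peak_pA = m * g_max * drive * 1e3, v_rest = v_rest, g_max = g_max)
}
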