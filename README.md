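# glomflow

Biophysics of concentration-dependent **depolarizing block** in olfactory
receptor neurons (ORNs), paired with the glomerular **calcium-imaging
analysis pipeline** used to quantify it — plus a synthetic imaging-cohort
generator so the whole pipeline is testable end to end.

## The problem

ORNs are gigaohm-impedance cells driven by odor-evoked receptor currents
that can reach ~100 pA. A weak odor produces sustained spiking; a strong
odor clamps the membrane depolarized, locks Nav channels in their
inactivated state and silences the axon (depolarizing block). Seen through
a glomerular calcium indicator, the response to a strong odor is a brief
onset transient, a fall *below* the pre-stimulus baseline, and a delayed
rebound burst once the receptor current decays — a signature quantified by
the adaptation index **AI = (peak − mean of last 100 ms of stimulus) /
peak** (AI = 1: complete adaptation; AI > 1: response falls below
baseline).

`glomflow` provides:

- a four-compartment Hodgkin–Huxley ORN model (end bulb – dendrite – soma –
  1.6-mm axon) with stochastic end-bulb noise, integrated by a fast
  backward-Euler cable solver (Rcpp);
- the odor-evoked receptor conductance `g(t) = m(a + b − c)` — onset
  sigmoid, post-offset decay, slow adaptation — with weak/strong parameter
  sets and a stochastic duration multiplier `tx`, calibrated to 13 pA
  (weak) / 96 pA (strong) peak receptor currents;
- population readouts: 50-ms PSTHs and a GCaMP6f-kernel convolution
  (`k(t) ∝ t·e^{−(t+0.15)/0.15}`) turning spike rates into a glomerular
  calcium proxy;
- imaging statistics: ΔF/F, adaptation index (5-point mean filter), SNR ≥ 5
  responsiveness with the successive-concentration rule, response maps
  (σ = 2 Gaussian, masked), response amplitudes, percept labelling
  (weak ≤ 0.01 % sv < transition < 0.3 % sv ≤ strong), linear-SVM percept
  classification with leave-one-out weighted F1 and weight attribution, and
  activation-time ranking;
- a synthetic cohort generator (naive / food-associated / exposed mice)
  whose block-mode trace shape is derived from the simulator itself, with
  ground truth for parameter-recovery testing;
- a config-driven pipeline (`load_run_config()`, `run_pipeline()`) writing
  tidy CSV/JSON reports with a manifest.

## Worked example

```r
library(glomflow)

cell <- build_cell()                      # printed morphology & densities
input_resistance(cell)                    # 1.85 GOhm (DC, -1 pA step)

# basal activity: end-bulb noise (mean 0.5 pA, SD 0.014 nA per 25-us step)
spontaneous_rate(cell, duration_s = 30, n_neurons = 20)$rate_hz
# 7.34 Hz

# weak (13 pA) vs strong (96 pA) 60-s stimuli, 100 neurons
m_w <- calibrate_m(cell, "weak")$m
stim <- stimulus_spec(t0 = 5000, td = 60000, intensity = "weak", m = m_w)
pop <- simulate_population(cell, 75000, stim = stim, n_neurons = 100,
                           cfg = sim_config(dt = 0.05, seed = 42,
                                            record_sites = NULL))
p <- psth(pop, window = c(0, 75000))      # baseline 7.0 Hz, stimulus ~37-49 Hz
proxy <- baseline_relative(gcamp_convolve(p), c(0, 5))
adaptation_index(proxy$signal, proxy$t_s, c(5, 65))$ai
# 0.47  (weak: sustained, incomplete adaptation)
```

The same computation for the strong stimulus gives an onset burst, 0 Hz
during the stimulus (axonal silence with the population signal below
baseline), a rebound after the conductance envelope decays, a convolved
peak ~5× *smaller* than the weak stimulus' (4.4 vs 23.0 a.u. — the
GCaMP kernel low-pass filters the brief burst), and AI = 1.73.

On the analysis side:

```r
spec <- cohort_spec(cohort = "naive", seed = 17)   # 9 mice, 8-step ladder
tables <- generate_cohort(spec)
stats <- cohort_trial_stats(tables)                # SNR, amplitude, AI per trial

ds <- generate_percept_dataset(spec, tables = tables)
rep <- fit_percept_classifier(ds$per_mouse[[1]]$x, ds$per_mouse[[1]]$labels,
                              top_k = 1)
rep$f1          # ~0.95-1.0 leave-one-out weighted F1
```

In the naive cohort the primary glomerulus has AI ≈ 0.2 at weak
concentrations and AI ≈ 1.7 at strong ones, activates first (rank 1) at
weak concentrations but lags later-recruited glomeruli at strong ones; in
the food-associated cohort the block disappears (AI < 1 throughout) and the
concentration of maximal response shifts ~2 orders of magnitude upward.

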