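# Integrator behaviour: determinism, passive analytics, oracle equivalence,
# spike detection, input resistance, spontaneous rate, calibration.

test_that("identical seed and configuration give bit-identical spike trains", {
  cell <- gf_cell()
  stim <- stimulus_spec(t0 = 500, td = 1500, intensity = "weak",
                        m = gf_m("weak"))
  cfg <- sim_config(seed = 11, record_sites = NULL)
  r1 <- simulate_population(cell, 2500, stim = stim, n_neurons = 3, cfg = cfg,
                            record_first = FALSE)
  r2 <- simulate_population(cell, 2500, stim = stim, n_neurons = 3, cfg = cfg,
                            record_first = FALSE)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- simulate_population(cell, 2500, stim = stim, n_neurons = 3,
                            cfg = sim_config(seed = 12, record_sites = NULL),
                            record_first = FALSE)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("passive single compartment charges with tau = Cm/gpas = 12.5 ms", {
  cell <- patch_cell(passive_only = TRUE)
  dt <- 0.025
  res <- glomflow:::run_chain(cell, v_init = -50, gating_init = numeric(0),
                              n_steps = 100 / dt, dt = dt,
                              inj_node = 1, inj_nA = 1e-3,
                              record_nodes = 1, record_every = 1)
  v <- res$v[, 1]
  t <- seq(0, by = dt, length.out = length(v))
  dv_inf <- v[length(v)] + 50
  # voltage reaches (1 - 1/e) of its step response at t = tau
  i_tau <- which.min(abs((v + 50) / dv_inf - (1 - exp(-1))))
  expect_equal(t[i_tau], 12.5, tolerance = 0.03)
  # steady state: 1 pA over gpas * area
  g_uS <- sum(cell$gpas_uS)
  expect_equal(dv_inf, 1e-3 / g_uS, tolerance = 1e-3)
})

test_that("single-compartment stepping matches an independent HH integration", {
  skip_if_not_installed("deSolve")
  cell <- patch_cell()
  gna <- sum(cell$gna_uS); gk <- sum(cell$gk_uS); gpas <- sum(cell$gpas_uS)
  cap <- sum(cell$cap_nF)
  vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                                 x / (exp(x / y) - 1))
  rates <- function(v) list(
    am = 0.1 * vtrap(-(v + 40), 10), bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20), bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * vtrap(-(v + 55), 10), bn = 0.125 * exp(-(v + 65) / 80))
  deriv <- function(t, y, p) {
    with(as.list(y), {
      r <- rates(V)
      ina <- gna * m^3 * h * (V - 50)
      ik <- gk * n^4 * (V + 77)
      il <- gpas * (V + 50)
      list(c(V = (-ina - ik - il + 2e-4) / cap,
             m = r$am * (1 - m) - r$bm * m,
             h = r$ah * (1 - h) - r$bh * h,
             n = r$an * (1 - n) - r$bn * n))
    })
  }
  v0 <- -65
  r0 <- rates(v0)
  y0 <- c(V = v0, m = r0$am / (r0$am + r0$bm), h = r0$ah / (r0$ah + r0$bh),
          n = r0$an / (r0$an + r0$bn))
  times <- seq(0, 100, by = 0.5)
  ref <- deSolve::lsoda(y0, times, deriv, NULL, rtol = 1e-9, atol = 1e-9)
  dt <- 0.025
  res <- glomflow:::run_chain(cell, v_init = v0, gating_init = numeric(0),
                              n_steps = 100 / dt, dt = dt,
                              inj_node = 1, inj_nA = 2e-4,
                              record_nodes = 1, record_every = 20)
  v_pkg <- res$v[, 1]
  expect_lt(max(abs(v_pkg - ref[, "V"])), 0.5)
})

test_that("spike detection counts threshold crossings with refractory lockout", {
  # flat trace at rest
  expect_length(detect_spikes(rep(-63, 100), seq_len(100)), 0)
  # synthetic 3-spike waveform with known crossing times
  t <- seq(0, 50, by = 0.1)
  v <- rep(-70, length(t))
  for (ts in c(10, 20, 35)) v[t >= ts & t < ts + 1] <- 30
  sp <- detect_spikes(v, t, threshold = -20)
  expect_equal(sp, c(10, 20, 35))
  # shrinking spikelets below threshold are not counted
  v2 <- rep(-70, length(t))
  for (ts in c(10, 20, 35)) v2[t >= ts & t < ts + 1] <- -40
  expect_length(detect_spikes(v2, t, threshold = -20), 0)
  # refractory lockout merges rapid double crossings
  v3 <- rep(-70, length(t))
  v3[t >= 10 & t < 10.3] <- 0
  v3[t >= 10.8 & t < 11.1] <- 0
  expect_length(detect_spikes(v3, t, threshold = -20, refractory_ms = 2), 1)
})

test_that("passive-only input resistance matches the analytic cable oracle", {
  cellp <- build_cell(mem = membrane_params(gna = 0, gk = 0))
  rin <- input_resistance(cellp)
  expect_equal(rin, analytic_passive_rin(), tolerance = 0.02)
  # isolated isopotential passive soma: 1/(gpas * area)
  patch <- patch_cell(passive_only = TRUE)
  rin_patch <- input_resistance(patch)
  expect_equal(rin_patch, 1e-3 / sum(patch$gpas_uS), tolerance = 0.01)
})

test_that("full-model input resistance is reported in gigaohms at DC", {
  rin <- input_resistance(gf_cell())
  # the active resting K conductance loads the membrane well below the
  # passive value (~5.2 GOhm); see the methods vignette
  expect_gt(rin, 1)
  expect_lt(rin, analytic_passive_rin())
  expect_error(input_resistance(gf_cell(), step_pA = 5), "1 pA")
})

test_that("spontaneous rate is zero without noise and nondecreasing in noise mean", {
  cell <- gf_cell()
  r0 <- spontaneous_rate(cell, noise = noise_spec(mean_pA = 0, sd_pA = 0),
                         duration_s = 3, n_neurons = 1)
  expect_equal(r0$rate_hz, 0)
  rates <- vapply(c(0, 0.5, 1.5), function(mu)
    spontaneous_rate(cell, noise = noise_spec(mean_pA = mu, sd_pA = 14),
                     duration_s = 5, n_neurons = 2,
                     cfg = sim_config(seed = 5))$rate_hz, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("m calibration hits the target peak currents at clamped rest", {
  cell <- gf_cell()
  calw <- calibrate_m(cell, "weak")
  cals <- calibrate_m(cell, "strong")
  expect_equal(calw$peak_pA, 13, tolerance = 0.01)
  expect_equal(cals$peak_pA, 96, tolerance = 0.01)
  # doubling m doubles the clamped peak current (linearity in clamp)
  expect_equal(calibrate_m(cell, "weak", target_pA = 26)$m, 2 * calw$m,
               tolerance = 1e-12)
  expect_gt(cals$m, calw$m)
})

test_that("halving dt changes the spike count of a weak trial by at most one", {
  cell <- gf_cell()
  stim <- stimulus_spec(t0 = 500, td = 3000, intensity = "weak",
                        m = gf_m("weak"))
  counts <- vapply(c(0.05, 0.025), function(dt) {
    r <- simulate_orn(cell, 4000, stim = stim, noise = NULL,
                      cfg = sim_config(dt = dt, record_sites = NULL))
    length(r$spikes)
  }, numeric(1))
  expect_lte(abs(diff(counts)), 1)
})

test_that("rebound latency after strong stimuli grows with stimulus duration", {
  cell <- gf_cell()
  m <- gf_m("strong")
  lat <- vapply(c(2000, 3500), function(td) {
    stim <- stimulus_spec(t0 = 500, td = td, intensity = "strong",
                          tx = 1.85, m = m)
    r <- simulate_orn(cell, 500 + td * 1.85 + 4000, stim = stim, noise = NULL,
                      cfg = sim_config(record_sites = NULL))
    post <- r$spikes[r$spikes > 500 + td]
    expect_gt(length(post), 0)
    post[1] - (500 + td)
  }, numeric(1))
  expect_gt(lat[2], lat[1])
})

test_that("numerical divergence raises an error naming the step size", {
  cell <- patch_cell()
  expect_error(
    glomflow:::run_chain(cell, v_init = -65, gating_init = numeric(0),
                         n_steps = 2000, dt = 0.05,
                         inj_node = 1, inj_nA = 50),
    "diverged.*0\\.05")
})
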