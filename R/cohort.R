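# Synthetic calcium-imaging cohorts: per-mouse glomerular trace tables
# across the concentration ladder for naive, food-associated, and exposed
# cohorts, with the statistical structure the analysis pipeline assumes.
# The default trace templates are parametric (fast); their block-mode shape
# constants (peak ratio, undershoot depth, rebound delay and amplitude) are
# taken from the mechanistic backend: the population simulator's convolved
# calcium proxy. A mechanistic backend is available for the primary
# glomerulus for direct simulator-derived traces.

#' Cohort specification
#'
#' Study conditions for a synthetic imaging cohort. The defaults follow the
#' experimental design: an 8-step concentration ladder from 3e-5 to 10 % sv
#' presented in ascending order, ~12 glomeruli in the field of view per
#' mouse, 1-3 trials per stimulus sampled at 42 Hz, and N = 9 mice.
#'
#' @param n_mice Number of mice.
#' @param cohort `"naive"`, `"associated"` (odor associated with food) or
#'   `"exposed"` (same odor exposure, no food association).
#' @param ladder Concentration ladder (% saturated vapor), strictly
#'   ascending.
#' @param n_glomeruli Glomeruli per field of view (1 primary + secondaries).
#' @param n_trials Trials per stimulus.
#' @param frame_hz Imaging frame rate (Hz).
#' @param stim_s Stimulus duration (s).
#' @param pre_s Pre-stimulus baseline recorded per trial (s).
#' @param post_s Post-stimulus recording (s).
#' @param noise_sd Baseline dF/F noise SD per frame.
#' @param artifact_prob Probability that a trial carries an
#'   irregular-breathing artifact (coherent activity drop).
#' @param seed Integer seed; the generated tables are a pure function of
#'   the spec including the seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 9,
                        cohort = c("naive", "associated", "exposed"),
                        ladder = c(3e-5, 1e-4, 3e-3, 1e-2, 0.1, 1, 3, 10),
                        n_glomeruli = 12, n_trials = 3, frame_hz = 42,
                        stim_s = 3, pre_s = 5, post_s = 7,
                        noise_sd = 0.03, artifact_prob = 0, seed = 1) {
  cohort <- match.arg(cohort)
  if (n_mice < 1) stop("n_mice must be >= 1")
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing")
  if (artifact_prob < 0 || artifact_prob > 1) stop("artifact_prob must be in [0, 1]")
  structure(list(n_mice = n_mice, cohort = cohort, ladder = ladder,
                 n_glomeruli = n_glomeruli, n_trials = n_trials,
                 frame_hz = frame_hz, stim_s = stim_s, pre_s = pre_s,
                 post_s = post_s, noise_sd = noise_sd,
                 artifact_prob = artifact_prob, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Block-mode template constants measured on the mechanistic backend
# (100-neuron strong-stimulus proxy, 3-s stimulus): peak amplitude ratio
# strong/weak ~0.2, undershoot plateau ~0.59 of the block peak, rebound
# ~2.2x the block peak arriving ~3.6 s after odor offset (growing with
# stimulus strength).
.block_shape <- list(peak_ratio = 0.2, undershoot_frac = 0.59,
                     rebound_frac = 2.2, rebound_delay_s = 3.6)

# Sustained response template (dF/F vs time from odor onset, seconds).
sustained_template <- function(t, amp, dur_s, lat = 0.15, tau_rise = 0.3,
                               k_adapt = 0.55, tau_adapt = 3, tau_off = 0.6) {
  y <- numeric(length(t))
  on <- t >= lat & t <= dur_s
  tt <- t[on] - lat
  y[on] <- amp * (1 - exp(-tt / tau_rise)) *
    ((1 - k_adapt) + k_adapt * exp(-tt / tau_adapt))
  after <- t > dur_s
  td <- dur_s - lat
  y_end <- amp * (1 - exp(-td / tau_rise)) *
    ((1 - k_adapt) + k_adapt * exp(-td / tau_adapt))
  y[after] <- y_end * exp(-(t[after] - dur_s) / tau_off)
  y
}

# Depolarizing-block response template: brief onset burst, sustained
# undershoot below baseline for the rest of the stimulus, rebound burst
# after the receptor-conductance envelope decays.
block_template <- function(t, amp, dur_s, lat = 0.3, tau_burst = 0.35,
                           undershoot = .block_shape$undershoot_frac * amp,
                           tau_under = 0.8,
                           rebound_delay = .block_shape$rebound_delay_s,
                           rebound_amp = .block_shape$rebound_frac * amp,
                           tau_rebound = 0.6) {
  y <- numeric(length(t))
  tt <- t - lat
  burst <- tt > 0
  y[burst] <- amp * (tt[burst] / tau_burst) * exp(1 - tt[burst] / tau_burst)
  under <- tt > 0
  t_reb <- dur_s + rebound_delay
  u <- -undershoot * (1 - exp(-tt[under] / tau_under))
  recover <- t[under] > t_reb
  u[recover] <- u[recover] * exp(-(t[under][recover] - t_reb) / 1.5)
  y[under] <- y[under] + u
  reb <- t > t_reb
  tr <- t[reb] - t_reb
  y[reb] <- y[reb] + rebound_amp * (tr / tau_rebound) * exp(1 - tr / tau_rebound)
  y
}

# Concentration-response curve of the primary glomerulus: log-normal bump
# over log10 concentration. Naive/exposed peak in the weak percept; the
# food-associated cohort's curve is shifted upward by ~2 log units (and
# broadened, retaining sensitivity at the weakest rungs).
primary_amp_curve <- function(lc, cohort) {
  switch(cohort,
         naive = exp(-(lc - (-2))^2 / (2 * 1.5^2)),
         exposed = exp(-(lc - (-1.5))^2 / (2 * 1.6^2)),
         associated = exp(-(lc - 0)^2 / (2 * 2.5^2)))
}

# Per-mouse glomerulus population: roles, thresholds, amplitude params.
glomerulus_models <- function(spec) {
  n_sec <- spec$n_glomeruli - 1
  tibble::tibble(
    glomerulus = seq_len(spec$n_glomeruli),
    role = c("primary", rep("secondary", n_sec)),
    threshold_lc = c(log10(min(spec$ladder)) - 0.1,
                     sort(stats::runif(n_sec, -1, 0.9))),
    amp_max = c(1, stats::runif(n_sec, 0.8, 1.6)))
}

# Response mode of the primary glomerulus at a concentration: block above
# the transition range for naive/exposed cohorts; always sustained after
# food association.
primary_mode <- function(conc, cohort) {
  if (cohort == "associated") return("sustained")
  if (conc >= 0.3) "block" else "sustained"
}

#' Generate a synthetic imaging cohort
#'
#' Produces glomerular fluorescence trace tables with the response
#' phenotypes of the chosen cohort: a primary glomerulus responding from
#' the lowest concentrations (sustained at weak concentrations; transient
#' burst + undershoot + rebound, i.e. depolarizing block, at strong
#' concentrations in naive and exposed cohorts; sustained throughout in the
#' food-associated cohort, with its sensitivity shifted ~2 orders of
#' magnitude upward), plus later-recruited secondary glomeruli, Gaussian
#' frame noise and optional irregular-breathing artifact trials.
#'
#' @param spec A [cohort_spec()].
#' @param backend `"parametric"` (closed-form templates, default) or
#'   `"mechanistic"` (primary-glomerulus traces derived from the population
#'   simulator's convolved calcium proxy; slow).
#' @param cell,n_neurons Used by the mechanistic backend.
#' @return A tibble with columns `mouse`, `glomerulus`, `concentration`,
#'   `trial`, `frame_time_s`, `F` (raw fluorescence, baseline 100).
#'   Attribute `ground_truth` holds the per-mouse glomerulus models, the
#'   per-trial artifact flags and the spec.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            backend = c("parametric", "mechanistic"),
                            cell = NULL, n_neurons = 60) {
  backend <- match.arg(backend)
  with_seed_(spec$seed, {
    fs <- spec$frame_hz
    t_s <- seq(0, spec$pre_s + spec$stim_s + spec$post_s - 1 / fs, by = 1 / fs)
    onset <- spec$pre_s
    t_rel <- t_s - onset
    mech <- if (backend == "mechanistic")
      mechanistic_templates(spec, cell, n_neurons) else NULL
    n_f <- length(t_s)
    n_g <- spec$n_glomeruli
    f_chunks <- list()
    meta <- list()
    truth_models <- list()
    truth_art <- list()
    f0 <- 100
    for (mi in seq_len(spec$n_mice)) {
      models <- glomerulus_models(spec)
      truth_models[[mi]] <- tibble::tibble(mouse = mi, models)
      for (ci in seq_along(spec$ladder)) {
        conc <- spec$ladder[ci]
        lc <- log10(conc)
        for (tr in seq_len(spec$n_trials)) {
          artifact <- stats::runif(1) < spec$artifact_prob
          truth_art[[length(truth_art) + 1]] <-
            tibble::tibble(mouse = mi, concentration = conc, trial = tr,
                           artifact = artifact)
          # the primary responds reliably; secondaries are noisier, with
          # larger trial-to-trial gain variability and occasional failures
          gain <- c(pmax(0.6, stats::rnorm(1, 1, 0.1)),
                    pmax(0, stats::rnorm(n_g - 1, 1, 0.35)) *
                      stats::rbinom(n_g - 1, 1, 0.9))
          art <- if (artifact) artifact_window(t_rel, spec) else NULL
          y_mat <- matrix(0, n_f, n_g)
          for (gi in seq_len(n_g)) {
            y <- glomerulus_response(t_rel, models[gi, ], conc, lc, spec, mech)
            y <- y * gain[gi]
            if (!is.null(art))
              y[art$mask] <- y[art$mask] * 0.02 - art$depth
            y_mat[, gi] <- y + stats::rnorm(n_f, 0, spec$noise_sd)
          }
          f_chunks[[length(f_chunks) + 1]] <- f0 * (1 + as.vector(y_mat))
          meta[[length(meta) + 1]] <- c(mi, conc, tr)
        }
      }
    }
    meta <- do.call(rbind, meta)
    n_chunk <- n_f * n_g
    out <- tibble::tibble(
      mouse = rep(meta[, 1], each = n_chunk),
      glomerulus = rep.int(rep(seq_len(n_g), each = n_f), nrow(meta)),
      concentration = rep(meta[, 2], each = n_chunk),
      trial = rep(meta[, 3], each = n_chunk),
      frame_time_s = rep.int(t_s, n_g * nrow(meta)),
      F = unlist(f_chunks, use.names = FALSE))
    attr(out, "ground_truth") <- list(
      models = do.call(rbind, truth_models),
      artifacts = do.call(rbind, truth_art),
      spec = spec)
    out
  })
}

# Noise-free dF/F response of one glomerulus to one stimulus.
glomerulus_response <- function(t_rel, md, conc, lc, spec, mech = NULL) {
  if (md$role == "primary") {
    amp <- primary_amp_curve(lc, spec$cohort)
    mode <- primary_mode(conc, spec$cohort)
    if (!is.null(mech)) {
      tmpl <- if (mode == "block") mech$block else mech$sustained
      return(amp * (if (mode == "block") .block_shape$peak_ratio else 1) *
               tmpl(t_rel))
    }
    if (mode == "block") {
      # block-mode peak is a fixed fraction of the sustained peak and the
      # rebound delay grows with stimulus strength (mechanistic constants)
      a <- .block_shape$peak_ratio * max(primary_amp_curve(-2, spec$cohort), amp)
      delay <- .block_shape$rebound_delay_s + 0.4 * (lc - log10(0.3))
      block_template(t_rel, a, spec$stim_s, rebound_delay = delay)
    } else {
      sustained_template(t_rel, amp, spec$stim_s)
    }
  } else {
    if (lc < md$threshold_lc) return(numeric(length(t_rel)))
    amp <- md$amp_max * min(1, (lc - md$threshold_lc) / 2)
    # secondaries activate faster (shorter latency) the further the
    # stimulus is above their threshold
    lat <- 0.1 + 0.5 * max(0, 1 - (lc - md$threshold_lc))
    sustained_template(t_rel, amp, spec$stim_s, lat = lat)
  }
}

# Irregular-breathing artifact: for ~1.2 s during the stimulus the odor
# input effectively ceases, so every glomerulus' response collapses and
# dips below baseline together.
artifact_window <- function(t_rel, spec) {
  start <- stats::runif(1, 0.3, max(0.4, spec$stim_s - 1.2))
  list(mask = t_rel >= start & t_rel <= start + 1.2,
       depth = max(0.15, 6 * spec$noise_sd))
}

# Simulator-derived primary-glomerulus templates, peak-normalized.
mechanistic_templates <- function(spec, cell = NULL, n_neurons = 60) {
  if (is.null(cell)) cell <- build_cell()
  make <- function(intensity) {
    cal <- calibrate_m(cell, intensity)
    stim <- stimulus_spec(t0 = spec$pre_s * 1000, td = spec$stim_s * 1000,
                          intensity = intensity,
                          tx = if (intensity == "weak") 1 else 1.65, m = cal$m)
    dur <- (spec$pre_s + spec$stim_s + spec$post_s) * 1000
    pop <- simulate_population(cell, dur, stim = stim, n_neurons = n_neurons,
                               cfg = sim_config(seed = spec$seed,
                                                record_sites = NULL),
                               record_first = FALSE)
    pr <- baseline_relative(gcamp_convolve(psth(pop, window = c(0, dur))),
                            c(0, spec$pre_s))
    sig <- pr$signal / max(abs(pr$signal[pr$t_s > spec$pre_s &
                                           pr$t_s < spec$pre_s + spec$stim_s]))
    t_rel_proxy <- pr$t_s - spec$pre_s
    function(t_rel) stats::approx(t_rel_proxy, sig, xout = t_rel,
                                  rule = 2)$y
  }
  list(sustained = make("weak"), block = make("strong"))
}

#' Inject irregular-breathing artifacts into existing tables
#'
#' Adds a coherent negative transient across all glomeruli to randomly
#' selected trials, keeping ground-truth flags for testing the exclusion
#' rule.
#'
#' @param tables A trace table from [generate_cohort()].
#' @param probability Per-trial artifact probability.
#' @param seed Integer seed.
#' @return The modified tables, with updated `ground_truth` artifact flags.
#' @export
inject_artifacts <- function(tables, probability, seed = 1) {
  gt <- attr(tables, "ground_truth")
  spec <- gt$spec
  with_seed_(seed, {
    trials <- unique(tables[, c("mouse", "concentration", "trial")])
    for (k in seq_len(nrow(trials))) {
      if (stats::runif(1) >= probability) next
      sel <- tables$mouse == trials$mouse[k] &
        tables$concentration == trials$concentration[k] &
        tables$trial == trials$trial[k]
      t_rel <- tables$frame_time_s[sel] - spec$pre_s
      art <- artifact_window(t_rel, spec)
      y <- tables$F[sel] / 100 - 1
      y[art$mask] <- y[art$mask] * 0.02 - art$depth
      tables$F[sel] <- 100 * (1 + y)
      ai <- gt$artifacts$mouse == trials$mouse[k] &
        gt$artifacts$concentration == trials$concentration[k] &
        gt$artifacts$trial == trials$trial[k]
      gt$artifacts$artifact[ai] <- TRUE
    }
  })
  attr(tables, "ground_truth") <- gt
  tables
}

#' Generate a percept-classification dataset
#'
#' Runs the generator and converts the traces into per-mouse matrices of
#' per-stimulus normalized glomerular response amplitudes with percept
#' labels (transition-range stimuli unlabeled), the input format of
#' [fit_percept_classifier()].
#'
#' @param spec A [cohort_spec()].
#' @param tables Optional pre-generated trace table (otherwise generated
#'   from `spec`).
#' @return List of class `percept_dataset`: `per_mouse` (each with `x`
#'   stimuli-by-glomeruli matrix, `labels`, `concentration`, `trial`) and
#'   `spec`.
#' @export
generate_percept_dataset <- function(spec = cohort_spec(), tables = NULL) {
  if (is.null(tables)) tables <- generate_cohort(spec)
  stats <- cohort_trial_stats(tables)
  per_mouse <- lapply(split(stats, stats$mouse), function(d) {
    d$stim_id <- paste(d$concentration, d$trial, sep = "_")
    gl <- sort(unique(d$glomerulus))
    stim <- unique(d[, c("stim_id", "concentration", "trial")])
    x <- matrix(0, nrow(stim), length(gl),
                dimnames = list(stim$stim_id, paste0("g", gl)))
    for (r in seq_len(nrow(d)))
      x[d$stim_id[r], paste0("g", d$glomerulus[r])] <- d$amplitude[r]
    # per-glomerulus normalization to the maximum across stimuli
    x <- apply(x, 2, normalize_responses)
    list(x = x, labels = label_percepts(stim$concentration),
         concentration = stim$concentration, trial = stim$trial)
  })
  structure(list(per_mouse = per_mouse, spec = attr(tables, "ground_truth")$spec),
            class = "percept_dataset")
}

#' Per-trial trace statistics for a cohort table
#'
#' Computes dF/F and the standard per-trial statistics (SNR, response
#' amplitude, adaptation index) for every mouse x glomerulus x
#' concentration x trial combination.
#'
#' @param tables Trace table with columns `mouse`, `glomerulus`,
#'   `concentration`, `trial`, `frame_time_s`, `F`.
#' @param onset_s,stim_s Stimulus onset and duration (s); defaults from the
#'   table's `ground_truth` spec when present.
#' @param baseline_s dF/F baseline window (s).
#' @param pre_s SNR pre-stimulus window (s).
#' @return Tibble with one row per trial and columns `snr`, `amplitude`,
#'   `ai` (NA when the AI peak is nonpositive).
#' @export
cohort_trial_stats <- function(tables, onset_s = NULL, stim_s = NULL,
                               baseline_s = 5, pre_s = 3) {
  gt <- attr(tables, "ground_truth")
  if (is.null(onset_s)) onset_s <- if (!is.null(gt)) gt$spec$pre_s else 5
  if (is.null(stim_s)) stim_s <- if (!is.null(gt)) gt$spec$stim_s else 3
  win <- c(onset_s, onset_s + stim_s)
  key <- interaction(tables$mouse, tables$glomerulus, tables$concentration,
                     tables$trial, drop = TRUE)
  parts <- split(seq_len(nrow(tables)), key)
  stats_mat <- matrix(NA_real_, length(parts), 7)
  for (k in seq_along(parts)) {
    ix <- parts[[k]]
    tt <- tables$frame_time_s[ix]
    x <- dff(tables$F[ix], tt, onset_s, baseline_s = min(baseline_s, onset_s))
    ai <- tryCatch(adaptation_index(x, tt, win)$ai,
                   error = function(e) NA_real_)
    stats_mat[k, ] <- c(tables$mouse[ix[1]], tables$glomerulus[ix[1]],
                        tables$concentration[ix[1]], tables$trial[ix[1]],
                        snr_response(x, tt, win, pre_s = pre_s),
                        response_amplitude(x, tt, win), ai)
  }
  res <- tibble::tibble(mouse = stats_mat[, 1], glomerulus = stats_mat[, 2],
                        concentration = stats_mat[, 3], trial = stats_mat[, 4],
                        snr = stats_mat[, 5], amplitude = stats_mat[, 6],
                        ai = stats_mat[, 7])
  res[order(res$mouse, res$glomerulus, res$concentration, res$trial), ]
}
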