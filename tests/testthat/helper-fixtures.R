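# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

gf_cell <- function() memo("cell", build_cell())

gf_rest <- function() memo("rest", rest_state(gf_cell()))

gf_m <- function(intensity) {
  memo(paste0("m_", intensity), calibrate_m(gf_cell(), intensity)$m)
}

# single-compartment soma-only cell (optionally passive)
patch_cell <- function(diam = 5, passive_only = FALSE) {
  mem <- if (passive_only) membrane_params(gna = 0, gk = 0) else membrane_params()
  build_cell(orn_morphology(axon = NULL, dendrite = NULL, end_bulb = NULL,
                            soma = list(diam = diam, nseg = 1)), mem)
}

# Analytic input resistance of the passive cell: soma + dendrite + end bulb
# lumped isopotentially, in parallel with the finite-cable axon input
# resistance (sealed end). Independent cable-theory oracle.
analytic_passive_rin <- function(morph = orn_morphology(),
                                 mem = membrane_params(gna = 0, gk = 0)) {
  g_cm2 <- mem$gpas * 1e-3                    # S/cm^2
  rm <- 1 / g_cm2                             # ohm cm^2
  area_um2 <- function(s) pi * s$diam * (if (is.null(s$L)) s$diam else s$L)
  lumped_um2 <- area_um2(morph$soma) + area_um2(morph$dendrite) +
    area_um2(morph$end_bulb)
  g_lumped <- g_cm2 * lumped_um2 * 1e-8       # S
  d_cm <- morph$axon$diam * 1e-4
  L_cm <- morph$axon$L * 1e-4
  lambda <- sqrt(rm * d_cm / (4 * mem$Ra))    # cm
  r_inf <- rm / (pi * d_cm * lambda)          # ohm, semi-infinite cable
  r_axon <- r_inf / tanh(L_cm / lambda)       # sealed-end finite cable
  1 / (g_lumped + 1 / r_axon) / 1e9           # GOhm
}

# small cohort spec for fast tests
small_cohort_spec <- function(...) {
  cohort_spec(n_mice = 2, n_glomeruli = 8, n_trials = 2, frame_hz = 21,
              post_s = 6, ...)
}
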