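# Four-compartment ORN morphology and membrane parameters, discretised into
# an unbranched chain of iso-potential nodes:
#   end bulb -- dendrite -- soma -- axon (distal tip last).
# Spherical sections (soma, end bulb) are represented as cylinders with
# length equal to their diameter, so surface area equals the sphere's
# (pi * d^2) and axial resistance follows the usual cable expression.

#' ORN morphology
#'
#' Dimensions of the four sections of the model olfactory receptor neuron.
#' Any section may be set to `NULL` to omit it (used for reduced test cells);
#' at least one section must remain.
#'
#' @param axon List with `L` (um), `diam` (um) and `nseg`; default 1.6 mm x
#'   0.2 um in 51 segments (the axon is much longer than its length
#'   constant, so it needs fine spatial discretisation).
#' @param soma List with `diam` (um) and `nseg`; sphere of 5 um.
#' @param dendrite List with `L`, `diam`, `nseg`; 12 um x 0.8 um.
#' @param end_bulb List with `diam`, `nseg`; sphere of 2 um. The receptor
#'   conductance and the noise current are placed here.
#' @return List of class `orn_morphology`.
#' @export
orn_morphology <- function(axon = list(L = 1600, diam = 0.2, nseg = 51),
                           soma = list(diam = 5, nseg = 1),
                           dendrite = list(L = 12, diam = 0.8, nseg = 5),
                           end_bulb = list(diam = 2, nseg = 1)) {
  sections <- list(end_bulb = end_bulb, dendrite = dendrite, soma = soma,
                   axon = axon)
  sections <- sections[!vapply(sections, is.null, logical(1))]
  if (!length(sections)) stop("morphology needs at least one section")
  for (nm in names(sections)) {
    s <- sections[[nm]]
    if (is.null(s$L)) s$L <- s$diam  # sphere as L = diam cylinder
    if (is.null(s$nseg)) s$nseg <- 1
    if (s$L <= 0 || s$diam <= 0 || s$nseg < 1)
      stop("section '", nm, "' has nonpositive dimensions")
    sections[[nm]] <- s
  }
  structure(sections, class = "orn_morphology")
}

#' Membrane and channel parameters
#'
#' Uniform-density standard Hodgkin-Huxley channels plus leak. Conductance
#' densities in mS/cm^2, reversals in mV, `Ra` in ohm cm, `Cm` in uF/cm^2.
#' `e_na`/`e_k` follow the canonical squid-axon values; `e_syn` is the
#' reversal of the odor-evoked receptor conductance, set depolarised (0 mV)
#' because the receptor current is dominated by the Ca-activated Cl current.
#'
#' @param Ra Axial resistivity (ohm cm).
#' @param Cm Specific capacitance (uF/cm^2).
#' @param gna,gk,gpas Channel densities (mS/cm^2).
#' @param epas Leak reversal (mV).
#' @param e_na,e_k Na and K reversals (mV).
#' @param e_syn Receptor-conductance reversal (mV).
#' @return List of class `membrane_params`.
#' @export
membrane_params <- function(Ra = 180, Cm = 1, gna = 32, gk = 8, gpas = 0.08,
                            epas = -50, e_na = 50, e_k = -77, e_syn = 0) {
  if (any(c(gna, gk, gpas) < 0)) stop("conductance densities must be >= 0")
  if (!(e_na > epas && epas > e_k)) stop("require e_na > epas > e_k")
  structure(list(Ra = Ra, Cm = Cm, gna = gna, gk = gk, gpas = gpas,
                 epas = epas, e_na = e_na, e_k = e_k, e_syn = e_syn),
            class = "membrane_params")
}

#' Build the coupled-node system for an ORN cell
#'
#' Discretises the morphology into a chain of nodes (end bulb first, distal
#' axon last), computing per-node membrane areas, capacitances, channel
#' conductances and inter-node axial coupling conductances from `Ra` and the
#' geometry.
#'
#' @param morph An [orn_morphology()].
#' @param mem A [membrane_params()].
#' @return List of class `orn_cell` with per-node vectors (`area_cm2`,
#'   `cap_nF`, `gna_uS`, `gk_uS`, `gpas_uS`), axial couplings `g_axial_uS`,
#'   node bookkeeping (`section`, `idx`) and the input parameters.
#' @export
build_cell <- function(morph = orn_morphology(), mem = membrane_params()) {
  if (!inherits(morph, "orn_morphology")) morph <- do.call(orn_morphology, morph)
  L <- diam <- numeric(0)
  section <- character(0)
  for (nm in names(morph)) {
    s <- morph[[nm]]
    L <- c(L, rep(s$L / s$nseg, s$nseg))
    diam <- c(diam, rep(s$diam, s$nseg))
    section <- c(section, rep(nm, s$nseg))
  }
  n <- length(L)
  um2_to_cm2 <- 1e-8
  area_cm2 <- pi * diam * L * um2_to_cm2          # lateral cylinder surface
  cap_nF <- mem$Cm * area_cm2 * 1e3               # uF/cm^2 * cm^2 -> nF
  dens_to_uS <- function(g_mS) g_mS * area_cm2 * 1e3  # mS/cm^2 * cm^2 -> uS
  # axial: half-cylinder resistances in ohm; Ra ohm cm, lengths cm, radii cm
  r_half <- mem$Ra * (L * 1e-4 / 2) / (pi * (diam * 1e-4 / 2)^2)
  g_axial_uS <- if (n > 1) 1e6 / (r_half[-n] + r_half[-1]) else numeric(0)
  idx <- list()
  for (nm in unique(section)) idx[[nm]] <- which(section == nm)
  idx$end_bulb_tip <- if ("end_bulb" %in% section) idx$end_bulb[1] else 1L
  idx$soma_node <- if ("soma" %in% section) idx$soma[1] else 1L
  idx$axon_tip <- if ("axon" %in% section) idx$axon[length(idx$axon)] else n
  structure(list(n_nodes = n, section = section, L_um = L, diam_um = diam,
                 area_cm2 = area_cm2, cap_nF = cap_nF,
                 gna_uS = dens_to_uS(mem$gna), gk_uS = dens_to_uS(mem$gk),
                 gpas_uS = dens_to_uS(mem$gpas), g_axial_uS = g_axial_uS,
                 idx = idx, morph = morph, mem = mem),
            class = "orn_cell")
}

#' @export
print.orn_cell <- function(x, ...) {
  cat("ORN cell:", x$n_nodes, "nodes (",
      paste(unique(x$section), collapse = " - "), ")\n")
  cat(sprintf("  total membrane area: %.1f um^2\n", sum(x$area_cm2) / 1e-8))
  invisible(x)
}
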