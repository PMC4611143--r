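## Sarcolemmal electrophysiology on the zero-thickness membrane.
##
## The membrane carries dual potentials (intracellular Psi_i and
## extracellular Psi_e per node pair, V_m = Psi_i - Psi_e) coupled by the
## capacitance approximation, plus a reduced six-current ionic model
## (I_Na, I_CaL, I_K, I_K1, I_NaCa, I_NaK) with Hodgkin-Huxley-style
## kinetics sized for a guinea-pig-like action potential (~200 ms APD).
## The ionic model is a pluggable surrogate: it maps (V, local
## concentrations on both sides) -> (currents, species fluxes), so a full
## reaction network can be substituted behind the same interface.

current_names <- c("I_Na", "I_CaL", "I_K", "I_K1", "I_NaCa", "I_NaK")

## species carried per unit net charge by each current (columns follow
## species_table(); rows follow current_names)
current_stoichiometry <- function(species = species_table()$name) {
  s <- matrix(0, 6, length(species), dimnames = list(current_names, species))
  s["I_Na", "Na"] <- 1
  s["I_CaL", "Ca"] <- 0.5          # z = 2: half a mole of Ca per charge
  s["I_K", "K"] <- 1
  s["I_K1", "K"] <- 1
  s["I_NaCa", "Na"] <- 3           # 3 Na : 1 Ca exchange, net +1 charge
  s["I_NaCa", "Ca"] <- -1
  s["I_NaK", "Na"] <- 3            # 3 Na out : 2 K in, net +1 charge
  s["I_NaK", "K"] <- -2
  s
}

#' Channel density map for surface and t-tubular membrane
#'
#' Per-current scale factors for the two membrane types.  Given
#' t-tubular:surface ratios, factors are normalised so that the
#' area-weighted mean is one (whole-cell conductance is conserved when
#' densities are redistributed).  Na+ channels are enriched in t-tubules by
#' default (ratio 2:1).
#'
#' @param ratios named numeric, t-tubular / surface density ratio per
#'   current (defaults: I_Na = 2, others 1).
#' @param area_surface,area_ttubular total membrane areas, um^2.
#' @return data.frame with columns current, surface, t_tubular.
#' @export
channel_density_map <- function(ratios = c(I_Na = 2),
                                area_surface, area_ttubular) {
  r <- stats::setNames(rep(1, 6), current_names)
  if (length(ratios)) {
    if (!all(names(ratios) %in% current_names)) stop("unknown current in ratios")
    r[names(ratios)] <- ratios
  }
  if (any(r < 0)) stop("density ratios must be >= 0")
  At <- area_ttubular; As <- area_surface
  surf <- (As + At) / (As + r * At)
  if (As + At == 0) surf <- rep(1, 6)
  data.frame(current = current_names, surface = surf, t_tubular = r * surf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Initial gating state of the reduced ionic model
#'
#' @param n number of membrane node pairs.
#' @param V initial membrane potential, mV.
#' @return matrix n x 5 (gates m, h, d, f, x), each in [0, 1].
#' @export
ionic_state_init <- function(n, V = -85) {
  gi <- gate_rates(rep(V, 1))
  g <- c(m = gi$m_inf, h = gi$h_inf, d = gi$d_inf, f = gi$f_inf, x = gi$x_inf)
  matrix(rep(g, each = n), n, 5, dimnames = list(NULL, c("m", "h", "d", "f", "x")))
}

## safe x / (1 - exp(-x)) with its limit 1 at x = 0
vexp <- function(x) {
  out <- x / (1 - exp(-x))
  small <- abs(x) < 1e-7
  out[small] <- 1
  out
}

## steady states and time constants of the five gates (vectorised over V)
gate_rates <- function(V) {
  am <- 3.2 * vexp(0.1 * (V + 47.13))
  bm <- 0.08 * exp(-V / 11)
  lo <- V < -40
  ah <- ifelse(lo, 0.135 * exp(-(V + 80) / 6.8), 0)
  bh <- ifelse(lo, 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
               1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1))))
  d_inf <- 1 / (1 + exp(-(V + 10) / 6.24))
  tau_d <- pmax(0.6, pmin(d_inf / (0.2184 * vexp((V + 10) / 6.24)), 6))
  f_inf <- 1 / (1 + exp((V + 28) / 6.5)) + 0.03 / (1 + exp((50 - V) / 20))
  tau_f <- 70 + 260 / (1 + exp((V + 28) / 8))
  x_inf <- 1 / (1 + exp(-(V + 21.5) / 7.5))
  tau_x <- 260 + 600 * exp(-((V + 30)^2) / 1000)
  list(m_inf = am / (am + bm), tau_m = 1 / (am + bm),
       h_inf = ah / (ah + bh), tau_h = 1 / (ah + bh),
       d_inf = d_inf, tau_d = tau_d,
       f_inf = f_inf, tau_f = tau_f,
       x_inf = x_inf, tau_x = tau_x)
}

## advance gates by dt with the Rush-Larsen exponential update (bounded in
## [0,1] for any dt)
gates_step <- function(gates, V, dt) {
  gr <- gate_rates(V)
  for (nm in colnames(gates)) {
    gi <- gr[[paste0(nm, "_inf")]]
    ta <- gr[[paste0("tau_", nm)]]
    gates[, nm] <- gi + (gates[, nm] - gi) * exp(-dt / ta)
  }
  gates
}

#' Nernst reversal potential
#' @param C_e,C_i extracellular / intracellular concentration, mM (> 0).
#' @param z valence (non-zero).
#' @param constants [phys_constants()].
#' @return potential in mV.
#' @export
nernst <- function(C_e, C_i, z, constants = phys_constants()) {
  if (any(C_e <= 0) || any(C_i <= 0))
    stop("non-positive concentration in a reversal potential")
  constants$RT_F / z * log(C_e / C_i)
}

## default ionic model conductances (A/F per mV), reduced surrogate
ionic_conductances <- function() {
  c(g_Na = 16, g_CaL = 0.105, g_K = 0.11, g_K1 = 0.42, g_Kp = 0.007,
    k_NaCa = 1400, P_NaK = 1.4)
}

#' Compute sarcolemmal ionic currents of the reduced model
#'
#' Hodgkin-Huxley style currents per membrane node pair, scaled by the
#' per-membrane-type channel densities.  Reversal potentials are computed
#' from the local concentrations on the two sides of each pair.
#'
#' @param gates n x 5 gate matrix (columns m, h, d, f, x).
#' @param V membrane potential per pair, mV.
#' @param Ci,Ce local concentrations, n x species matrices (columns named).
#' @param density_scale n x 6 matrix of density factors (rows = pairs,
#'   columns = currents), e.g. built from [channel_density_map()].
#' @param g conductance set, see \code{ionic_conductances}.
#' @param constants [phys_constants()].
#' @return list with \code{I} (n x 6 matrix, A/F, outward positive),
#'   \code{I_total} (n), and \code{flux} (n x species molar stoichiometry
#'   times current, A/F equivalent — multiply by area * charge_flux to get
#'   amol/ms).
#' @export
compute_ionic_currents <- function(gates, V, Ci, Ce, density_scale,
                                   g = ionic_conductances(),
                                   constants = phys_constants()) {
  RTF <- constants$RT_F
  E_Na <- nernst(Ce[, "Na"], Ci[, "Na"], 1, constants)
  E_K <- nernst(Ce[, "K"], Ci[, "K"], 1, constants)
  E_Ca <- nernst(Ce[, "Ca"], Ci[, "Ca"], 2, constants)

  I <- matrix(0, length(V), 6, dimnames = list(NULL, current_names))
  I[, "I_Na"] <- g["g_Na"] * gates[, "m"]^3 * gates[, "h"] * (V - E_Na)
  fCa <- 1 / (1 + Ci[, "Ca"] / 6e-4)
  ## GHK-like saturation of the driving force at strongly positive V
  rect <- 1 / (1 + exp((V - 35) / 12))
  I[, "I_CaL"] <- g["g_CaL"] * gates[, "d"] * gates[, "f"] * fCa * rect * (V - E_Ca)
  I[, "I_K"] <- g["g_K"] * sqrt(Ce[, "K"] / 5.4) * gates[, "x"]^2 * (V - E_K)
  k1inf <- 1 / (1 + exp(0.1 * (V - E_K - 12)))
  ## inward rectifier plus a time-independent plateau K component
  kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  I[, "I_K1"] <- (g["g_K1"] * sqrt(Ce[, "K"] / 5.4) * k1inf +
                    g["g_Kp"] * kp) * (V - E_K)
  eg <- exp(0.35 * V / RTF); egm <- exp(-0.65 * V / RTF)
  I[, "I_NaCa"] <- g["k_NaCa"] *
    (eg * Ci[, "Na"]^3 * Ce[, "Ca"] - egm * Ce[, "Na"]^3 * Ci[, "Ca"] * 2.5) /
    ((87.5^3 + Ce[, "Na"]^3) * (1.38 + Ce[, "Ca"]) * (1 + 0.1 * egm))
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
  I[, "I_NaK"] <- g["P_NaK"] * fnak * (Ce[, "K"] / (Ce[, "K"] + 1.5)) /
    (1 + (10 / Ci[, "Na"])^1.5)

  I <- I * density_scale
  list(I = I, I_total = rowSums(I))
}

#' Stimulus current
#'
#' The pacing stimulus: -100 A/F applied to all sarcolemmal node pairs for
#' 0.5 ms from stimulus onset, carried by a configurable species (default
#' K+ so that electroneutrality remains solvable).
#'
#' @param t current time, ms.
#' @param onset stimulus onset, ms.
#' @param duration pulse duration, ms (default 0.5).
#' @param amplitude A/F (default -100; negative = inward).
#' @return scalar current density (A/F) at time t.
#' @export
apply_stimulus <- function(t, onset = 0, duration = 0.5, amplitude = -100) {
  if (t >= onset && t < onset + duration) amplitude else 0
}

#' Lumped sarcolemmal potential update
#'
#' The reaction-diffusion limit: one membrane potential for the whole cell,
#' advanced by the area-weighted sum of all membrane currents,
#' dV/dt = -(1/C_m) * sum(I_total) / sum(area) (I_total in A/F, so C_m
#' cancels and the rate is in mV/ms).
#'
#' @param I_total current density per pair, A/F (outward positive).
#' @param area membrane area per pair, um^2.
#' @param dt time step, ms.
#' @return scalar potential increment, mV.
#' @export
lumped_potential_step <- function(I_total, area, dt) {
  -dt * sum(I_total * area) / sum(area)
}

#' Membrane electroneutrality residuals at one node pair
#'
#' The dual conditions at a sarcolemmal node: on the intracellular side the
#' transported charge storage, the fixed-charge rate, the ionic current and
#' the capacitive current sum to zero; the extracellular side mirrors it
#' with flipped membrane terms (their sum leaves only the two sides' ion
#' storage terms).
#'
#' @param dCdt_i,dCdt_e species concentration rates on each side, mM/ms
#'   (named or ordered as [species_table()]).
#' @param dCFdt_i,dCFdt_e fixed-charge concentration rates, mM/ms.
#' @param phi_w_i,phi_w_e fluid volume fractions.
#' @param I_total membrane current density, A/F.
#' @param dVdt rate of V_m = Psi_i - Psi_e, mV/ms.
#' @param volume_i,volume_e nodal mixture volumes, um^3.
#' @param area membrane area, um^2.
#' @param species species table.
#' @param constants [phys_constants()].
#' @return numeric length-2: intracellular and extracellular residuals
#'   (amol/ms of charge).
#' @export
membrane_electroneutrality_residuals <- function(dCdt_i, dCdt_e,
                                                 dCFdt_i = 0, dCFdt_e = 0,
                                                 phi_w_i, phi_w_e,
                                                 I_total, dVdt,
                                                 volume_i, volume_e, area,
                                                 species = species_table(),
                                                 constants = phys_constants()) {
  cf <- constants$charge_flux
  stor_i <- sum(species$z * dCdt_i) * phi_w_i * volume_i + dCFdt_i * phi_w_i * volume_i
  stor_e <- sum(species$z * dCdt_e) * phi_w_e * volume_e + dCFdt_e * phi_w_e * volume_e
  r_i <- stor_i + area * cf * I_total + area * cf * dVdt
  r_e <- stor_e - area * cf * I_total - area * cf * dVdt
  c(intra = r_i, extra = r_e)
}

#' Voltage-clamp constraint set
#'
#' Builds the Dirichlet constraints of the clamp protocol: the electrical
#' potential of the outer extracellular boundary is fixed at zero and the
#' intracellular potential of the m-line core nodes at the command voltage.
#'
#' @param mesh a \code{tricell_mesh} (needs an extracellular shell).
#' @param V_cmd command potential, mV.
#' @return list with integer vectors \code{intra_dof}, \code{extra_dof} and
#'   values \code{intra_val}, \code{extra_val}.
#' @export
apply_voltage_clamp <- function(mesh, V_cmd) {
  if (mesh$shell_layers == 0)
    stop("voltage clamp requires an extracellular shell (bath) mesh")
  bath <- mesh$extra_dof[mesh$boundary_tags$outer_bath]
  core <- intersect(mesh$boundary_tags$m_line, mesh$intra_nodes)
  list(intra_dof = mesh$intra_dof[core],
       intra_val = rep(V_cmd, length(core)),
       extra_dof = bath[!is.na(bath)],
       extra_val = rep(0, sum(!is.na(bath))))
}
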