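#' Physical constants and internal unit system
#'
#' The package works in a single consistent unit system chosen for
#' subcellular electromechanics: length in micrometres, time in
#' milliseconds, concentration in millimolar (1 mM is exactly 1 amol/um^3,
#' which makes nodal mole bookkeeping trivial), electrical potential in
#' millivolts, pressure in kilopascals and membrane current density in A/F
#' (current normalised by membrane capacitance, so 1 A/F drives 1 mV/ms).
#'
#' @param T_abs absolute temperature in kelvin (default 310 K, i.e. 37 C).
#' @param Cm_uF_cm2 membrane specific capacitance in uF/cm^2 (default 1.0;
#'   the source model never states it).
#' @return a list of named constants:
#' \describe{
#'   \item{RT_F}{thermal voltage R*T/F in mV (26.73 mV at 310 K).}
#'   \item{RT_kPa}{R*T expressed as osmotic pressure per unit
#'     concentration, kPa/mM.}
#'   \item{F_C_per_mol}{Faraday constant, C/mol.}
#'   \item{Cm}{membrane capacitance in F/um^2.}
#'   \item{charge_flux}{molar charge flux through the membrane per unit
#'     area per unit current density, amol/(um^2 ms) per A/F.  Equal to
#'     \code{Cm * 1e15 / F}; also the capacitive surface charge in
#'     amol/(um^2 mV).}
#' }
#' @export
phys_constants <- function(T_abs = 310, Cm_uF_cm2 = 1.0) {
  R_J <- 8.314462618
  F_C <- 96485.33212
  Cm <- Cm_uF_cm2 * 1e-6 / 1e8       # F/um^2
  list(
    T_abs = T_abs,
    RT_F = R_J * T_abs / F_C * 1e3,  # mV
    RT_kPa = R_J * T_abs / 1e3,      # kPa per mM (R*T in J/mol / 1000)
    F_C_per_mol = F_C,
    Cm = Cm,
    # amol of unit charge per um^2 per ms per (A/F):
    #   Cm [F/um^2] * I [A/F = V/s] = A/um^2; * 1e-3 s/ms / F [C/mol] * 1e18
    charge_flux = Cm * 1e-3 / F_C * 1e18
  )
}

#' Solute species of the ionic phase
#'
#' The nine transported solutes: four ions and five energy metabolites.
#' Metabolite valences default to 0 (transported but charge-inert, their
#' charges absorbed into the fixed-charge pool C^F); they can be overridden.
#'
#' Cytosolic diffusion coefficients for K+, Na+ and Cl- follow the model's
#' parameter table (980, 665, 1015 um^2/s; half their free-solution values).
#' The remaining coefficients are not stated there and use literature-scale
#' defaults on the same half-of-water convention.
#'
#' @param z_metabolites optional named numeric vector of metabolite
#'   valences (names among ATP, ADP, Cr, CrP, Pi) overriding the default 0.
#' @return data.frame with columns \code{name}, \code{z} (valence) and
#'   \code{D_cyto} (cytosolic diffusion coefficient, um^2/ms).
#' @export
species_table <- function(z_metabolites = NULL) {
  tab <- data.frame(
    name = c("Na", "K", "Ca", "Cl", "ATP", "ADP", "Cr", "CrP", "Pi"),
    z = c(1, 1, 2, -1, 0, 0, 0, 0, 0),
    # um^2/ms (table values are per second; see package vignette)
    D_cyto = c(665, 980, 300, 1015, 140, 140, 260, 240, 330) / 1000,
    stringsAsFactors = FALSE
  )
  if (!is.null(z_metabolites)) {
    idx <- match(names(z_metabolites), tab$name)
    if (anyNA(idx)) stop("unknown species in z_metabolites")
    tab$z[idx] <- z_metabolites
  }
  tab
}

#' Material and transport parameters of the triphasic mixture
#'
#' Defaults are the fitted/literature values of the source model's parameter
#' table: solid bulk modulus kappa_S = 25 kPa, permeability K = 700
#' um^4/mN/ms, truss conductance G = 1 um^3/MPa/ms, truss compliance
#' C = 100 x element lumen volume um^3/MPa, fluid volume fractions per
#' compartment (mitochondria 0.617, myofibril 0.787, SR 0.752, cytosol
#' 0.833, t-tubule 0.900), and an intra-t-tubular diffusion restriction of
#' 0.08 relative to cytosol.  The deviatoric shear modulus (10 kPa), osmotic
#' coefficient (0.9) and t-tubule radius (0.125 um) are implementation
#' choices (never stated at the source) and are configurable.
#'
#' @param kappa_S solid-phase bulk modulus, kPa.
#' @param shear_modulus deviatoric (neo-Hookean) shear modulus, kPa.
#' @param K_perm Darcy permeability in um^4/mN/ms (stored internally in
#'   um^2/(kPa ms); see Details).
#' @param phi_osm osmotic coefficient (dimensionless).
#' @param truss_G truss element fluid conductance, um^3/MPa/ms.
#' @param truss_C_per_vol truss compliance per unit lumen volume, 1/MPa.
#' @param ttubule_radius lumen radius, um.
#' @param restriction intra-t-tubular diffusion factor relative to cytosol.
#' @param D_extracellular_scale extracellular (free solution) diffusion
#'   relative to cytosol; 2 by the half-of-water convention.
#' @param C_F optional fixed-charge concentration (mM) per compartment; by
#'   default the simulator initialises nodal C^F from electroneutrality of
#'   the initial state.
#' @param species species table, see [species_table()].
#' @param constants physical constants, see [phys_constants()].
#' @param T_max_active maximal active tension, kPa (default 10; the source
#'   reports normalized force only, and this scale keeps reduced-mesh
#'   strains within the validity of trilinear kinematics).
#' @return list of class \code{tricell_params}.
#'
#' @details Unit conversions folded in here: pressure is kPa internally, so
#' the permeability 700 um^4/mN/ms becomes \code{700e-6} um^2/(kPa ms)
#' (1 kPa = 1e3 Pa = 1e-6 mN/um^2), truss conductance 1 um^3/MPa/ms becomes
#' \code{1e-3} um^3/(kPa ms) and the compliance 100/MPa becomes 0.1/kPa.
#' @export
material_params <- function(kappa_S = 25,
                            shear_modulus = 10,
                            K_perm = 700,
                            phi_osm = 0.9,
                            truss_G = 1.0,
                            truss_C_per_vol = 100,
                            ttubule_radius = 0.125,
                            restriction = 0.08,
                            D_extracellular_scale = 2,
                            C_F = NULL,
                            species = species_table(),
                            constants = phys_constants(),
                            T_max_active = 10) {
  stopifnot(kappa_S > 0, shear_modulus > 0, K_perm > 0,
            phi_osm > 0, phi_osm <= 1,
            truss_G > 0, truss_C_per_vol >= 0,
            ttubule_radius > 0, restriction > 0, restriction <= 1)
  phi_w <- c(myofibril = 0.787, mitochondria = 0.617, cytosol = 0.833,
             jsr = 0.752, nsr = 0.752, extracellular = 1.0)
  structure(list(
    kappa_S = kappa_S,
    shear_modulus = shear_modulus,
    K_perm = K_perm * 1e-6,          # um^2/(kPa ms)
    phi_osm = phi_osm,
    phi_w = phi_w,
    truss_G = truss_G * 1e-3,        # um^3/(kPa ms)
    truss_C_per_vol = truss_C_per_vol * 1e-3,  # 1/kPa per unit volume
    ttubule_radius = ttubule_radius,
    restriction = restriction,
    D_extracellular_scale = D_extracellular_scale,
    phi_w_ttubule = 0.900,
    C_F = C_F,
    species = species,
    constants = constants,
    T_max_active = T_max_active
  ), class = "tricell_params")
}

#' Restricted diffusion coefficients for the t-tubule lumen
#'
#' Applies the single fitted restriction factor (default 0.08 of the
#' cytosolic value, the value that reproduced solution-switch experiments)
#' to every species, returning lumen diffusion coefficients.
#'
#' @param params [material_params()] list.
#' @param restriction restriction factor in (0, 1]; defaults to the value
#'   stored in \code{params}.
#' @return named numeric vector of lumen diffusion coefficients (um^2/ms).
#' @export
restricted_diffusion_coeffs <- function(params, restriction = params$restriction) {
  stopifnot(restriction > 0, restriction <= 1)
  stats::setNames(params$species$D_cyto * restriction, params$species$name)
}
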