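## Reduced subcellular reaction surrogates supplying the f^alpha_subcell
## source terms: RyR calcium-induced calcium release from JSR units, SERCA
## uptake into a network-SR pool with first-order JSR refill, a rapid
## cytosolic Ca buffer, simplified mitochondrial uniporter / Na-Ca exchange,
## and Ca-driven active tension.  Rate constants are sized to give a
## diastolic free [Ca] of ~0.1 uM and local twitch peaks of order 1 uM.
## Everything lives behind the subcellular-source interface so a full
## ionic/metabolic reaction network can replace it.

#' Default parameters of the reduced subcellular reaction set
#'
#' @return list of rate constants and capacities; concentrations in mM,
#'   rates in 1/ms or mM/ms, volumes in um^3.
#' @export
subcell_params <- function() {
  list(
    ## RyR release unit
    ryr_K = 7e-4,          # mM, Ca trigger half-activation
    ryr_hill = 4,          # trigger cooperativity
    ryr_k_open = 1,        # 1/ms
    ryr_k_close = 0.12,    # 1/ms
    ryr_k_recover = 0.004, # 1/ms, refractory recovery
    dyad_gain = 1e-3,      # mM per A/F: junctional microdomain Ca per unit
                           # inward L-type current (sub-grid local control)
    g_rel = 0.5,           # 1/ms, release rate constant (store volume ref.)
    csq_capacity = 40,     # calsequestrin buffering: total/free Ca in JSR
    ## SR pump and stores
    serca_Vmax = 6e-4,     # mM/ms (cytosol-referenced)
    serca_K = 2.8e-4,      # mM
    serca_hill = 2,
    leak_rate = 5.7e-5,    # 1/ms (NSR->cytosol, concentration-driven)
    refill_rate = 0.08,    # 1/ms (NSR->JSR, store volume referenced)
    nsr_Ca0 = 1.2,         # mM, initial NSR free Ca
    jsr_Ca0 = 1.2,         # mM, initial JSR free Ca
    ## rapid cytosolic buffer
    buf_Bmax = 0.10,       # mM binding sites
    buf_K = 6e-4,          # mM
    ## mitochondria
    mito_V_uni = 2e-3,     # mM/ms
    mito_K_uni = 0.01,     # mM
    mito_V_ncx = 1.2e-5,   # mM/ms
    mito_K_ncx = 0.01,     # mM
    mito_Ca0 = 2e-4,       # mM
    ## crossbridge activation
    act_K = 6e-4,          # mM
    act_hill = 3,
    act_tau_on = 25,       # ms
    act_tau_off = 45,      # ms
    Ca0 = 1e-4             # mM diastolic free Ca
  )
}

## rapid-buffer factor: fraction of a total-Ca increment that stays free
buffer_beta <- function(Ca, sc) {
  1 / (1 + sc$buf_Bmax * sc$buf_K / (sc$buf_K + Ca)^2)
}

## buffer-bound Ca at free concentration Ca
buffer_bound <- function(Ca, sc) {
  sc$buf_Bmax * Ca / (sc$buf_K + Ca)
}

## total (free + bound) Ca at free concentration Ca
ca_total_of_free <- function(Ca, sc) {
  Ca + buffer_bound(Ca, sc)
}

## exact inverse of the rapid-buffer relation: free Ca for a given total
## (positive root of Ca^2 + Ca (K + Bmax - T) - K T = 0)
ca_free_of_total <- function(Tt, sc) {
  b <- sc$buf_K + sc$buf_Bmax - Tt
  (-b + sqrt(b * b + 4 * sc$buf_K * Tt)) / 2
}

#' RyR release flux of one or more JSR units
#'
#' Threshold-triggered, store-load-dependent release with refractory
#' closure.  The trigger is a Hill function of the local cytosolic free
#' [Ca]; open units release at a rate proportional to the JSR-cytosol Ca
#' difference, so an empty store releases nothing.
#'
#' @param Ca_local cytosolic free [Ca] at the unit, mM.
#' @param Ca_jsr JSR free [Ca], mM.
#' @param open RyR open fraction in [0,1].
#' @param sc [subcell_params()].
#' @return release flux in mM/ms referenced to the JSR store volume
#'   (positive = store to cytosol); multiply by the store's effective
#'   volume (lumen volume x csq_capacity) for amol/ms.
#' @export
ryr_release_flux <- function(Ca_local, Ca_jsr, open, sc = subcell_params()) {
  sc$g_rel * open * pmax(Ca_jsr - Ca_local, 0)
}

## RyR gating rates (d open / dt, d refractory / dt)
ryr_gating <- function(Ca_local, open, refr, sc) {
  H <- Ca_local^sc$ryr_hill / (Ca_local^sc$ryr_hill + sc$ryr_K^sc$ryr_hill)
  avail <- pmax(1 - open - refr, 0)
  list(do = sc$ryr_k_open * H * avail - sc$ryr_k_close * open,
       dw = sc$ryr_k_close * open - sc$ryr_k_recover * refr)
}

#' SERCA uptake and NSR-to-JSR refill fluxes
#'
#' Hill-type uptake from cytosol into the network SR plus a small
#' concentration-driven leak back, and first-order refill of JSR stores
#' from the NSR pool.
#'
#' @param Ca cytosolic free [Ca], mM (vector over nodes).
#' @param Ca_nsr NSR free [Ca], mM (scalar pool).
#' @param Ca_jsr JSR free [Ca] per unit, mM.
#' @param sc [subcell_params()].
#' @return list: \code{uptake} (mM/ms, cytosol-referenced, per node),
#'   \code{leak} (mM/ms, per node), \code{refill} (mM/ms, store-referenced,
#'   per unit).
#' @export
serca_and_refill <- function(Ca, Ca_nsr, Ca_jsr, sc = subcell_params()) {
  up <- sc$serca_Vmax * Ca^sc$serca_hill /
    (Ca^sc$serca_hill + sc$serca_K^sc$serca_hill)
  leak <- sc$leak_rate * pmax(Ca_nsr - Ca, 0)
  refill <- sc$refill_rate * (Ca_nsr - Ca_jsr)
  list(uptake = up, leak = leak, refill = refill)
}

#' Mitochondrial Ca exchange flux
#'
#' Uniporter influx rising steeply with cytosolic [Ca] and a
#' mito-Na/Ca-exchanger efflux saturating in matrix [Ca]; the combination
#' damps cytosolic transients (lower peaks) while sustaining resting [Ca]
#' near the balance point.
#'
#' @param Ca cytosolic free [Ca], mM.
#' @param Ca_mito matrix [Ca], mM.
#' @param sc [subcell_params()].
#' @return list with \code{uni} (influx, mM/ms cytosol-referenced) and
#'   \code{ncx} (efflux, mM/ms); net cytosolic source is \code{ncx - uni}.
#' @export
mito_ca_exchange <- function(Ca, Ca_mito, sc = subcell_params()) {
  uni <- sc$mito_V_uni * Ca^2 / (Ca^2 + sc$mito_K_uni^2)
  ncx <- sc$mito_V_ncx * Ca_mito / (Ca_mito + sc$mito_K_ncx)
  list(uni = uni, ncx = ncx)
}

#' Active tension from crossbridge activation
#'
#' First-order activation driven by a Hill function of the local free
#' [Ca]; tension is T_max times the activation, along the long (z) axis.
#' The activation lag makes the force peak follow the Ca peak.
#'
#' @param Ca local free [Ca], mM (per myofibril element).
#' @param act current activation in [0,1].
#' @param dt time step, ms.
#' @param sc [subcell_params()].
#' @param T_max maximal tension, kPa.
#' @return list \code{act} (updated activation), \code{tension} (kPa).
#' @export
active_stress <- function(Ca, act, dt, sc = subcell_params(), T_max = 30) {
  a_inf <- Ca^sc$act_hill / (Ca^sc$act_hill + sc$act_K^sc$act_hill)
  tau <- ifelse(a_inf > act, sc$act_tau_on, sc$act_tau_off)
  act <- a_inf + (act - a_inf) * exp(-dt / tau)
  list(act = act, tension = T_max * act)
}
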