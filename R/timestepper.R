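## Multirate operator splitting: mechanics (dt_mech), membrane/transport
## electrical steps (dt_elec) nested inside each mechanics step, and
## adaptive chemistry sub-steps nested inside each electrical step.
## Splitting order per coarse step: (1) electrical + chemical inner loop
## with frozen geometry and fluid velocities, (2) mechanics/fluid solve
## with the updated active stress and osmotic/electrical loads.

#' Multirate stepping configuration
#'
#' Defaults follow the source model: mechanics at 1 ms, electrical at
#' 1e-2 ms, chemistry adaptive between 1e-2 and 1e-5 ms.
#'
#' @param dt_mech mechanics step, ms.
#' @param dt_elec electrical step, ms (dt_mech must be a multiple).
#' @param dt_chem_max,dt_chem_min chemistry step bounds, ms.
#' @param rtol_chem relative tolerance of the chemistry error controller.
#' @param newton_tol,newton_max_iter Newton settings for the mechanics solve.
#' @param output_stride record observables every this many electrical steps.
#' @param refresh_every rebuild cadence (ms) of the lagged operator
#'   coefficients (potential system, convection); defaults to the
#'   mechanics step.  Single-rate reference runs set this to the multirate
#'   value so both runs carry the same coefficient lag.
#' @param debug_checks run in-line conservation checks at every accepted
#'   mechanics step (slower; used by the conservation test suite).
#' @return list of class \code{stepping_config}.
#' @export
stepping_config <- function(dt_mech = 1.0, dt_elec = 1e-2,
                            dt_chem_max = 1e-2, dt_chem_min = 1e-5,
                            rtol_chem = 2e-3,
                            newton_tol = 1e-9, newton_max_iter = 4,
                            output_stride = 100L,
                            refresh_every = NULL,
                            debug_checks = FALSE) {
  stopifnot(dt_mech >= dt_elec, dt_elec >= dt_chem_max,
            dt_chem_max >= dt_chem_min, dt_chem_min > 0)
  if (abs(dt_mech / dt_elec - round(dt_mech / dt_elec)) > 1e-9)
    stop("dt_mech must be an integer multiple of dt_elec")
  if (is.null(refresh_every)) refresh_every <- dt_mech
  structure(list(dt_mech = dt_mech, dt_elec = dt_elec,
                 dt_chem_max = dt_chem_max, dt_chem_min = dt_chem_min,
                 dt_chem = dt_chem_max, rtol_chem = rtol_chem,
                 newton_tol = newton_tol, newton_max_iter = newton_max_iter,
                 output_stride = as.integer(output_stride),
                 refresh_every = refresh_every,
                 debug_checks = debug_checks),
            class = "stepping_config")
}

## refresh the per-mechanics-interval caches: potential system (lagged
## concentrations) and convection operators (frozen fluid velocities)
refresh_cache <- function(model, state, dt_elec, clamp = NULL) {
  cache <- model$cache
  if (model$mode == "triphasic") {
    cache$psys <- psi_system_update(model, state, dt_elec, clamp)
    W <- state$W_elem
    cache$Cv_i <- if (!is.null(W) && any(W != 0))
      convection_operator(model$ts_i, model$mesh, W_elem = W) else NULL
    cache$Cv_e <- if (!is.null(state$w_truss) && length(state$w_truss) &&
                        any(state$w_truss != 0))
      convection_operator(model$ts_e, model$mesh, W_elem = NULL,
                          w_truss = state$w_truss) else NULL
    ## central-difference convection needs cell Peclet below 2
    if (!is.null(W) && length(W)) {
      pe <- max(abs(W)) * model$mesh$h / min(model$params$species$D_cyto)
      if (is.finite(pe) && pe >= 2)
        stop(sprintf("element Peclet number %.2f >= 2; refine dt/mesh", pe))
    }
  }
  invisible(cache)
}

## one electrical step (dt = dt_elec); returns state (+ step diagnostics in
## state$decomp when ctrl$track_decomposition)
elec_step <- function(model, state, dt, ctrl,
                      stim_fn = NULL, clamp = NULL, track = FALSE) {
  sp <- model$params$species
  D <- sp$D_cyto; z <- sp$z
  cfc <- model$params$constants$charge_flux
  memb <- model$memb
  idof <- memb$idof; edof <- memb$edof; area <- memb$area
  n_i <- model$ts_i$ndof; n_e <- model$ts_e$ndof

  V_old <- if (model$mode == "triphasic")
    state$Psi_i[idof] - state$Psi_e[edof] else rep(state$V_lumped, nrow(memb))

  cur <- compute_ionic_currents(state$gates, V_old,
                                state$Ci[idof, , drop = FALSE],
                                state$Ce[edof, , drop = FALSE],
                                model$density_scale, model$conductances,
                                model$params$constants)
  I_st <- if (is.null(stim_fn)) 0 else stim_fn(state$t)
  I_tot <- cur$I_total + I_st

  ## transport terms (amol/ms)
  Tdiff_i <- as.matrix(model$ts_i$K_base %*% state$Ci) * model$Drep_i
  Tdiff_e <- as.matrix(model$ts_e$K_base %*% state$Ce) * model$Drep_e
  cache <- model$cache
  conv_i <- if (!is.null(cache$Cv_i)) as.matrix(cache$Cv_i %*% state$Ci) else NULL
  conv_e <- if (!is.null(cache$Cv_e)) as.matrix(cache$Cv_e %*% state$Ce) else NULL

  Mig_i <- matrix(0, n_i, length(z)); Mig_e <- matrix(0, n_e, length(z))
  if (model$mode == "triphasic") {
    ps <- cache$psys
    b_i <- -as.vector(Tdiff_i %*% z)
    b_e <- -as.vector(Tdiff_e %*% z)
    if (!is.null(conv_i)) b_i <- b_i - as.vector(conv_i %*% z)
    if (!is.null(conv_e)) b_e <- b_e - as.vector(conv_e %*% z)
    b_i[idof] <- b_i[idof] - area * cfc * I_tot + ps$cc * V_old
    b_e[edof] <- b_e[edof] + area * cfc * I_tot - ps$cc * V_old
    Psi <- psi_solve(ps, c(b_i, b_e))
    state$Psi_i <- Psi[seq_len(n_i)]
    state$Psi_e <- Psi[n_i + seq_len(n_e)]
    for (a in ps$charged) {
      if (!is.null(ps$Amig_i[[a]]))
        Mig_i[, a] <- as.vector(ps$Amig_i[[a]] %*% state$Psi_i)
      if (!is.null(ps$Amig_e[[a]]))
        Mig_e[, a] <- as.vector(ps$Amig_e[[a]] %*% state$Psi_e)
    }
    V_new <- state$Psi_i[idof] - state$Psi_e[edof]
  } else {
    state$V_lumped <- state$V_lumped + lumped_potential_step(I_tot, area, dt)
    V_new <- rep(state$V_lumped, nrow(memb))
  }

  ## membrane species fluxes, amol/ms (positive into the compartment)
  Iw <- cur$I %*% model$stoich                       # n x species, A/F
  if (I_st != 0) Iw[, "K"] <- Iw[, "K"] + I_st
  q <- -(area * cfc) * Iw
  memb_i <- matrix(0, n_i, length(z)); memb_i[idof, ] <- q
  memb_e <- matrix(0, n_e, length(z)); memb_e[edof, ] <- -q

  rate_i <- -Tdiff_i - Mig_i + memb_i
  rate_e <- -Tdiff_e - Mig_e + memb_e
  if (!is.null(conv_i)) rate_i <- rate_i - conv_i
  if (!is.null(conv_e)) rate_e <- rate_e - conv_e

  if (isTRUE(ctrl$debug_checks) && model$mode == "triphasic") {
    ## transport electroneutrality: away from the membrane the charge rate
    ## of the update must vanish to linear-solver accuracy, relative to the
    ## charge-carrying terms that entered the solve
    rq <- as.vector(rate_i %*% z)
    interior <- setdiff(seq_len(n_i), idof)
    den <- max(abs(Tdiff_i %*% z)) + max(abs(Mig_i %*% z)) +
      max(abs(area * cfc * I_tot)) + 1e-12 * mean(model$ts_i$mass_phi)
    state$eln_max <- max(state$eln_max %||% 0,
                         max(abs(rq[interior])) / den)
  }

  dCi <- rate_i * (dt / model$ts_i$mass_phi)
  dCe <- rate_e * (dt / model$ts_e$mass_phi)
  ## rapid cytosolic Ca buffer: advance the total and invert exactly
  sc <- model$subcell
  ca_new <- ca_free_of_total(ca_total_of_free(state$Ci[, "Ca"], sc) +
                               dCi[, "Ca"], sc)
  state$Ci <- state$Ci + dCi
  state$Ci[, "Ca"] <- ca_new
  state$Ce <- state$Ce + dCe
  state$cum_memb <- state$cum_memb + colSums(q) * dt
  ## the advective form -(grad C).W is not discretely conservative; its net
  ## node-integrated source closes the species budget identity
  if (!is.null(conv_i))
    state$cum_adv <- state$cum_adv - colSums(conv_i) * dt

  ## bath Dirichlet values
  if (length(model$bath_edof)) {
    state$Ce[model$bath_edof, ] <- matrix(model$bath_C, length(model$bath_edof),
                                          length(z), byrow = TRUE)
  }

  state$gates <- gates_step(state$gates, V_new, dt)

  if (track) {
    dd <- colSums(abs(Tdiff_i))
    mm <- stats::setNames(colSums(abs(Mig_i)), names(dd))
    cc2 <- stats::setNames(
      if (!is.null(conv_i)) colSums(abs(conv_i)) else numeric(length(z)),
      names(dd))
    if (is.null(state$decomp))
      state$decomp <- list(diff = dd, mig = mm, conv = cc2,
                           int_diff = dd * dt, int_mig = mm * dt,
                           int_conv = cc2 * dt)
    else
      state$decomp <- list(diff = pmax(state$decomp$diff, dd),
                           mig = pmax(state$decomp$mig, mm),
                           conv = pmax(state$decomp$conv, cc2),
                           int_diff = state$decomp$int_diff + dd * dt,
                           int_mig = state$decomp$int_mig + mm * dt,
                           int_conv = state$decomp$int_conv + cc2 * dt)
  }

  state$I_last <- cur$I
  ch <- chem_advance(model, state, dt, ctrl)
  state <- ch$state
  ## release-time detection at full electrical resolution
  if (length(model$site_idof)) {
    hit <- is.na(state$release_t) &
      state$Ci[model$site_idof, "Ca"] > 2 * model$subcell$Ca0
    if (any(hit)) state$release_t[hit] <- state$t + dt
  }
  state$I_stim_last <- I_st
  state$V_memb <- V_new
  state$t <- state$t + dt
  attr(state, "ctrl") <- ch$ctrl
  state
}

#' Advance the coupled model through a time window
#'
#' Runs the multirate loop from the state's current time to \code{t_end}:
#' for each mechanics step, \code{dt_mech/dt_elec} electrical steps each
#' with nested adaptive chemistry; then the mechanics/fluid solve.  The
#' caller supplies protocol hooks (stimulus function, clamp constraints,
#' bath schedule) and an observer invoked on the output stride.
#'
#' @param model a \code{tricell_model} (mechanics initialised via
#'   \code{mech_init} unless \code{mechanics = FALSE}).
#' @param state initial state (defaults to \code{model$state}).
#' @param t_end end time, ms.
#' @param cfg [stepping_config()].
#' @param stim_fn function(t) -> stimulus current density (A/F), or NULL.
#' @param clamp voltage-clamp constraints ([apply_voltage_clamp()]), a
#'   function(t) returning them, or NULL.
#' @param bath_fn function(t) -> named bath concentrations (mM) or NULL.
#' @param mechanics logical; FALSE freezes geometry and fluid (pure
#'   electrodiffusion).
#' @param observer function(state) called on the output stride, or NULL.
#' @param mech mechanics system from \code{mech_init} (built on demand).
#' @return final state (with observer side effects).
#' @export
advance_cycle <- function(model, state = model$state, t_end,
                          cfg = stepping_config(),
                          stim_fn = NULL, clamp = NULL, bath_fn = NULL,
                          mechanics = TRUE, observer = NULL, mech = NULL) {
  if (mechanics && is.null(mech))
    mech <- mech_init(model, "isometric", cfg$dt_mech)
  if (!is.null(mech)) model$cache$mech <- mech
  ctrl <- cfg
  n_sub <- round(cfg$dt_mech / cfg$dt_elec)
  n_mech <- ceiling((t_end - state$t) / cfg$dt_mech - 1e-9)
  step_count <- 0L
  next_refresh <- -Inf
  for (k in seq_len(n_mech)) {
    cl <- if (is.function(clamp)) clamp(state$t) else clamp
    if (!is.null(bath_fn)) {
      bc <- bath_fn(state$t)
      if (!is.null(bc)) model$bath_C[names(bc)] <- bc
    }
    if (state$t >= next_refresh - 1e-12 || is.function(clamp) ||
        !is.null(bath_fn)) {
      refresh_cache(model, state, cfg$dt_elec, cl)
      next_refresh <- state$t + (cfg$refresh_every %||% cfg$dt_mech)
    }
    for (s in seq_len(n_sub)) {
      state <- elec_step(model, state, cfg$dt_elec, ctrl,
                         stim_fn = stim_fn, clamp = cl,
                         track = isTRUE(cfg$track_decomposition))
      ctrl <- attr(state, "ctrl")
      step_count <- step_count + 1L
      if (!is.null(observer) && step_count %% cfg$output_stride == 0L)
        observer(state)
    }
    if (mechanics) {
      ## activation of the crossbridges follows the element-mean free Ca
      if (length(model$myo_e)) {
        Ca_e <- as.vector(Matrix::crossprod(model$S_myo, state$Ci[, "Ca"]))
        as_ <- active_stress(Ca_e, state$act, cfg$dt_mech, model$subcell,
                             model$params$T_max_active)
        state$act <- as_$act
      }
      state <- mech_step(model, mech, state, n_newton = cfg$newton_max_iter)
    }
    if (isTRUE(cfg$debug_checks)) state <- conservation_checks(model, state)
  }
  state
}

## in-line conservation diagnostics at accepted mechanics steps: records the
## worst incompressibility residual seen so far (the electroneutrality of
## the transport update is tracked per electrical step in elec_step)
conservation_checks <- function(model, state) {
  if (!is.null(state$Qdiv)) {
    r <- incompressibility_residual(model, state)
    state$incomp_max <- max(state$incomp_max %||% 0, max(abs(r)))
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total calcium inventory of the model (bookkeeping)
#'
#' Sums free cytosolic Ca, rapid-buffer-bound Ca, JSR/NSR store content,
#' mitochondrial matrix content, extracellular Ca and the cumulative
#' transmembrane Ca transfer, in amol.  Constant in time up to solver
#' tolerance.
#'
#' @param model a \code{tricell_model}.
#' @param state a model state.
#' @return named numeric vector of pool sizes plus \code{total}.
#' @export
ca_inventory <- function(model, state) {
  m_i <- model$ts_i$mass_phi
  free <- sum(state$Ci[, "Ca"] * m_i)
  bound <- sum(buffer_bound(state$Ci[, "Ca"], model$subcell) * m_i)
  jsr <- sum(state$Ca_jsr * model$V_store)
  nsr <- state$Ca_nsr * model$V_nsr
  mito <- if (length(model$mito_e))
    sum(state$Ca_mito * model$ts_i$Ve *
          unname(model$params$phi_w["mitochondria"])) else 0
  extr <- sum(state$Ce[, "Ca"] * model$ts_e$mass_phi)
  c(free = free, bound = bound, jsr = jsr, nsr = nsr, mito = mito,
    extracellular = extr,
    total_intra = free + bound + jsr + nsr + mito,
    total = free + bound + jsr + nsr + mito + extr)
}
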