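## The assembled triphasic cell model: transport operators on both sides of
## the sarcolemma, membrane pairing, subcellular reaction maps and the
## electrical/chemical stepping kernel.
##
## Electrical sub-step (dt_elec): membrane ionic currents are evaluated
## explicitly; the electroneutrality condition is solved implicitly for the
## potential field (a sparse SPD system over all intra- and extracellular
## potential DOFs, coupled across the membrane by the capacitance term);
## species are then advanced explicitly with diffusion, convection and the
## migration flux computed from the fresh potential, which keeps the
## discrete nodal charge balance exact by construction.

#' Assemble a runnable triphasic cell model
#'
#' @param mesh a \code{tricell_mesh}.
#' @param params [material_params()].
#' @param mode \code{"triphasic"} (dual potentials, electromigration,
#'   convection) or \code{"rd"} (the reaction-diffusion limit: lumped
#'   membrane potential, no potential gradients, no convection).
#' @param density_ratios t-tubular:surface channel density ratios, see
#'   [channel_density_map()].
#' @param conductances ionic model conductances.
#' @param subcell [subcell_params()].
#' @param C_i0,C_e0 named initial concentrations (mM); defaults are
#'   guinea-pig resting values with a standard Tyrode bath.
#' @param V0 initial membrane potential, mV.
#' @param CF_i0,CF_e0 optional nodal fixed-charge vectors (mM), overriding
#'   the electroneutral initialisation.
#' @return list of class \code{tricell_model} with a ready initial state in
#'   \code{$state}.
#' @export
build_model <- function(mesh, params = material_params(),
                        mode = c("triphasic", "rd"),
                        density_ratios = c(I_Na = 2),
                        conductances = ionic_conductances(),
                        subcell = subcell_params(),
                        C_i0 = NULL, C_e0 = NULL, V0 = -85.8,
                        CF_i0 = NULL, CF_e0 = NULL) {
  mode <- match.arg(mode)
  sp <- params$species
  nsp <- nrow(sp)

  ts_i <- make_transport_side(mesh, params, "intra")
  ts_e <- make_transport_side(mesh, params, "extra")

  memb <- mesh$membrane
  npair <- nrow(memb)
  areas <- membrane_areas(mesh)
  dmap <- channel_density_map(density_ratios, areas["surface"], areas["t_tubular"])
  dens <- as.matrix(dmap[, c("surface", "t_tubular")])
  density_scale <- t(dens[, ifelse(memb$type == "surface", 1, 2), drop = FALSE])
  dimnames(density_scale) <- list(NULL, current_names)

  defaults_i <- c(Na = 10, K = 140, Ca = 1e-4, Cl = 20,
                  ATP = 7, ADP = 0.05, Cr = 15, CrP = 20, Pi = 3)
  defaults_e <- c(Na = 140, K = 5.4, Ca = 1.8, Cl = 126,
                  ATP = 1e-3, ADP = 1e-3, Cr = 1e-3, CrP = 1e-3, Pi = 1e-3)
  if (!is.null(C_i0)) defaults_i[names(C_i0)] <- C_i0
  if (!is.null(C_e0)) defaults_e[names(C_e0)] <- C_e0

  Ci <- matrix(rep(defaults_i[sp$name], each = ts_i$ndof), ts_i$ndof, nsp,
               dimnames = list(NULL, sp$name))
  Ce <- matrix(rep(defaults_e[sp$name], each = ts_e$ndof), ts_e$ndof, nsp,
               dimnames = list(NULL, sp$name))

  ## fixed charge from initial electroneutrality (configurable override)
  CF_i <- if (!is.null(CF_i0)) rep(CF_i0, length.out = ts_i$ndof) else
    if (is.null(params$C_F)) rep(-sum(sp$z * defaults_i[sp$name]), ts_i$ndof)
  else rep(params$C_F, length.out = ts_i$ndof)
  CF_e <- if (!is.null(CF_e0)) rep(CF_e0, length.out = ts_e$ndof) else
    rep(-sum(sp$z * defaults_e[sp$name]), ts_e$ndof)

  bath_edof <- mesh$extra_dof[mesh$boundary_tags$outer_bath]
  bath_edof <- bath_edof[!is.na(bath_edof)]

  ## ---- subcellular maps ---------------------------------------------------
  sites <- mesh$release_sites
  site_idof <- mesh$intra_dof[sites$gnode]
  site_pair <- match(sites$gnode, memb$gnode)      # NA for interior units
  V_store <- sites$vol_jsr * subcell$csq_capacity  # effective store volume

  intra_lab <- as.character(mesh$label[mesh$is_intra])
  intra_hex <- mesh$hex[mesh$is_intra, , drop = FALSE]
  mito_e <- which(intra_lab == "mitochondria")
  myo_e <- which(intra_lab == "myofibril")
  nsr_e <- which(intra_lab == "nsr")
  Ve <- mesh$h^3
  conn_i <- matrix(mesh$intra_dof[intra_hex], ncol = 8)

  elem2node <- function(eset) {
    if (!length(eset)) return(NULL)
    Matrix::sparseMatrix(i = as.vector(conn_i[eset, , drop = FALSE]),
                         j = rep(seq_along(eset), times = 8),
                         x = 1 / 8, dims = c(ts_i$ndof, length(eset)))
  }
  S_mito <- elem2node(mito_e)
  S_myo <- elem2node(myo_e)
  V_nsr <- max(length(nsr_e), 1) * Ve * unname(params$phi_w["nsr"])

  state <- list(
    t = 0,
    Ci = Ci, Ce = Ce,
    Psi_i = rep(if (mode == "triphasic") V0 else 0, ts_i$ndof),
    Psi_e = rep(0, ts_e$ndof),
    V_lumped = V0,
    gates = ionic_state_init(npair, V0),
    Ca_jsr = rep(subcell$jsr_Ca0, nrow(sites)),
    ryr_o = rep(0, nrow(sites)),
    ryr_w = rep(0, nrow(sites)),
    Ca_nsr = subcell$nsr_Ca0,
    Ca_mito = rep(subcell$mito_Ca0, length(mito_e)),
    act = rep(0, length(myo_e)),
    U = NULL, P = NULL, PT = NULL,   # mechanics, filled by mech_init
    Qdiv = NULL, W_elem = NULL, w_truss = NULL,
    cum_memb = stats::setNames(rep(0, nsp), sp$name),  # amol through membrane
    cum_adv = stats::setNames(rep(0, nsp), sp$name),   # net advective source
    cum_mouth = 0,                                      # um^3 through mouths
    release_t = rep(NA_real_, nrow(sites))              # first Ca crossing
  )

  model <- structure(list(
    mesh = mesh, params = params, mode = mode,
    ts_i = ts_i, ts_e = ts_e,
    memb = memb, density_scale = density_scale, conductances = conductances,
    bath_edof = bath_edof, bath_C = defaults_e[sp$name],
    CF_i = CF_i, CF_e = CF_e,
    subcell = subcell,
    site_idof = site_idof, site_pair = site_pair, V_store = V_store,
    mito_e = mito_e, myo_e = myo_e, S_mito = S_mito, S_myo = S_myo,
    V_nsr = V_nsr, conn_i = conn_i,
    stoich = current_stoichiometry(sp$name),
    Drep_i = matrix(rep(sp$D_cyto, each = ts_i$ndof), ts_i$ndof, nsp),
    Drep_e = matrix(rep(sp$D_cyto, each = ts_e$ndof), ts_e$ndof, nsp),
    state = state,
    cache = new.env(parent = emptyenv())
  ), class = "tricell_model")
  model
}

## ---- potential system ------------------------------------------------------

## (re)build the electroneutrality system for the current concentrations:
## L = sum_alpha z_alpha A_mig_alpha on both sides + capacitive pair
## coupling (area * charge_flux / dt); factor with Dirichlet elimination.
## Also stores the per-species migration operators for the flux updates.
psi_system_update <- function(model, state, dt, clamp = NULL) {
  p <- model$params; sp <- p$species
  n_i <- model$ts_i$ndof; n_e <- model$ts_e$ndof
  ntot <- n_i + n_e
  charged <- which(sp$z != 0)

  Amig_i <- Amig_e <- vector("list", nrow(sp))
  Li <- Le <- NULL
  for (a in charged) {
    Amig_i[[a]] <- migration_operator(model$ts_i, model$mesh, p, state$Ci[, a], a)
    Amig_e[[a]] <- migration_operator(model$ts_e, model$mesh, p, state$Ce[, a], a)
    Li <- if (is.null(Li)) sp$z[a] * Amig_i[[a]] else Li + sp$z[a] * Amig_i[[a]]
    Le <- if (is.null(Le)) sp$z[a] * Amig_e[[a]] else Le + sp$z[a] * Amig_e[[a]]
  }

  cf <- p$constants$charge_flux
  cc <- model$memb$area * cf / dt
  gi <- model$memb$idof; ge <- n_i + model$memb$edof
  A <- if (n_e > 0) Matrix::bdiag(Li, Le) else Li
  if (length(gi))
    A <- A + Matrix::sparseMatrix(i = c(gi, gi, ge, ge),
                                  j = c(gi, ge, gi, ge),
                                  x = c(cc, -cc, -cc, cc),
                                  dims = c(ntot, ntot))

  dir_dof <- n_i + model$bath_edof
  dir_val <- rep(0, length(dir_dof))
  if (!is.null(clamp) && !is.null(clamp$field_offset) &&
      clamp$field_offset != 0) {
    ## field stimulation: opposite outer planes held at +/- offset/2
    xb <- model$mesh$nodes[model$mesh$boundary_tags$outer_bath, 1]
    yb <- model$mesh$nodes[model$mesh$boundary_tags$outer_bath, 2]
    dir_val <- ifelse(xb >= yb, clamp$field_offset / 2, -clamp$field_offset / 2)
  }
  if (!is.null(clamp) && length(clamp$intra_dof)) {
    dir_dof <- c(dir_dof, clamp$intra_dof)
    dir_val <- c(dir_val, clamp$intra_val)
  }
  if (!length(dir_dof)) { dir_dof <- 1L; dir_val <- 0 }  # gauge pin
  free <- setdiff(seq_len(ntot), dir_dof)

  A <- methods::as(A, "CsparseMatrix")
  Aff <- A[free, free, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE, perm = TRUE)

  list(A = A, fac = fac, free = free, dir_dof = dir_dof, dir_val = dir_val,
       Amig_i = Amig_i, Amig_e = Amig_e, cc = cc, charged = charged)
}

## solve the potential system for given transport charge RHS
psi_solve <- function(ps, b) {
  x <- numeric(length(b))
  x[ps$dir_dof] <- ps$dir_val
  rhs <- b[ps$free] - as.vector(ps$A[ps$free, ps$dir_dof, drop = FALSE] %*% ps$dir_val)
  x[ps$free] <- as.vector(Matrix::solve(ps$fac, rhs))
  x
}

## ---- chemistry --------------------------------------------------------------

## pack/unpack the stiff reaction state advanced by the adaptive stepper
## the chemistry integrates TOTAL cytosolic Ca (free + rapid-buffer bound),
## which makes the Ca inventory conserve exactly; fluxes are evaluated at
## the free concentration via the closed-form inversion
chem_pack <- function(state, sc) {
  list(Ca = ca_total_of_free(state$Ci[, "Ca"], sc),
       Ca_jsr = state$Ca_jsr, o = state$ryr_o,
       w = state$ryr_w, Ca_nsr = state$Ca_nsr, Ca_mito = state$Ca_mito)
}

chem_unpack <- function(state, y, sc) {
  state$Ci[, "Ca"] <- ca_free_of_total(y$Ca, sc)
  state$Ca_jsr <- y$Ca_jsr; state$ryr_o <- pmin(pmax(y$o, 0), 1)
  state$ryr_w <- pmin(pmax(y$w, 0), 1)
  state$Ca_nsr <- y$Ca_nsr; state$Ca_mito <- y$Ca_mito
  state
}

## time derivative of the reaction state (vectorised); mass in amol, free
## cytosolic Ca subject to the rapid-buffer factor beta
chem_rhs <- function(model, y) {
  sc <- model$subcell
  m <- model$ts_i$mass_phi
  Ca_free <- ca_free_of_total(y$Ca, sc)
  dCa <- numeric(length(y$Ca))      # total-Ca rate per node, mM/ms

  ## SERCA uptake and SR leak act on every intracellular node
  sr <- serca_and_refill(Ca_free, y$Ca_nsr, y$Ca_jsr, sc)
  dCa <- dCa - sr$uptake + sr$leak
  dnsr <- (sum((sr$uptake - sr$leak) * m) -
             sum(sr$refill * model$V_store)) / model$V_nsr

  ## RyR release units; junctional units sense the bulk Ca plus the
  ## L-type microdomain elevation (sub-grid local control)
  Ca_loc <- Ca_free[model$site_idof]
  rel <- ryr_release_flux(Ca_loc, y$Ca_jsr, y$o, sc)       # store-referenced
  gat <- ryr_gating(Ca_loc + (y$dyad %||% 0), y$o, y$w, sc)
  djsr <- -rel + sr$refill
  q_rel <- rel * model$V_store                              # amol/ms
  dCa_rel <- numeric(length(dCa))
  agg <- rowsum(q_rel, model$site_idof)
  dCa_rel[as.integer(rownames(agg))] <- agg[, 1]
  dCa <- dCa + dCa_rel / m

  ## mitochondria (element-level, distributed to nodes)
  dmito <- NULL
  if (length(model$mito_e)) {
    phi_m <- unname(model$params$phi_w["mitochondria"])
    Ca_e <- as.vector(Matrix::crossprod(model$S_mito, Ca_free))  # element means
    mx <- mito_ca_exchange(Ca_e, y$Ca_mito, sc)
    net_e <- mx$ncx - mx$uni                                  # mM/ms to cytosol
    dCa <- dCa + as.vector(model$S_mito %*% (net_e * model$ts_i$Ve * phi_m)) / m
    dmito <- mx$uni - mx$ncx
  }

  list(Ca = dCa, Ca_jsr = djsr, o = gat$do, w = gat$dw,
       Ca_nsr = dnsr, Ca_mito = dmito)
}

## y + h * f elementwise over the packed lists
chem_axpy <- function(y, f, h) {
  for (nm in names(y)) if (!is.null(f[[nm]])) y[[nm]] <- y[[nm]] + h * f[[nm]]
  y
}

#' One adaptive chemistry sub-step
#'
#' Advances the stiff subcellular reaction state by an embedded
#' Euler/Heun pair with a proportional step-size controller (safety factor
#' 0.9, rejection halves the step, dt kept within the configured bounds).
#'
#' @param model a \code{tricell_model}.
#' @param y packed chemistry state (see source).
#' @param dt_try step to attempt, ms.
#' @param dt_min,dt_max step bounds, ms.
#' @param rtol,atol error tolerances.
#' @return list \code{y} (possibly unchanged), \code{dt_used},
#'   \code{dt_next}, \code{accepted}.
#' @export
adaptive_chemistry_step <- function(model, y, dt_try,
                                    dt_min = 1e-5, dt_max = 1e-2,
                                    rtol = 2e-3, atol = NULL) {
  if (is.null(atol))
    atol <- c(Ca = 2e-6, Ca_jsr = 1e-5, o = 1e-4, w = 1e-4,
              Ca_nsr = 1e-6, Ca_mito = 1e-7)   # Ca on the total scale
  f1 <- chem_rhs(model, y)
  y1 <- chem_axpy(y, f1, dt_try)                    # Euler
  f2 <- chem_rhs(model, y1)
  y2 <- chem_axpy(y, chem_axpy(f1, f2, 1), dt_try / 2)  # Heun
  err <- 0
  for (nm in names(y)) {
    if (!nm %in% names(atol)) next          # frozen inputs (dyad boost)
    if (is.null(y[[nm]]) || !length(y[[nm]])) next
    sc <- atol[[nm]] + rtol * abs(y2[[nm]])
    err <- max(err, max(abs(y2[[nm]] - y1[[nm]]) / sc))
  }
  if (!is.finite(err)) err <- 2
  accepted <- err <= 1 || dt_try <= dt_min * (1 + 1e-12)
  fac <- if (err > 0) 0.9 / sqrt(err) else 2
  dt_next <- min(max(dt_try * min(2, max(0.2, fac)), dt_min), dt_max)
  list(y = if (accepted) y2 else y, dt_used = if (accepted) dt_try else 0,
       dt_next = if (accepted) dt_next else max(dt_try / 2, dt_min),
       accepted = accepted, err = err)
}

## integrate chemistry across one electrical step [t, t+dt]
chem_advance <- function(model, state, dt, ctrl) {
  y <- chem_pack(state, model$subcell)
  ## junctional microdomain boost, frozen over the electrical step
  if (!is.null(state$I_last) && length(model$site_pair)) {
    b <- numeric(length(model$site_idof))
    ok <- !is.na(model$site_pair)
    b[ok] <- model$subcell$dyad_gain *
      pmax(-state$I_last[model$site_pair[ok], "I_CaL"], 0)
    y$dyad <- b
  }
  remaining <- dt
  dt_try <- min(ctrl$dt_chem, remaining)
  n_rej <- 0L
  while (remaining > 1e-12) {
    st <- adaptive_chemistry_step(model, y, min(dt_try, remaining),
                                  ctrl$dt_chem_min, ctrl$dt_chem_max,
                                  ctrl$rtol_chem)
    if (st$accepted) {
      y <- st$y
      remaining <- remaining - st$dt_used
    } else {
      n_rej <- n_rej + 1L
      if (n_rej > 200L)
        stop("chemistry step rejected below dt_chem_min; worst error ", st$err)
    }
    dt_try <- st$dt_next
  }
  ctrl$dt_chem <- dt_try
  state <- chem_unpack(state, y, model$subcell)
  list(state = state, ctrl = ctrl)
}
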