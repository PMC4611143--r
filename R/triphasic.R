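## Residual forms of the governing triphasic equations, exposed as testable
## operations.  The production stepper uses the same operators (assembled in
## operators.R / mechanics.R); these functions present the equations one at
## a time for verification against independent oracles.
##
## Sign conventions: residuals are written so that the physically stable
## transport results, i.e. concentration balance
##   Phi^w dC/dt + W . grad C - div[ D (grad C + z F/(R T) C grad Psi) ] - f = 0
## (diffusion smooths, fluid advects ions along W, f is a source), mixture
## momentum div Pi = 0 with Pi the first Piola-Kirchhoff stress including
## passive solid stress, fluid pressure and active tension, solid
## compressibility J - 1 + P_S/kappa_S = 0, and mixture incompressibility
## J - 1 + div Q^w = 0 (with the t-tubule compliance slack where a lumen is
## hosted).

#' Mixture momentum and solid-compressibility residuals
#'
#' Assembles the nodal residual of the mixture momentum balance for a
#' displacement/pressure state (compressible neo-Hookean solid, fluid
#' pressure, active tension along the long axis) together with the
#' element-wise solid compressibility residual J - 1 + P_S/kappa_S, where
#' P_S = -kappa_S (J - 1) is the constitutively consistent solid pressure
#' (so the compressibility residual vanishes identically unless P_S is
#' supplied explicitly).
#'
#' @param model a \code{tricell_model} with mechanics initialised.
#' @param mech mechanics system from \code{mech_init}.
#' @param U nodal displacement vector (3 per intracellular node), um.
#' @param P_w element fluid pressures, kPa.
#' @param T_a element active tensions, kPa.
#' @param P_S optional element solid pressures (default: consistent value).
#' @return list \code{momentum} (length 3 n), \code{compressibility}
#'   (length E), \code{J} (element mean volume change).
#' @export
mixture_momentum_residual <- function(model, mech, U,
                                      P_w = numeric(mech$E),
                                      T_a = numeric(mech$E),
                                      P_S = NULL) {
  p <- model$params
  f <- neo_internal_force(mech, model$ts_i$ref, U, P_w, T_a,
                          mech$mu, p$kappa_S)
  Jbar <- 1 + as.vector(Matrix::crossprod(mech$G, U)) / mech$Ve
  if (is.null(P_S)) P_S <- -p$kappa_S * (Jbar - 1)
  list(momentum = f, compressibility = Jbar - 1 + P_S / p$kappa_S, J = Jbar)
}

#' Fluid momentum (Darcy) residual
#'
#' Per-element residual of the fluid balance: W + K (grad P_w +
#' R T (1 - phi) grad C_total - C^F grad Psi) = 0; a state satisfying the
#' Darcy closure has residual zero.
#'
#' @param model a \code{tricell_model}.
#' @param mech mechanics system.
#' @param state model state carrying \code{W_elem}, \code{P}, \code{Ci},
#'   \code{Psi_i}.
#' @return E x 3 matrix of residuals, um/ms.
#' @export
fluid_momentum_residual <- function(model, mech, state) {
  dd <- darcy_drive(model, mech, state)
  state$W_elem - gradFV_pairs(mech, state$P, dd$Ct_e, dd$Ps_e, dd$CF_e,
                              model$params)
}

## shared FV gradient-based Darcy velocity (also used by mech_step's tail)
gradFV_pairs <- function(mech, P, Ct_e, Ps_e, CF_e, p) {
  E <- mech$E
  g3 <- function(v) {
    g <- matrix(0, E, 3); cnt <- matrix(0, E, 3)
    pr <- mech$pairs
    if (is.null(pr)) return(g)
    dvec <- cbind(mech$ijk[pr[, 2], 1] - mech$ijk[pr[, 1], 1],
                  mech$ijk[pr[, 2], 2] - mech$ijk[pr[, 1], 2],
                  mech$ijk[pr[, 2], 3] - mech$ijk[pr[, 1], 3])
    dd2 <- max.col(abs(dvec))
    df <- (v[pr[, 2]] - v[pr[, 1]]) / mech$h
    for (d in 1:3) {
      sel <- dd2 == d
      if (!any(sel)) next
      for (cidx in 1:2) {
        a1 <- rowsum(df[sel], pr[sel, cidx])
        g[as.integer(rownames(a1)), d] <- g[as.integer(rownames(a1)), d] + a1[, 1]
        c1 <- rowsum(rep(1, sum(sel)), pr[sel, cidx])
        cnt[as.integer(rownames(c1)), d] <- cnt[as.integer(rownames(c1)), d] + c1[, 1]
      }
    }
    g / pmax(cnt, 1)
  }
  RT1p <- p$constants$RT_kPa * (1 - p$phi_osm)
  -p$K_perm * (g3(P) + RT1p * g3(Ct_e) - CF_e * 0.096485 * g3(Ps_e))
}

#' Mixture incompressibility residual
#'
#' Element-wise residual of J - 1 + div Q^w, minus the compliance slack of
#' hosted t-tubule lumens (volume change of the mixture accommodated by
#' lumen dilation).
#'
#' @param model a \code{tricell_model} with mechanics state.
#' @param state model state (\code{U}, \code{Qdiv}, \code{PT}, \code{P}).
#' @return numeric vector over intracellular elements.
#' @export
incompressibility_residual <- function(model, state) {
  mech <- model$cache$mech
  if (is.null(mech)) stop("mechanics not initialised")
  Jm1 <- as.vector(Matrix::crossprod(mech$G, state$U)) / mech$Ve
  slack <- numeric(mech$E)
  if (mech$n_t > 0) {
    dp <- state$PT - state$P[mech$host]
    agg <- rowsum(mech$C_t[mech$t_int] * dp[mech$t_int], mech$host[mech$t_int])
    slack[as.integer(rownames(agg))] <- agg[, 1]
  }
  Jm1 + state$Qdiv - slack / mech$Ve
}

#' Ion balance residual
#'
#' Nodal residual (amol/ms) of the intracellular species balance for a
#' given concentration rate: M_phi dC/dt + K_D C + A_mig Psi + Conv C -
#' membrane - f.  With \code{dCdt} taken from an accepted step the residual
#' is zero to solver accuracy.
#'
#' @param model a \code{tricell_model}.
#' @param state model state.
#' @param dCdt matrix of concentration rates (nodes x species), mM/ms.
#' @param f_subcell matrix of subcellular sources (amol/ms) or NULL.
#' @param memb_flux matrix of membrane fluxes (amol/ms) or NULL.
#' @return nodes x species residual matrix, amol/ms.
#' @export
ion_balance_residual <- function(model, state, dCdt, f_subcell = NULL,
                                 memb_flux = NULL) {
  sp <- model$params$species
  Tdiff <- sweep(as.matrix(model$ts_i$K_base %*% state$Ci), 2, sp$D_cyto, "*")
  Mig <- matrix(0, model$ts_i$ndof, nrow(sp))
  for (a in which(sp$z != 0)) {
    Am <- migration_operator(model$ts_i, model$mesh, model$params,
                             state$Ci[, a], a)
    if (!is.null(Am)) Mig[, a] <- as.vector(Am %*% state$Psi_i)
  }
  conv <- if (!is.null(model$cache$Cv_i))
    as.matrix(model$cache$Cv_i %*% state$Ci) else 0
  r <- dCdt * model$ts_i$mass_phi + Tdiff + Mig + conv
  if (!is.null(memb_flux)) r <- r - memb_flux
  if (!is.null(f_subcell)) r <- r - f_subcell
  r
}

#' Electroneutrality residual
#'
#' Nodal residual of the electroneutrality condition
#' sum_alpha z_alpha dC_alpha/dt + dC^F/dt = 0 (amol/ms of charge).
#'
#' @param model a \code{tricell_model}.
#' @param dCdt nodes x species concentration-rate matrix, mM/ms.
#' @param dCFdt fixed-charge rate (mM/ms), default 0.
#' @return numeric vector over intracellular nodes.
#' @export
electroneutrality_residual <- function(model, dCdt, dCFdt = 0) {
  z <- model$params$species$z
  (as.vector(dCdt %*% z) + dCFdt) * model$ts_i$mass_phi
}

#' Generic Newton solve on a residual closure
#'
#' Damped Newton iteration with a user Jacobian (constant matrix, function,
#' or NULL for a finite-difference Jacobian on small systems).  Reports the
#' iteration count; raises on divergence with the best residual norm and
#' the worst degree of freedom.
#'
#' @param residual_fn function(x) -> residual vector.
#' @param x0 initial guess.
#' @param jacobian constant matrix, function(x) -> matrix, or NULL.
#' @param tol infinity-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return list \code{x}, \code{iterations}, \code{residual_norm}.
#' @export
newton_solve <- function(residual_fn, x0, jacobian = NULL,
                         tol = 1e-10, max_iter = 25) {
  x <- x0
  fd_jac <- function(x) {
    r0 <- residual_fn(x)
    n <- length(x); m <- length(r0)
    J <- matrix(0, m, n)
    hstep <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- xp[j] + hstep[j]
      J[, j] <- (residual_fn(xp) - r0) / hstep[j]
    }
    J
  }
  best <- Inf
  for (it in 0:max_iter) {
    r <- residual_fn(x)
    nrm <- max(abs(r))
    best <- min(best, nrm)
    if (nrm < tol)
      return(list(x = x, iterations = it, residual_norm = nrm))
    if (it == max_iter) break
    J <- if (is.null(jacobian)) fd_jac(x)
    else if (is.function(jacobian)) jacobian(x)
    else jacobian
    dx <- as.vector(Matrix::solve(J, -r))
    ## simple backtracking damping
    lam <- 1
    repeat {
      xn <- x + lam * dx
      rn <- tryCatch(max(abs(residual_fn(xn))), error = function(e) Inf)
      if (rn < nrm || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- x + lam * dx
  }
  stop(sprintf(
    "Newton did not converge in %d iterations; best residual %.3g, worst DOF %d",
    max_iter, best, which.max(abs(residual_fn(x)))))
}
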