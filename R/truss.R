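## Simplified triphasic truss elements for the t-tubule network: lumen flow
## driven by nodal pressure differences, compliant dilation against the
## surrounding mixture, open-end exchange with the extracellular bath, and
## restricted intra-lumen diffusion (handled inside the transport
## operators).  These functions expose the elementary relations; the
## coupled system is assembled in mech_init / mech_step.

#' Fluid flow through a truss element
#'
#' Flow from node j to node i, W_(j->i) = G (p_j - p_i); antisymmetric in
#' its arguments.
#'
#' @param p_j,p_i nodal pressures, kPa.
#' @param G element conductance, um^3/(kPa ms).
#' @return volumetric flow, um^3/ms.
#' @export
truss_flow <- function(p_j, p_i, G = material_params()$truss_G) {
  G * (p_j - p_i)
}

#' Assemble the conductance Laplacian of a truss network
#'
#' @param elems data.frame with integer columns \code{a}, \code{b}.
#' @param G conductance per element (scalar or vector), um^3/(kPa ms).
#' @param n number of nodes.
#' @return sparse n x n matrix L with (L p)_i = sum_j G (p_i - p_j).
#' @export
truss_network_matrix <- function(elems, G, n) {
  G <- rep(G, length.out = nrow(elems))
  Matrix::sparseMatrix(
    i = c(elems$a, elems$b, elems$a, elems$b),
    j = c(elems$a, elems$b, elems$b, elems$a),
    x = c(G, G, -G, -G), dims = c(n, n))
}

#' Nodal fluid-conservation residual of a truss network
#'
#' At a rigid interior node the net inflow sum_j G (p_j - p_i) must vanish;
#' with wall compliance C_t the residual is the imbalance between net
#' inflow and compliant storage C_t d(p_i - p_host)/dt.
#'
#' @param elems truss element table (columns a, b).
#' @param p nodal lumen pressures, kPa.
#' @param G conductance, um^3/(kPa ms).
#' @param C_t nodal compliance, um^3/kPa (default 0 = rigid).
#' @param ddp_dt rate of the wall pressure difference, kPa/ms (default 0).
#' @return residual per node, um^3/ms (zero at conservation).
#' @export
interior_node_conservation <- function(elems, p, G, C_t = 0, ddp_dt = 0) {
  n <- length(p)
  L <- truss_network_matrix(elems, G, n)
  -as.vector(L %*% p) - C_t * ddp_dt
}

#' Open-end (mouth) fluid exchange bookkeeping
#'
#' The fluid budget at the t-tubule mouths: the time-integrated mouth
#' outflow must equal the net volume released by the cell (mixture volume
#' change plus lumen storage), so their sum over a closed cycle returns to
#' zero.  Returns the components from a simulated state.
#'
#' @param model a \code{tricell_model} with mechanics state.
#' @param state model state after stepping.
#' @return named numeric: \code{mouth_outflow_integral} (um^3),
#'   \code{lumen_storage} (um^3, sum of C_t * (p_t - P_host)),
#'   \code{mixture_volume_change} (um^3, integral of div Q^w over the cell).
#' @export
open_end_coupling <- function(model, state) {
  mech <- model$cache$mech
  if (is.null(mech)) stop("mechanics not initialised")
  storage <- if (mech$n_t > 0)
    sum(mech$C_t[mech$t_int] * state$dp_old[mech$t_int]) else 0
  c(mouth_outflow_integral = state$cum_mouth,
    lumen_storage = storage,
    mixture_volume_change = sum(state$Qdiv) * mech$Ve)
}
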