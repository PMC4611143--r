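## Quasi-static poroelastic mechanics of the mixture with the t-tubule
## truss fluid network.
##
## Unknowns per mechanics step: nodal solid displacement u (trilinear),
## element-constant fluid pressure P_w (stabilised mixed pair with a
## finite-volume Darcy coupling between neighbouring elements), and truss
## lumen pressures p_t.  The solid is compressible neo-Hookean
## (psi = mu/2 (I1 - 3) - mu ln J + kappa_S/2 (J-1)^2, so the solid
## pressure P_S = -kappa_S (J-1) satisfies the compressibility condition by
## construction); the production solver is a modified Newton iteration with
## the constant small-strain tangent, exact to round-off at twitch strains.
## Osmotic (RT (1-phi) grad C_total) and electrical (C^F grad Psi) driving
## forces enter the Darcy fluxes explicitly.

## 6x6 isotropic elasticity matrix (Voigt, engineering shear)
elastic_D <- function(lambda, mu) {
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  D
}

## reference 24x24 stiffness, 24-vector divergence coupling and z-active
## vector for the unit hex of edge h
hex_mech_reference <- function(ref, lambda, mu) {
  Ke <- matrix(0, 24, 24)
  ge <- numeric(24)
  az <- numeric(24)
  D <- elastic_D(lambda, mu)
  for (q in 1:8) {
    dN <- ref$dN_gp[q, , ]          # 8 x 3
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]; B[2, c0 + 2] <- dN[a, 2]; B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    Ke <- Ke + t(B) %*% D %*% B * ref$detJ
    for (a in 1:8) {
      ge[3 * (a - 1) + 1:3] <- ge[3 * (a - 1) + 1:3] + dN[a, ] * ref$detJ
      az[3 * (a - 1) + 3] <- az[3 * (a - 1) + 3] + dN[a, 3] * ref$detJ
    }
  }
  list(Ke = Ke, ge = ge, az = az)
}

## initialise the mechanics subsystem; bc_mode: isometric, free or rigid
## (rigid = displacement suppressed entirely, used by clamp protocols)
mech_init <- function(model, bc_mode = c("isometric", "free", "rigid"),
                      dt_mech = 1.0) {
  bc_mode <- match.arg(bc_mode)
  mesh <- model$mesh; p <- model$params
  ref <- model$ts_i$ref
  mu <- p$shear_modulus
  lambda <- p$kappa_S - 2 * mu / 3
  mref <- hex_mech_reference(ref, lambda, mu)

  conn <- model$conn_i                       # E x 8 intra dofs
  E <- nrow(conn); n_i <- model$ts_i$ndof
  Ve <- mesh$h^3; h <- mesh$h
  nU <- 3 * n_i

  udof <- function(nodes, d) 3 * (nodes - 1) + d
  conn_u <- matrix(0L, E, 24)
  for (a in 1:8) conn_u[, 3 * (a - 1) + 1:3] <- cbind(udof(conn[, a], 1),
                                                      udof(conn[, a], 2),
                                                      udof(conn[, a], 3))

  ## K_uu
  ii <- conn_u[, rep(1:24, times = 24), drop = FALSE]
  jj <- conn_u[, rep(1:24, each = 24), drop = FALSE]
  K <- Matrix::sparseMatrix(i = as.vector(t(ii)), j = as.vector(t(jj)),
                            x = rep(as.vector(mref$Ke), E), dims = c(nU, nU))
  ## G coupling (nU x E)
  G <- Matrix::sparseMatrix(i = as.vector(t(conn_u)),
                            j = rep(seq_len(E), each = 24),
                            x = rep(mref$ge, E), dims = c(nU, E))

  ## FV neighbour pairs among intracellular elements
  ijk <- mesh$cell_ijk[mesh$is_intra, , drop = FALSE]
  key <- ijk[, 1] + 1e3 * ijk[, 2] + 1e6 * ijk[, 3]
  lookup <- stats::setNames(seq_len(E), key)
  pairs <- NULL
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb_key <- (ijk[, 1] + d[1]) + 1e3 * (ijk[, 2] + d[2]) + 1e6 * (ijk[, 3] + d[3])
    hit <- lookup[as.character(nb_key)]
    ok <- !is.na(hit)
    pairs <- rbind(pairs, cbind(which(ok), unname(hit[ok])))
  }
  Tface <- p$K_perm * h                      # um^3/(kPa ms) per face
  T_lap <- Matrix::sparseMatrix(
    i = c(pairs[, 1], pairs[, 2], pairs[, 1], pairs[, 2]),
    j = c(pairs[, 1], pairs[, 2], pairs[, 2], pairs[, 1]),
    x = c(rep(Tface, 2 * nrow(pairs)), rep(-Tface, 2 * nrow(pairs))),
    dims = c(E, E))

  ## truss hosting: interior (non-mouth) truss nodes attach to an adjacent
  ## intracellular element of the z-line layer
  tr <- mesh$truss
  n_t <- nrow(tr$nodes)
  host <- integer(0); C_t <- numeric(0); t_int <- integer(0)
  G_t <- NULL
  if (n_t > 0) {
    ## nodal lumen volume = half the volume of adjacent truss elements
    vol_n <- numeric(n_t)
    for (e in seq_len(nrow(tr$elems))) {
      vol_n[tr$elems$a[e]] <- vol_n[tr$elems$a[e]] + tr$elems$lumen_vol[e] / 2
      vol_n[tr$elems$b[e]] <- vol_n[tr$elems$b[e]] + tr$elems$lumen_vol[e] / 2
    }
    C_all <- p$truss_C_per_vol * vol_n       # um^3/kPa per node
    t_int <- which(!tr$nodes$mouth)
    nx <- mesh$dims["nx"]; ny <- mesh$dims["ny"]
    ei <- pmin(pmax(round(tr$nodes$x / h) - 1, 0), nx - 1)
    ej <- pmin(pmax(round(tr$nodes$y / h) - 1, 0), ny - 1)
    ekey <- ei + 1e3 * ej
    host_all <- unname(lookup[as.character(ekey)])
    host <- host_all
    C_t <- C_all
    gcon <- p$truss_G                        # um^3/(kPa ms)
    G_t <- Matrix::sparseMatrix(
      i = c(tr$elems$a, tr$elems$b, tr$elems$a, tr$elems$b),
      j = c(tr$elems$a, tr$elems$b, tr$elems$b, tr$elems$a),
      x = c(rep(gcon, 2 * nrow(tr$elems)), rep(-gcon, 2 * nrow(tr$elems))),
      dims = c(n_t, n_t))
  }

  ## global saddle matrix over [U; P; PT]
  ntot <- nU + E + n_t
  iP <- nU + seq_len(E); iT <- nU + E + seq_len(n_t)
  Cdiag_e <- numeric(E)
  Cmap <- NULL
  if (n_t > 0) {
    agg <- rowsum(C_t[t_int], host[t_int])
    Cdiag_e[as.integer(rownames(agg))] <- agg[, 1]
    Cmap <- Matrix::sparseMatrix(i = host[t_int], j = t_int,
                                 x = C_t[t_int], dims = c(E, n_t))
  }
  blocks <- list(
    list(K, 0L, 0L), list(-G, 0L, nU), list(-Matrix::t(G), nU, 0L),
    list(-(dt_mech * T_lap + Matrix::Diagonal(E, Cdiag_e)), nU, nU))
  if (n_t > 0) {
    blocks <- c(blocks, list(
      list(Cmap, nU, nU + E), list(Matrix::t(Cmap), nU + E, nU),
      list(-(Matrix::Diagonal(n_t, C_t) + dt_mech * G_t), nU + E, nU + E)))
  }
  tl <- lapply(blocks, function(b) {
    m <- methods::as(methods::as(b[[1]], "CsparseMatrix"), "TsparseMatrix")
    cbind(m@i + 1L + b[[2]], m@j + 1L + b[[3]], m@x)
  })
  tl <- do.call(rbind, tl)
  A <- Matrix::sparseMatrix(i = tl[, 1], j = tl[, 2], x = tl[, 3],
                            dims = c(ntot, ntot))

  ## boundary conditions
  nd <- mesh$nodes[mesh$intra_nodes, , drop = FALSE]
  tol <- 1e-9
  fixed <- c(udof(which(nd[, 1] < tol), 1),
             udof(which(nd[, 2] < tol), 2),
             udof(which(nd[, 3] < tol), 3))
  mline <- which(abs(nd[, 3] - mesh$L["Lz"]) < tol)
  master_map <- seq_len(ntot)
  if (bc_mode == "isometric") {
    fixed <- c(fixed, udof(mline, 3))
  } else if (bc_mode == "free") {
    ## workless planar constraint: all m-line axial displacements share one
    ## master DOF (a Lagrange-multiplier-free realisation of the prescribed
    ## planar motion)
    mz <- udof(mline, 3)
    master_map[mz] <- mz[1]
  } else {
    fixed <- seq_len(nU)
  }
  if (n_t > 0) fixed <- c(fixed, iT[tr$nodes$mouth])  # mouths at bath pressure

  ## condense the master map, then eliminate fixed DOFs
  keep <- sort(setdiff(unique(master_map), fixed))
  red_id <- match(master_map, keep)           # NA for fixed
  Tm <- Matrix::sparseMatrix(i = which(!is.na(red_id)),
                             j = red_id[!is.na(red_id)], x = 1,
                             dims = c(ntot, length(keep)))
  A_red <- Matrix::t(Tm) %*% A %*% Tm
  ## rigid mode leaves only the (singular) pure-Neumann pressure block; it
  ## is used for residual evaluation, never solved
  fac <- if (bc_mode == "rigid") NULL else
    Matrix::lu(methods::as(A_red, "CsparseMatrix"))

  list(bc_mode = bc_mode, dt = dt_mech, mref = mref, conn_u = conn_u,
       K = K, G = G, T_lap = T_lap, G_t = G_t, Cmap = Cmap, C_t = C_t,
       host = host, t_int = t_int, Cdiag_e = Cdiag_e,
       nU = nU, E = E, n_t = n_t, ntot = ntot, iP = iP, iT = iT,
       Tm = Tm, fac = fac, pairs = pairs, Tface = Tface,
       ijk = ijk, lookup = lookup, Ve = Ve, h = h,
       az = mref$az, lambda = lambda, mu = mu)
}

## per-element mean of a nodal intracellular field
elem_mean <- function(model, v) {
  rowMeans(matrix(v[model$conn_i], ncol = 8))
}

## minimum Jacobian determinant over elements/quadrature points (cheap
## inversion guard for the line search)
min_J <- function(mech, ref, U) {
  Ue <- matrix(U[t(mech$conn_u)], nrow = 24)
  Jmin <- Inf
  for (q in 1:8) {
    dN <- ref$dN_gp[q, , ]
    Fq <- matrix(0, mech$E, 9)
    for (d in 1:3) for (k in 1:3) {
      rows <- 3 * (0:7) + d
      Fq[, d + 3 * (k - 1)] <- colSums(Ue[rows, , drop = FALSE] * dN[, k]) +
        as.numeric(d == k)
    }
    J <- Fq[, 1] * (Fq[, 5] * Fq[, 9] - Fq[, 8] * Fq[, 6]) -
      Fq[, 4] * (Fq[, 2] * Fq[, 9] - Fq[, 8] * Fq[, 3]) +
      Fq[, 7] * (Fq[, 2] * Fq[, 6] - Fq[, 5] * Fq[, 3])
    Jmin <- min(Jmin, min(J))
  }
  Jmin
}

## vectorised neo-Hookean internal force over intracellular elements
## (includes the pressure term -P_w J F^-T and active tension along z)
neo_internal_force <- function(mech, ref, U, P_w, T_a, mu, kappa) {
  E <- mech$E
  Ue <- matrix(U[t(mech$conn_u)], nrow = 24)  # 24 x E (x1,y1,z1,x2,...)
  f <- matrix(0, 24, E)
  Jmin <- Inf; jarg <- NA
  for (q in 1:8) {
    dN <- ref$dN_gp[q, , ]                    # 8 x 3
    ## deformation gradient per element: F = I + sum_a u_a (dN_a)^T
    Fq <- matrix(0, E, 9)                     # column-major 3x3
    for (d in 1:3) for (k in 1:3) {
      rows <- 3 * (0:7) + d
      Fq[, d + 3 * (k - 1)] <- colSums(Ue[rows, , drop = FALSE] * dN[, k]) +
        as.numeric(d == k)
    }
    F11 <- Fq[, 1]; F21 <- Fq[, 2]; F31 <- Fq[, 3]
    F12 <- Fq[, 4]; F22 <- Fq[, 5]; F32 <- Fq[, 6]
    F13 <- Fq[, 7]; F23 <- Fq[, 8]; F33 <- Fq[, 9]
    co11 <- F22 * F33 - F23 * F32; co12 <- F23 * F31 - F21 * F33
    co13 <- F21 * F32 - F22 * F31
    co21 <- F13 * F32 - F12 * F33; co22 <- F11 * F33 - F13 * F31
    co23 <- F12 * F31 - F11 * F32
    co31 <- F12 * F23 - F13 * F22; co32 <- F13 * F21 - F11 * F23
    co33 <- F11 * F22 - F12 * F21
    J <- F11 * co11 + F12 * co12 + F13 * co13
    if (min(J) <= 0 && min(J) < Jmin) { Jmin <- min(J); jarg <- which.min(J) }
    ## P = mu F + (kappa (J-1) J - mu) F^-T, with J F^-T = cof(F) and
    ## cof(F)[i,j] = dJ/dF[i,j] = co[i,j] as built above
    cf <- (kappa * (J - 1) * J - mu) / J
    P11 <- mu * F11 + cf * co11; P12 <- mu * F12 + cf * co12
    P13 <- mu * F13 + cf * co13
    P21 <- mu * F21 + cf * co21; P22 <- mu * F22 + cf * co22
    P23 <- mu * F23 + cf * co23
    P31 <- mu * F31 + cf * co31; P32 <- mu * F32 + cf * co32
    P33 <- mu * F33 + cf * co33
    ## fluid pressure: -P_w J F^-T = -P_w cof(F)
    P11 <- P11 - P_w * co11; P12 <- P12 - P_w * co12; P13 <- P13 - P_w * co13
    P21 <- P21 - P_w * co21; P22 <- P22 - P_w * co22; P23 <- P23 - P_w * co23
    P31 <- P31 - P_w * co31; P32 <- P32 - P_w * co32; P33 <- P33 - P_w * co33
    ## active tension along the deformed fiber: T_a (F e_z) (e_z)^T
    P13 <- P13 + T_a * F13; P23 <- P23 + T_a * F23; P33 <- P33 + T_a * F33
    ## nodal forces: f[a,d] += sum_k P[d,k] dN[a,k] * detJ
    for (a in 1:8) {
      w <- dN[a, ] * ref$detJ
      f[3 * (a - 1) + 1, ] <- f[3 * (a - 1) + 1, ] +
        P11 * w[1] + P12 * w[2] + P13 * w[3]
      f[3 * (a - 1) + 2, ] <- f[3 * (a - 1) + 2, ] +
        P21 * w[1] + P22 * w[2] + P23 * w[3]
      f[3 * (a - 1) + 3, ] <- f[3 * (a - 1) + 3, ] +
        P31 * w[1] + P32 * w[2] + P33 * w[3]
    }
  }
  if (is.finite(Jmin) && Jmin <= 0)
    stop(sprintf("element inversion: J = %.3g in element %d", Jmin, jarg))
  fv <- numeric(mech$nU)
  agg <- rowsum(as.vector(f), as.vector(t(mech$conn_u)))
  fv[as.integer(rownames(agg))] <- agg[, 1]
  fv
}

## osmotic + electrical inter-element Darcy driving, um^3/ms outflow per
## element (explicit), plus element Darcy velocity recovery
darcy_drive <- function(model, mech, state) {
  p <- model$params
  RT1p <- p$constants$RT_kPa * (1 - p$phi_osm)
  Ct_e <- elem_mean(model, rowSums(state$Ci))
  Ps_e <- elem_mean(model, state$Psi_i)
  CF_e <- elem_mean(model, model$CF_i)
  pr <- mech$pairs
  drive <- numeric(mech$E)
  if (!is.null(pr)) {
    d_os <- RT1p * (Ct_e[pr[, 1]] - Ct_e[pr[, 2]])
    ## C^F grad Psi converted to a pressure difference:
    ## 1 mM * 1 mV * F = 96.485 Pa = 0.096485 kPa
    d_el <- 0.5 * (CF_e[pr[, 1]] + CF_e[pr[, 2]]) *
      (Ps_e[pr[, 1]] - Ps_e[pr[, 2]]) * 0.096485
    q <- mech$Tface * (d_os - d_el)
    drive_agg <- rowsum(c(q, -q), c(pr[, 1], pr[, 2]))
    drive[as.integer(rownames(drive_agg))] <- drive_agg[, 1]
  }
  list(drive = drive, Ct_e = Ct_e, Ps_e = Ps_e, CF_e = CF_e)
}

## advance mechanics + fluid by one dt_mech; returns updated state
mech_step <- function(model, mech, state, n_newton = 2) {
  if (is.null(mech$fac)) stop("mechanics system not solvable in rigid mode")
  p <- model$params
  E <- mech$E; nU <- mech$nU; n_t <- mech$n_t
  if (is.null(state$U)) {
    state$U <- numeric(nU); state$P <- numeric(E); state$PT <- numeric(n_t)
    state$Qdiv <- numeric(E); state$dp_old <- numeric(n_t)
    state$W_elem <- matrix(0, E, 3); state$w_truss <- numeric(0)
  }
  ## active tension per intracellular element
  T_a <- numeric(E)
  if (length(model$myo_e))
    T_a[model$myo_e] <- p$T_max_active * state$act

  dd <- darcy_drive(model, mech, state)
  dt <- mech$dt
  x <- c(state$U, state$P, state$PT)
  for (it in seq_len(n_newton)) {
    U <- x[1:nU]; P <- x[mech$iP]; PT <- if (n_t > 0) x[mech$iT] else numeric(0)
    fint <- neo_internal_force(mech, model$ts_i$ref, U, P, T_a,
                               mech$mu, p$kappa_S)
    ## residual of the full system (same arrangement as the matrix)
    R <- numeric(mech$ntot)
    R[1:nU] <- fint
    divu <- as.vector(Matrix::crossprod(mech$G, U))
    out_p <- as.vector(mech$T_lap %*% P)
    R[mech$iP] <- -(divu + state$Qdiv * mech$Ve + dt * (out_p + dd$drive))
    if (n_t > 0) {
      dp <- PT - P[mech$host]
      R[mech$iP] <- R[mech$iP] + {
        v <- numeric(E)
        agg <- rowsum(mech$C_t[mech$t_int] * dp[mech$t_int],
                      mech$host[mech$t_int])
        v[as.integer(rownames(agg))] <- agg[, 1]
        v
      }
      net_in <- as.vector(mech$G_t %*% PT)   # = sum_j G (pt_i - pt_j)
      rT <- -(mech$C_t * (dp - state$dp_old) + dt * net_in)
      rT[model$mesh$truss$nodes$mouth] <- 0
      R[mech$iT] <- rT
    }
    Rr <- as.vector(Matrix::crossprod(mech$Tm, R))
    if (max(abs(Rr)) < 1e-11) break
    dx <- as.vector(mech$Tm %*%
                      as.vector(Matrix::solve(mech$fac, -Rr)))
    ## full modified-Newton steps (the mass/truss rows are linear and close
    ## exactly at lam = 1); backtrack only if a step inverts an element
    lam <- 1
    while (min_J(mech, model$ts_i$ref, (x + lam * dx)[1:nU]) <= 0 &&
             lam >= 1 / 64) {
      lam <- lam / 2
    }
    x <- x + lam * dx
    if (max(abs(lam * dx)) < 1e-12) break
  }

  U <- x[1:nU]; P <- x[mech$iP]; PT <- if (n_t > 0) x[mech$iT] else numeric(0)
  out_p <- as.vector(mech$T_lap %*% P)
  state$Qdiv <- state$Qdiv + dt * (out_p + dd$drive) / mech$Ve
  if (n_t > 0) {
    state$dp_old <- PT - P[mech$host]
    tr <- model$mesh$truss
    state$w_truss <- p$truss_G * (PT[tr$elems$a] - PT[tr$elems$b]) / tr$elems$area
    ## bath exchange at the mouths (positive = out of the cell into bath)
    mouth <- which(tr$nodes$mouth)
    if (length(mouth)) {
      qm <- -as.vector(mech$G_t %*% PT)[mouth]  # inflow to mouth from network
      state$mouth_flow <- qm
      state$cum_mouth <- state$cum_mouth + dt * sum(qm)
    }
  }

  ## element Darcy velocity W = -K (grad P + RT(1-phi) grad Ctot - C^F grad Psi)
  state$W_elem <- gradFV_pairs(mech, P, dd$Ct_e, dd$Ps_e, dd$CF_e, p)
  state$U <- U; state$P <- P; state$PT <- PT
  state$tension <- T_a
  state
}
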