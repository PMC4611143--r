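## Finite-element operators on the structured hex grid and the truss
## network.  All elements are identical axis-aligned cubes of edge h, so a
## single set of reference matrices (computed by 2x2x2 Gauss quadrature)
## serves every element; per-element material coefficients scale them at
## assembly time.

## reference trilinear hex matrices for edge length h
hex_reference <- function(h) {
  g <- 1 / sqrt(3)
  gp <- as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
  corners <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  ## VTK node order
  vtk <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  shape <- function(p) {  # values and ref-gradients of the 8 shape functions
    N <- numeric(8); dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      s <- vtk[a, ]
      N[a] <- prod(1 + s * p) / 8
      for (d in 1:3) {
        q <- (1 + s * p); q[d] <- s[d]
        dN[a, d] <- prod(q) / 8
      }
    }
    list(N = N, dN = dN)
  }
  detJ <- (h / 2)^3
  K <- matrix(0, 8, 8)            # int grad Ni . grad Nj
  G <- array(0, c(8, 8, 3))       # int Ni dNj/dx_d
  M <- matrix(0, 8, 8)            # int Ni Nj (consistent)
  Ngp <- matrix(0, 8, 8); dNgp <- array(0, c(8, 8, 3))
  for (q in 1:8) {
    s <- shape(gp[q, ])
    dNx <- s$dN * (2 / h)
    K <- K + (dNx %*% t(dNx)) * detJ
    M <- M + (s$N %*% t(s$N)) * detJ
    for (d in 1:3) G[, , d] <- G[, , d] + (s$N %*% t(dNx[, d])) * detJ
    Ngp[q, ] <- s$N; dNgp[q, , ] <- dNx
  }
  list(h = h, K = K, M = M, G = G, N_gp = Ngp, dN_gp = dNgp,
       detJ = detJ, w = rep(detJ, 8))
}

## build the assembly index skeleton for a set of hex elements on a DOF map
## (rows/cols for the 64 entries of each element, column-major over (i,j))
hex_skeleton <- function(hex_conn, dofmap) {
  conn <- matrix(dofmap[hex_conn], nrow(hex_conn), 8)
  ii <- conn[, rep(1:8, times = 8), drop = FALSE]
  jj <- conn[, rep(1:8, each = 8), drop = FALSE]
  list(i = as.vector(t(ii)), j = as.vector(t(jj)), conn = conn,
       nelem = nrow(conn))
}

## assemble sum_e coeff_e * ref (an 8x8 reference matrix) into sparse n x n
assemble_hex <- function(skel, ref8, coeff, ndof, extra = NULL) {
  vals <- rep(as.vector(ref8), times = skel$nelem) * rep(coeff, each = 64)
  i <- skel$i; j <- skel$j
  if (!is.null(extra)) {
    i <- c(i, extra$i); j <- c(j, extra$j); vals <- c(vals, extra$x)
  }
  Matrix::sparseMatrix(i = i, j = j, x = vals, dims = c(ndof, ndof))
}

## truss (two-node line) triplets for a stiffness-type operator with
## per-element coefficient k_e: k_e * [[1,-1],[-1,1]]
truss_triplets <- function(a_dof, b_dof, k_e) {
  list(i = c(a_dof, a_dof, b_dof, b_dof),
       j = c(a_dof, b_dof, a_dof, b_dof),
       x = c(k_e, -k_e, -k_e, k_e))
}

## lumped nodal quantity: sum_e coeff_e * V_e / 8 to each element node
lump_nodal <- function(skel, coeff, Ve, ndof) {
  v <- numeric(ndof)
  add <- rep(coeff * Ve / 8, times = 8)
  idx <- as.vector(skel$conn)
  agg <- rowsum(add, idx)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

## Transport operator bundle for one side (intra or extra) of the membrane.
## Holds the static diffusion stiffness per species, lumped masses (with
## and without the fluid fraction), and the skeleton needed to reassemble
## concentration- or velocity-dependent operators quickly.
make_transport_side <- function(mesh, params, side = c("intra", "extra")) {
  side <- match.arg(side)
  ref <- hex_reference(mesh$h)
  sp <- params$species
  nsp <- nrow(sp)
  lab <- as.character(mesh$label)

  if (side == "intra") {
    sel <- mesh$is_intra
    dofmap <- mesh$intra_dof
    ndof <- mesh$n_intra_dof
  } else {
    sel <- !mesh$is_intra
    dofmap <- mesh$extra_dof
    ndof <- mesh$n_extra_dof
  }
  hexes <- mesh$hex[sel, , drop = FALSE]
  elab <- lab[sel]
  skel <- if (nrow(hexes) > 0) hex_skeleton(hexes, dofmap) else NULL

  ## per-element diffusion scale and fluid fraction
  dscale <- if (side == "intra") rep(1, sum(sel)) else
    rep(params$D_extracellular_scale, sum(sel))
  phiw <- if (side == "intra") unname(params$phi_w[elab]) else
    rep(unname(params$phi_w["extracellular"]), sum(sel))

  ## truss contributions live on the extracellular side.  The t-tubular
  ## diffusion restriction is a single factor for every species, so the
  ## species diffusion coefficient factors out of the whole operator: one
  ## base stiffness serves all nine species (scaled by D_alpha per column).
  tr <- mesh$truss
  has_truss <- side == "extra" && nrow(tr$elems) > 0
  extra <- NULL
  if (has_truss) {
    k_e <- params$restriction * tr$elems$area / tr$elems$L
    extra <- truss_triplets(tr$nodes$edof[tr$elems$a],
                            tr$nodes$edof[tr$elems$b], k_e)
  }
  if (!is.null(skel)) {
    K_base <- assemble_hex(skel, ref$K, dscale, ndof, extra)
  } else if (!is.null(extra)) {
    K_base <- Matrix::sparseMatrix(i = extra$i, j = extra$j, x = extra$x,
                                   dims = c(ndof, ndof))
  } else {
    K_base <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(ndof, ndof))
  }

  Ve <- mesh$h^3
  mass_phi <- if (!is.null(skel)) lump_nodal(skel, phiw, Ve, ndof) else numeric(ndof)
  mass_one <- if (!is.null(skel)) lump_nodal(skel, rep(1, sum(sel)), Ve, ndof) else numeric(ndof)
  if (has_truss) {
    phit <- params$phi_w_ttubule
    for (e in seq_len(nrow(tr$elems))) {
      ad <- tr$nodes$edof[tr$elems$a[e]]; bd <- tr$nodes$edof[tr$elems$b[e]]
      v2 <- tr$elems$lumen_vol[e] / 2
      mass_phi[c(ad, bd)] <- mass_phi[c(ad, bd)] + v2 * phit
      mass_one[c(ad, bd)] <- mass_one[c(ad, bd)] + v2
    }
  }

  list(side = side, ref = ref, skel = skel, ndof = ndof, dofmap = dofmap,
       elem_sel = which(sel), elab = elab, dscale = dscale, phiw = phiw,
       K_base = K_base, mass_phi = mass_phi, mass_one = mass_one,
       has_truss = has_truss, Ve = Ve)
}

## migration stiffness for species a: coefficient D_e * z_a/RT_F * Cbar_e
## (element mean of nodal concentration); truss segments use the restricted
## D and the segment mean.  Returns sparse ndof x ndof.
migration_operator <- function(ts, mesh, params, Cnodal, a) {
  sp <- params$species
  z <- sp$z[a]
  if (z == 0) return(NULL)
  RTF <- params$constants$RT_F
  extra <- NULL
  if (ts$has_truss) {
    tr <- mesh$truss
    Dlum <- restricted_diffusion_coeffs(params)[[a]]
    cm <- (Cnodal[tr$nodes$edof[tr$elems$a]] + Cnodal[tr$nodes$edof[tr$elems$b]]) / 2
    k_e <- Dlum * (z / RTF) * cm * tr$elems$area / tr$elems$L
    extra <- truss_triplets(tr$nodes$edof[tr$elems$a],
                            tr$nodes$edof[tr$elems$b], k_e)
  }
  if (!is.null(ts$skel)) {
    cbar <- rowMeans(matrix(Cnodal[ts$skel$conn], ncol = 8))
    coeff <- sp$D_cyto[a] * ts$dscale * (z / RTF) * cbar
    assemble_hex(ts$skel, ts$ref$K, coeff, ts$ndof, extra)
  } else if (!is.null(extra)) {
    Matrix::sparseMatrix(i = extra$i, j = extra$j, x = extra$x,
                         dims = c(ts$ndof, ts$ndof))
  } else NULL
}

## convection operator: conv_i = int N_i W . grad C, with element-constant
## W (3 columns per element); optional truss part with per-element axial
## velocity w_t (um/ms) and lumen area.
convection_operator <- function(ts, mesh, W_elem = NULL, w_truss = NULL) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  if (!is.null(ts$skel) && !is.null(W_elem)) {
    ref <- ts$ref
    vals <- rep(as.vector(ref$G[, , 1]), times = ts$skel$nelem) * rep(W_elem[, 1], each = 64) +
            rep(as.vector(ref$G[, , 2]), times = ts$skel$nelem) * rep(W_elem[, 2], each = 64) +
            rep(as.vector(ref$G[, , 3]), times = ts$skel$nelem) * rep(W_elem[, 3], each = 64)
    i <- ts$skel$i; j <- ts$skel$j; x <- vals
  }
  if (ts$has_truss && !is.null(w_truss)) {
    tr <- mesh$truss
    ad <- tr$nodes$edof[tr$elems$a]; bd <- tr$nodes$edof[tr$elems$b]
    ## int N_i w dC/ds on a 2-node segment: w*A/2 * [[-1,1],[-1,1]] in the
    ## local (a,b) ordering with s from a to b
    k <- w_truss * tr$elems$area / 2
    i <- c(i, ad, ad, bd, bd)
    j <- c(j, ad, bd, ad, bd)
    x <- c(x, -k, k, -k, k)
  }
  if (length(i) == 0) return(NULL)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(ts$ndof, ts$ndof))
}
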