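## Synthetic cardiomyocyte segment meshes.
##
## Geometry convention: z is the cell long axis, the z-line plane is z = 0
## and the m-line plane is z = segment_length; x = 0 and y = 0 are the
## symmetry (center) planes of a quarter cross-section; the sarcolemma lies
## on x = Lx and y = Ly with an extracellular shell beyond it.  All
## coordinates in um, 0-based structured indices internally, 1-based ids in
## the returned tables.

#' Geometry specification for a synthetic myocyte segment
#'
#' Describes a half-sarcomere segment of a quarter cross-section.  Defaults
#' give a desk-scale quarter-section model: 10 x 10 um cross-section,
#' 1 um (half-sarcomere) length, 0.5 um elements, 25 myofibril bundles on a
#' 2 um lattice, t-tubules on the z-line plane along the inter-bundle
#' streets with alternating penetration depth, junctional-SR release sites
#' every \code{jsr_spacing} along the z-line.
#'
#' @param segment_length half-sarcomere length, um.
#' @param cross_section numeric length-2, quarter cross-section extents, um.
#' @param n_myofibrils number of myofibril bundles (arranged on a near
#'   square lattice); 0 for none.
#' @param element_size hexahedral element edge, um; must divide all
#'   dimensions within rounding.
#' @param t_tubule_paths list of polylines (each an n x 3 matrix, z = 0) or
#'   NULL for the default street-aligned network.
#' @param jsr_spacing spacing of JSR release sites, um.
#' @param mito_placement_seed integer seed for the random placement of
#'   mitochondria among street columns.
#' @param extracellular_shell_thickness bath shell thickness, um (0 = none).
#' @param ttubule_radius lumen radius, um.
#' @param sub_sarcolemmal_mitochondria logical; if FALSE, columns adjacent
#'   to the surface sarcolemma are excluded from mitochondria placement
#'   (the de-SSM contrast).
#' @return list of class \code{cell_geometry_spec}.
#' @export
cell_geometry_spec <- function(segment_length = 1.0,
                               cross_section = c(10, 10),
                               n_myofibrils = 25,
                               element_size = 0.5,
                               t_tubule_paths = NULL,
                               jsr_spacing = 0.4,
                               mito_placement_seed = 1L,
                               extracellular_shell_thickness = element_size,
                               ttubule_radius = 0.125,
                               sub_sarcolemmal_mitochondria = TRUE) {
  stopifnot(segment_length > 0, all(cross_section > 0), element_size > 0,
            jsr_spacing > 0, ttubule_radius > 0,
            extracellular_shell_thickness >= 0, n_myofibrils >= 0)
  ndiv <- c(cross_section, segment_length) / element_size
  if (any(abs(ndiv - round(ndiv)) > 1e-6))
    stop("element_size must divide the segment dimensions")
  structure(list(
    segment_length = segment_length,
    cross_section = cross_section,
    n_myofibrils = as.integer(n_myofibrils),
    element_size = element_size,
    t_tubule_paths = t_tubule_paths,
    jsr_spacing = jsr_spacing,
    mito_placement_seed = as.integer(mito_placement_seed),
    extracellular_shell_thickness = extracellular_shell_thickness,
    ttubule_radius = ttubule_radius,
    sub_sarcolemmal_mitochondria = sub_sarcolemmal_mitochondria
  ), class = "cell_geometry_spec")
}

#' Intracellular compartment volume fractions
#'
#' The myocyte interior is composed of myofibril, mitochondria, cytosol,
#' junctional SR and network SR in the ratio 54 : 35 : 8 : 0.03 : 3; the
#' default renormalises that ratio to sum to one.
#'
#' @param myofibril,mitochondria,cytosol,jsr,nsr non-negative fractions.
#' @return list of class \code{compartment_fractions} (fractions sum to 1).
#' @export
compartment_fractions <- function(myofibril = 54, mitochondria = 35,
                                  cytosol = 8, jsr = 0.03, nsr = 3) {
  v <- c(myofibril = myofibril, mitochondria = mitochondria,
         cytosol = cytosol, jsr = jsr, nsr = nsr)
  if (any(v < 0)) stop("fractions must be non-negative")
  s <- sum(v)
  if (s <= 0) stop("fractions must not all be zero")
  structure(as.list(v / s), class = "compartment_fractions")
}

## internal: run code under a temporary seed, restoring RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

compartment_levels <- c("myofibril", "mitochondria", "cytosol",
                        "jsr", "nsr", "extracellular")

## default t-tubule network: polylines on the z-line plane along the
## street lines of the bundle lattice (the node line between the last
## myofibril row of a tile and its street row), alternating full / half
## penetration depth to give a spread of membrane distances.
default_ttubule_paths <- function(Lx, Ly, tile, h, b_cells) {
  off <- b_cells * h                                 # street line offset in tile
  paths <- list()
  ky <- seq(off, Ly - tile + off, by = tile)
  for (i in seq_along(ky)) {
    x_in <- if (i %% 2 == 1) h else Lx / 2          # full / half depth
    paths[[length(paths) + 1]] <-
      cbind(x = seq(Lx, x_in, by = -h), y = ky[i], z = 0)
  }
  kx <- seq(off, Lx - tile + off, by = tile)
  for (i in seq_along(kx)) {
    y_in <- if (i %% 2 == 0) h else Ly / 2
    paths[[length(paths) + 1]] <-
      cbind(x = kx[i], y = seq(Ly, y_in, by = -h), z = 0)
  }
  paths
}

## cells of the z-line layer adjacent to a polyline segment midpoint
adjacent_cells_2d <- function(m, h, nx, ny) {
  rng <- function(f) {
    if (abs(f - round(f)) < 1e-6) round(f) + c(-1L, 0L) else floor(f)
  }
  cand <- expand.grid(i = rng(m[1] / h), j = rng(m[2] / h))
  cand[cand$i >= 0 & cand$i < nx & cand$j >= 0 & cand$j < ny, , drop = FALSE]
}

#' Build a labeled hexahedral + truss mesh of a myocyte segment
#'
#' Generates a structured axis-aligned hexahedral grid covering the
#' intracellular quarter cross-section plus an extracellular shell, labels
#' the intracellular elements by compartment to match the requested volume
#' fractions (myofibril bundles on a lattice, NSR sheathing the bundles,
#' mitochondria placed by seeded randomization among the remaining street
#' columns, the rest cytosol), lays the t-tubule truss network on the
#' z-line plane avoiding myofibril elements, attaches JSR release sites
#' every \code{jsr_spacing}, and pairs intra/extracellular degrees of
#' freedom across the sarcolemma (surface and t-tubular).
#'
#' The result is deterministic for a fixed \code{mito_placement_seed}.
#'
#' @param spec [cell_geometry_spec()].
#' @param fractions [compartment_fractions()].
#' @return list of class \code{tricell_mesh}; key entries: \code{nodes}
#'   (n x 3), \code{hex} (e x 8 connectivity), \code{label} (per element),
#'   \code{membrane} (node-pair table with areas and type), \code{truss}
#'   (lumen network), \code{release_sites}, \code{boundary_tags}, and DOF
#'   index maps \code{intra_dof} / \code{extra_dof}.
#' @export
build_mesh <- function(spec = cell_geometry_spec(),
                       fractions = compartment_fractions()) {
  stopifnot(inherits(spec, "cell_geometry_spec"),
            inherits(fractions, "compartment_fractions"))
  h <- spec$element_size
  nx <- round(spec$cross_section[1] / h)
  ny <- round(spec$cross_section[2] / h)
  nz <- round(spec$segment_length / h)
  sh <- round(spec$extracellular_shell_thickness / h)
  ncx <- nx + sh; ncy <- ny + sh; ncz <- nz
  Lx <- nx * h; Ly <- ny * h; Lz <- nz * h

  ## ---- nodes and cells of the full structured grid -----------------------
  nnx <- ncx + 1; nny <- ncy + 1; nnz <- ncz + 1
  gid <- function(i, j, k) 1L + i + j * nnx + k * nnx * nny  # 0-based ijk
  xs <- (0:ncx) * h; ys <- (0:ncy) * h; zs <- (0:ncz) * h
  nodes <- cbind(x = rep(xs, times = nny * nnz),
                 y = rep(rep(ys, each = nnx), times = nnz),
                 z = rep(zs, each = nnx * nny))
  ci <- rep(0:(ncx - 1), times = ncy * ncz)
  cj <- rep(rep(0:(ncy - 1), each = ncx), times = ncz)
  ck <- rep(0:(ncz - 1), each = ncx * ncy)
  hex <- cbind(gid(ci, cj, ck), gid(ci + 1, cj, ck),
               gid(ci + 1, cj + 1, ck), gid(ci, cj + 1, ck),
               gid(ci, cj, ck + 1), gid(ci + 1, cj, ck + 1),
               gid(ci + 1, cj + 1, ck + 1), gid(ci, cj + 1, ck + 1))
  nelem <- nrow(hex)
  is_intra <- ci < nx & cj < ny

  ## ---- bundle lattice geometry --------------------------------------------
  ## Each tile of the lattice holds a myofibril block at its low-index
  ## corner (local indices 0..b-1 in x and y) and a one-cell street along
  ## its high edges; t-tubules run along the node lines between block and
  ## street, so they always border a non-myofibril cell.
  nbx <- nby <- 0L; tpx <- tpy <- nx
  if (spec$n_myofibrils > 0) {
    nbx <- as.integer(ceiling(sqrt(spec$n_myofibrils)))
    nby <- as.integer(ceiling(spec$n_myofibrils / nbx))
    tpx <- max(2L, as.integer(round(nx / nbx)))
    tpy <- max(2L, as.integer(round(ny / nby)))
  }
  b_cells <- max(1L, min(tpx, tpy) - 1L)
  tile <- tpx * h

  ## ---- t-tubule paths ----------------------------------------------------
  paths <- spec$t_tubule_paths
  if (is.null(paths)) {
    paths <- if (nx > 2 * tpx && sh > 0)
      default_ttubule_paths(Lx, Ly, tile, h, b_cells) else list()
  }
  for (p in paths) {
    if (!is.matrix(p) || ncol(p) != 3) stop("t_tubule_paths must be n x 3 matrices")
    if (any(abs(p[, 3]) > 1e-9)) stop("t-tubule polylines must lie on the z-line plane")
  }
  snap <- function(v) as.integer(round(v / h))
  colkey <- function(i, j) i + nx * j

  ## ---- compartment labels (column-based) ---------------------------------
  ncol_xy <- nx * ny
  n_intra <- ncol_xy * nz
  fr <- unlist(fractions[c("myofibril", "mitochondria", "cytosol", "jsr", "nsr")])
  n_myo_col <- round(fr[["myofibril"]] * ncol_xy)
  n_mit_col <- round(fr[["mitochondria"]] * ncol_xy)
  n_nsr_col <- round(fr[["nsr"]] * ncol_xy)

  col_i <- rep(0:(nx - 1), times = ny)
  col_j <- rep(0:(ny - 1), each = nx)
  col_label <- rep("cytosol", ncol_xy)
  col_bundle <- rep(NA_integer_, ncol_xy)

  if (spec$n_myofibrils > 0 && n_myo_col > 0) {
    tx <- pmin(col_i %/% tpx, nbx - 1L)
    ty <- pmin(col_j %/% tpy, nby - 1L)
    li <- col_i - tx * tpx; lj <- col_j - ty * tpy
    bundle <- tx + nbx * ty
    eligible <- bundle < spec$n_myofibrils & li < b_cells & lj < b_cells
    if (sum(eligible) < n_myo_col)
      stop(sprintf(
        "infeasible fractions: myofibril needs %d columns, lattice offers %d",
        n_myo_col, sum(eligible)))
    ## fill bundles evenly, innermost cells of each block first
    dc <- pmax(abs(li - (b_cells - 1) / 2), abs(lj - (b_cells - 1) / 2))
    ord <- order(!eligible, dc, bundle, col_i, col_j)
    rank_in_bundle <- integer(ncol_xy)
    e_ord <- ord[seq_len(sum(eligible))]
    rank_in_bundle[e_ord] <- stats::ave(seq_along(e_ord),
                                        bundle[e_ord], FUN = seq_along)
    ord2 <- order(!eligible, rank_in_bundle, dc, bundle)
    col_label[ord2[seq_len(n_myo_col)]] <- "myofibril"
    col_bundle[col_label == "myofibril"] <-
      bundle[col_label == "myofibril"] + 1L
  } else if (n_myo_col > 0) {
    stop("infeasible fractions: myofibril fraction > 0 but n_myofibrils = 0")
  }

  ## NSR: columns face-adjacent to a myofibril column
  myo_mask <- col_label == "myofibril"
  if (n_nsr_col > 0) {
    adj <- rep(FALSE, ncol_xy)
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i2 <- col_i + d[1]; j2 <- col_j + d[2]
      ok <- i2 >= 0 & i2 < nx & j2 >= 0 & j2 < ny
      nb <- rep(FALSE, ncol_xy)
      nb[ok] <- myo_mask[1 + i2[ok] + nx * j2[ok]]
      adj <- adj | nb
    }
    cand <- which(adj & col_label == "cytosol")
    if (length(cand) < n_nsr_col)
      stop("infeasible fractions: nsr target exceeds columns adjacent to myofibril")
    ## spread deterministically along the candidate list
    pick <- cand[unique(round(seq(1, length(cand), length.out = n_nsr_col)))]
    k <- 1L
    while (length(pick) < n_nsr_col) {      # fill after rounding collisions
      extra <- setdiff(cand, pick)
      pick <- c(pick, extra[seq_len(min(n_nsr_col - length(pick), length(extra)))])
      k <- k + 1L; if (k > 3L) break
    }
    col_label[pick[seq_len(n_nsr_col)]] <- "nsr"
  }

  ## mitochondria: seeded sample of remaining cytosol columns
  if (n_mit_col > 0) {
    cand <- which(col_label == "cytosol")
    if (!spec$sub_sarcolemmal_mitochondria) {
      surf <- col_i == nx - 1 | col_j == ny - 1
      cand <- setdiff(cand, which(surf))
    }
    if (length(cand) < n_mit_col)
      stop("infeasible fractions: mitochondria target exceeds free columns")
    pick <- with_seed(spec$mito_placement_seed,
                      sample(cand, n_mit_col, replace = FALSE))
    col_label[pick] <- "mitochondria"
  }

  label <- rep("extracellular", nelem)
  ckey <- colkey(ci, cj)
  label[is_intra] <- col_label[1 + ckey[is_intra]]

  ## ---- truss network ------------------------------------------------------
  r_t <- spec$ttubule_radius
  t_nodes <- data.frame(gnode = integer(0), x = numeric(0), y = numeric(0),
                        z = numeric(0), mouth = logical(0), path = integer(0),
                        arc = numeric(0))
  t_elems <- data.frame(a = integer(0), b = integer(0), L = numeric(0))
  for (ip in seq_along(paths)) {
    p <- paths[[ip]]
    ids <- gid(snap(p[, 1]), snap(p[, 2]), snap(p[, 3]))
    arc <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    for (q in seq_len(nrow(p))) {
      if (!ids[q] %in% t_nodes$gnode) {
        on_surf <- abs(p[q, 1] - Lx) < 1e-9 || abs(p[q, 2] - Ly) < 1e-9
        t_nodes <- rbind(t_nodes, data.frame(
          gnode = ids[q], x = p[q, 1], y = p[q, 2], z = p[q, 3],
          mouth = on_surf && sh > 0, path = ip, arc = arc[q]))
      }
    }
    ai <- match(ids[-nrow(p)], t_nodes$gnode)
    bi <- match(ids[-1], t_nodes$gnode)
    Lseg <- sqrt(rowSums(diff(p)^2))
    t_elems <- rbind(t_elems, data.frame(a = ai, b = bi, L = Lseg))
    ## the tubule must avoid myofibril element interiors
    for (s in seq_len(nrow(p) - 1)) {
      m <- (p[s, ] + p[s + 1, ]) / 2
      cand <- adjacent_cells_2d(m, h, nx, ny)
      if (nrow(cand) > 0 &&
          all(col_label[1 + colkey(cand$i, cand$j)] == "myofibril"))
        stop("t-tubule path crosses myofibril elements")
    }
  }
  if (nrow(t_elems) > 0) {
    t_elems$area <- pi * r_t^2
    t_elems$lumen_vol <- t_elems$area * t_elems$L
  }

  ## ---- JSR release sites and volumetric JSR elements ----------------------
  ## Release sites tile the z-line plane of the intracellular region on a
  ## jsr_spacing grid (snapped to mesh nodes); each carries an equal share
  ## of the JSR volume fraction.  A small number of elements adjacent to
  ## membrane-facing sites are labeled jsr to carry the volumetric share.
  sx <- unique(pmin(snap(seq(0, Lx, by = spec$jsr_spacing)), nx))
  sy <- unique(pmin(snap(seq(0, Ly, by = spec$jsr_spacing)), ny))
  site_g <- as.vector(outer(sx, sy, function(i, j) gid(i, j, 0L)))
  site_xy <- cbind(nodes[site_g, 1], nodes[site_g, 2])

  ## distance to nearest membrane: surface planes or truss nodes
  d_surf <- pmin(Lx - site_xy[, 1], Ly - site_xy[, 2])
  if (nrow(t_nodes) > 0) {
    d_tub <- apply(site_xy, 1, function(pt)
      sqrt(min((t_nodes$x - pt[1])^2 + (t_nodes$y - pt[2])^2)))
    d_mem <- pmin(d_surf, d_tub)
  } else d_mem <- d_surf
  V_intra <- n_intra * h^3
  release_sites <- data.frame(gnode = site_g,
                              x = site_xy[, 1], y = site_xy[, 2], z = 0,
                              dist = d_mem,
                              vol_jsr = fr["jsr"] * V_intra / length(site_g))

  n_jsr_el <- max(if (fr["jsr"] > 0) 1L else 0L, round(fr["jsr"] * n_intra))
  if (n_jsr_el > 0 && n_intra > 0) {
    near <- order(release_sites$dist)  # membrane-facing sites first
    placed <- 0L
    for (sidx in near) {
      i0 <- snap(release_sites$x[sidx]); j0 <- snap(release_sites$y[sidx])
      for (dd in list(c(-1, -1), c(0, -1), c(-1, 0), c(0, 0))) {
        i2 <- i0 + dd[1]; j2 <- j0 + dd[2]
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny) next
        eid <- 1 + i2 + ncx * j2   # layer 0 cell id
        if (label[eid] %in% c("cytosol", "nsr")) {
          label[eid] <- "jsr"; placed <- placed + 1L; break
        }
      }
      if (placed >= n_jsr_el) break
    }
  }

  ## ---- DOF maps -----------------------------------------------------------
  nnode <- nrow(nodes)
  touch_intra <- rep(FALSE, nnode); touch_extra <- rep(FALSE, nnode)
  touch_intra[as.vector(hex[is_intra, , drop = FALSE])] <- TRUE
  touch_extra[as.vector(hex[!is_intra, , drop = FALSE])] <- TRUE
  intra_nodes <- which(touch_intra)
  intra_dof <- rep(NA_integer_, nnode)
  intra_dof[intra_nodes] <- seq_along(intra_nodes)

  extra_nodes <- which(touch_extra)
  extra_dof <- rep(NA_integer_, nnode)
  extra_dof[extra_nodes] <- seq_along(extra_nodes)
  n_extra_grid <- length(extra_nodes)

  ## truss lumen DOFs: mouths share the grid extracellular DOF; interior
  ## truss nodes get appended lumen DOFs
  if (nrow(t_nodes) > 0) {
    t_nodes$edof <- NA_integer_
    nxt <- n_extra_grid
    for (q in seq_len(nrow(t_nodes))) {
      g <- t_nodes$gnode[q]
      if (t_nodes$mouth[q] && !is.na(extra_dof[g])) {
        t_nodes$edof[q] <- extra_dof[g]
      } else {
        nxt <- nxt + 1L
        t_nodes$edof[q] <- nxt
      }
    }
    n_extra <- nxt
  } else n_extra <- n_extra_grid

  ## ---- membrane pairing ---------------------------------------------------
  ## surface: grid nodes on the sarcolemma planes shared by intra and extra
  memb <- NULL
  if (sh > 0) {
    shared <- which(touch_intra & touch_extra)
    ## nodal area: sum of adjacent surface membrane faces / 4
    area <- rep(0, nnode)
    ## faces on x = Lx between cells (nx-1, j, k) and (nx, j, k)
    for (j in 0:(ny - 1)) for (k in 0:(nz - 1)) {
      fn <- c(gid(nx, j, k), gid(nx, j + 1, k), gid(nx, j, k + 1), gid(nx, j + 1, k + 1))
      area[fn] <- area[fn] + h^2 / 4
    }
    for (i in 0:(nx - 1)) for (k in 0:(nz - 1)) {
      fn <- c(gid(i, ny, k), gid(i + 1, ny, k), gid(i, ny, k + 1), gid(i + 1, ny, k + 1))
      area[fn] <- area[fn] + h^2 / 4
    }
    memb <- data.frame(gnode = shared,
                       idof = intra_dof[shared],
                       edof = extra_dof[shared],
                       area = area[shared],
                       type = "surface", stringsAsFactors = FALSE)
  }
  if (nrow(t_nodes) > 0) {
    half <- rep(0, nrow(t_nodes))
    for (e in seq_len(nrow(t_elems))) {
      half[t_elems$a[e]] <- half[t_elems$a[e]] + t_elems$L[e] / 2
      half[t_elems$b[e]] <- half[t_elems$b[e]] + t_elems$L[e] / 2
    }
    tm <- data.frame(gnode = t_nodes$gnode,
                     idof = intra_dof[t_nodes$gnode],
                     edof = t_nodes$edof,
                     area = 2 * pi * r_t * half,
                     type = "t_tubular", stringsAsFactors = FALSE)
    tm <- tm[!is.na(tm$idof) & !t_nodes$mouth, ]  # mouths carry no membrane
    memb <- rbind(memb, tm)
  }
  if (is.null(memb))
    memb <- data.frame(gnode = integer(0), idof = integer(0),
                       edof = integer(0), area = numeric(0),
                       type = character(0), stringsAsFactors = FALSE)

  mesh <- structure(list(
    h = h, dims = c(nx = nx, ny = ny, nz = nz), shell_layers = sh,
    grid = c(ncx = ncx, ncy = ncy, ncz = ncz),
    L = c(Lx = Lx, Ly = Ly, Lz = Lz),
    nodes = nodes, hex = hex,
    label = factor(label, levels = compartment_levels),
    is_intra = is_intra,
    cell_ijk = cbind(ci, cj, ck),
    intra_dof = intra_dof, extra_dof = extra_dof,
    intra_nodes = intra_nodes, extra_nodes = extra_nodes,
    n_intra_dof = length(intra_nodes), n_extra_dof = n_extra,
    membrane = memb,
    truss = list(nodes = t_nodes, elems = t_elems, radius = r_t,
                 paths = paths),
    release_sites = release_sites,
    col_info = data.frame(i = col_i, j = col_j, label = col_label,
                          bundle = col_bundle),
    fractions_requested = fractions,
    spec = spec
  ), class = "tricell_mesh")
  mesh <- tag_boundaries(mesh)

  meas <- measure_fractions(mesh)
  err <- abs(unlist(meas) - fr)
  if (any(err > 0.02)) {
    worst <- names(which.max(err))
    stop(sprintf(
      "infeasible fractions at this discretization: %s off by %.3f (absolute)",
      worst, max(err)))
  }
  mesh
}

#' Tag boundary node sets of a segment mesh
#'
#' Marks the node sets used by boundary conditions: the symmetry
#' \code{center} planes (x = 0 and y = 0), the \code{z_line} (z = 0) and
#' \code{m_line} (z = segment length) planes, and \code{outer_bath} (the
#' outermost extracellular planes, empty when the mesh has no shell).
#'
#' @param mesh a \code{tricell_mesh}.
#' @return the mesh with \code{boundary_tags} replaced.
#' @export
tag_boundaries <- function(mesh) {
  stopifnot(inherits(mesh, "tricell_mesh"))
  nd <- mesh$nodes
  tol <- 1e-9
  Lx <- mesh$L["Lx"]; Ly <- mesh$L["Ly"]; Lz <- mesh$L["Lz"]
  sh <- mesh$shell_layers * mesh$h
  outer <- if (mesh$shell_layers > 0)
    which((abs(nd[, 1] - (Lx + sh)) < tol | abs(nd[, 2] - (Ly + sh)) < tol) &
            !is.na(mesh$extra_dof)) else integer(0)
  mesh$boundary_tags <- list(
    center = which(abs(nd[, 1]) < tol | abs(nd[, 2]) < tol),
    z_line = which(abs(nd[, 3]) < tol),
    m_line = which(abs(nd[, 3] - Lz) < tol),
    outer_bath = outer
  )
  mesh
}

#' Measure intracellular compartment volume fractions of a mesh
#'
#' Computes fractions from undeformed element volumes (structured grid, so
#' all elements have volume h^3).
#'
#' @param mesh a \code{tricell_mesh}.
#' @return a \code{compartment_fractions} list (sums to 1).
#' @export
measure_fractions <- function(mesh) {
  stopifnot(inherits(mesh, "tricell_mesh"))
  lab <- mesh$label[mesh$is_intra]
  n <- length(lab)
  if (n == 0) stop("mesh has no intracellular elements")
  f <- table(lab)[c("myofibril", "mitochondria", "cytosol", "jsr", "nsr")] / n
  structure(as.list(as.numeric(f)) |>
              stats::setNames(c("myofibril", "mitochondria", "cytosol",
                                "jsr", "nsr")),
            class = "compartment_fractions")
}

#' @export
print.tricell_mesh <- function(x, ...) {
  cat("tricell_mesh:", nrow(x$nodes), "nodes,", nrow(x$hex), "hex elements",
      sprintf("(%d intracellular), h = %g um\n", sum(x$is_intra), x$h))
  cat("  compartments:",
      paste(sprintf("%s=%d", levels(x$label), tabulate(x$label,
            nbins = nlevels(x$label))), collapse = " "), "\n")
  cat("  truss:", nrow(x$truss$elems), "elements,",
      nrow(x$truss$nodes), "nodes;",
      sum(x$membrane$type == "surface"), "surface +",
      sum(x$membrane$type == "t_tubular"), "t-tubular membrane node pairs\n")
  cat("  release sites:", nrow(x$release_sites), "\n")
  invisible(x)
}

#' Total membrane areas by type
#' @param mesh a \code{tricell_mesh}.
#' @return named numeric vector (um^2) with elements surface, t_tubular.
#' @export
membrane_areas <- function(mesh) {
  c(surface = sum(mesh$membrane$area[mesh$membrane$type == "surface"]),
    t_tubular = sum(mesh$membrane$area[mesh$membrane$type == "t_tubular"]))
}
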