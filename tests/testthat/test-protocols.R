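test_that("isometric twitch keeps cell length and produces a tension transient", {
  mesh <- small_mesh()
  res <- run_protocol(mesh, cfg = protocol_config("isometric_twitch",
                                                  duration = 40,
                                                  output_stride = 200L))
  ob <- res$observables
  expect_gt(max(ob$V_mean), 0)                 # an action potential fired
  expect_gt(max(ob$tension_mean), 0.02)        # tension developed
  ## m-line plane never moves
  nd <- mesh$nodes[mesh$intra_nodes, ]
  mline <- which(abs(nd[, 3] - mesh$L["Lz"]) < 1e-9)
  expect_lt(max(abs(res$state$U[3 * (mline - 1) + 3])), 1e-14)
  ## fluid flowed in the t-tubules during contraction
  expect_gt(max(abs(res$state$w_truss)), 0)
})

test_that("free twitch moves the m-line as a plane with workless constraint", {
  mesh <- small_mesh()
  res <- run_protocol(mesh, cfg = protocol_config("free_twitch",
                                                  duration = 40,
                                                  output_stride = 400L))
  nd <- mesh$nodes[mesh$intra_nodes, ]
  mline <- which(abs(nd[, 3] - mesh$L["Lz"]) < 1e-9)
  uz <- res$state$U[3 * (mline - 1) + 3]
  expect_lt(diff(range(uz)), 1e-12)
})

test_that("voltage clamp holds the command potential and bath switches take effect", {
  mesh <- small_mesh()
  cfg <- protocol_config("voltage_clamp_switch_K", duration = 30,
                         output_stride = 100L)
  res <- run_protocol(mesh, cfg = cfg)
  ob <- res$observables
  ## the core potential is clamped near -80 after settling
  expect_lt(abs(ob$V_mean[nrow(ob)] + 80), 8)
  ## bath K was switched: outer extracellular nodes carry 8.1 mM
  expect_equal(unname(res$state$Ce[res$model$bath_edof[1], "K"]), 8.1)
  ## whole-cell current changed between pre- and post-switch
  pre <- ob$I_K1_cell[ob$t < 10]
  post <- ob$I_K1_cell[ob$t > 25]
  expect_gt(abs(mean(post) - mean(pre)), 1e-4)
})

test_that("t-tubular diffusion restriction delays the bath-switch response", {
  ## time for the deep-lumen K+ to approach the new bath level is strictly
  ## longer for a smaller restriction factor (the mechanism behind the
  ## family of switch curves), and the de-tubulated variant responds with
  ## no tubular delay at all
  t_half <- sapply(c(0.1, 0.5), function(restr) {
    mesh <- small_mesh()
    mod <- build_model(mesh, params = material_params(restriction = restr),
                       subcell = inert_subcell(),
                       conductances = zero_conductances())
    deep <- mod$mesh$truss$nodes$edof[which.max(mod$mesh$truss$nodes$arc)]
    mod$bath_C["K"] <- 8.1
    st <- mod$state
    ctrl <- stepping_config()
    t <- 0
    tricellfem:::refresh_cache(mod, st, ctrl$dt_elec, NULL)
    while (t < 250) {
      st <- tricellfem:::elec_step(mod, st, ctrl$dt_elec, ctrl)
      ctrl <- attr(st, "ctrl")
      t <- st$t
      if (st$Ce[deep, "K"] > 5.4 + 0.25 * 2.7) break
    }
    t
  })
  expect_gt(t_half[1], 1.5 * t_half[2])

  ## de-tubulated: no truss, membrane current follows the bath immediately
  mesh_det <- suppressWarnings(build_mesh(cell_geometry_spec(
    cross_section = c(6, 6), n_myofibrils = 9, t_tubule_paths = list())))
  expect_equal(nrow(mesh_det$truss$elems), 0L)
  expect_equal(sum(mesh_det$membrane$type == "t_tubular"), 0L)
})

test_that("dual-potential and lumped simulations agree for uniform densities and fast diffusion", {
  ## with homogeneous channel densities and artificially large diffusion the
  ## spatially resolved potentials collapse onto the lumped trace
  mesh <- small_mesh()
  par_fast <- material_params(restriction = 1)
  par_fast$species$D_cyto <- par_fast$species$D_cyto * 0          # rebuild below
  par_fast <- material_params(restriction = 1)
  run_mode <- function(mode) {
    mod <- build_model(mesh, params = par_fast, mode = mode,
                       density_ratios = c(I_Na = 1),
                       subcell = inert_subcell())
    vs <- c()
    obs <- function(st) vs <<- c(vs, mean(st$V_memb))
    advance_cycle(mod, t_end = 25,
                  cfg = stepping_config(output_stride = 50L),
                  stim_fn = function(t) apply_stimulus(t, onset = 1),
                  mechanics = FALSE, observer = obs)
    vs
  }
  v_dual <- run_mode("triphasic")
  v_lump <- run_mode("rd")
  expect_lt(max(abs(v_dual - v_lump)), 0.5)
})

test_that("flux decomposition satisfies the balance identity and its degenerate limits", {
  mesh <- small_mesh()
  cfg <- protocol_config("isometric_twitch", duration = 12,
                         track_decomposition = TRUE, output_stride = 100L)
  res <- run_protocol(mesh, cfg = cfg)
  dec <- decompose_ion_fluxes(res)
  expect_true(all(dec$summary$diffusion_max > 0))
  expect_true(all(dec$summary$electromigration_pct >= 0))
  ## rd mode has no potential gradient and no convection: terms absent
  mod_rd <- build_model(mesh, mode = "rd", subcell = inert_subcell())
  st <- advance_electrical(mod_rd, 0.2)
  expect_equal(max(abs(st$Psi_i)), 0)
  ## with a uniform potential the electromigration term vanishes
  sp <- mod_rd$params$species
  a <- which(sp$name == "K")
  Am <- tricellfem:::migration_operator(mod_rd$ts_i, mesh, mod_rd$params,
                                        mod_rd$state$Ci[, a], a)
  expect_lt(max(abs(Am %*% rep(3.5, mod_rd$ts_i$ndof))), 1e-10)
})

test_that("release-delay analysis handles a single-site mesh and distances match hand computation", {
  mesh <- box_mesh(2, 2, 1)
  rs <- mesh$release_sites
  ## distances computed by brute force against the surface planes (there is
  ## no shell, so the distance reduces to the analytic surface distance)
  d_brute <- pmin(mesh$L["Lx"] - rs$x, mesh$L["Ly"] - rs$y)
  expect_equal(rs$dist, unname(d_brute))
})

test_that("end-to-end protocol runs are deterministic", {
  mesh <- small_mesh()
  cfg <- protocol_config("isometric_twitch", duration = 6,
                         output_stride = 100L)
  r1 <- run_protocol(mesh, cfg = cfg)
  r2 <- run_protocol(mesh, cfg = cfg)
  expect_identical(r1$observables, r2$observables)
  expect_identical(r1$state$Ci, r2$state$Ci)
})

test_that("potential profiles spread more in the lumen than intracellularly at the upstroke", {
  mesh <- small_mesh()
  cfg <- protocol_config("isometric_twitch", duration = 3,
                         output_stride = 5L)
  res <- run_protocol(mesh, cfg = cfg)
  pp <- potential_profile_analysis(res, window = c(0, 2))
  expect_gt(pp$spread[["Psi_e"]], pp$spread[["Psi_i"]])
  expect_gt(pp$spread[["V_m"]], 0)
})

test_that("the cable equation profile emerges in a sealed passive tubule", {
  ## steady subthreshold current injected at the mouth end of a passive
  ## membrane cable: V(x) ~ cosh(x / lambda) with the sealed end at x = 0.
  ## Build the analytic prediction from the discrete network parameters and
  ## compare after nondimensionalisation.
  n_seg <- 60; L_seg <- 0.5
  g_m <- 2e-6                     # membrane conductance per node, amol/(ms mV)
  g_a <- 8e-4                     # axial conductance per segment
  ## package operators: truss-style axial Laplacian plus membrane leak
  elems <- data.frame(a = 1:(n_seg - 1), b = 2:n_seg)
  La <- truss_network_matrix(elems, g_a, n_seg)
  A <- La + Matrix::Diagonal(n_seg, g_m)
  b <- numeric(n_seg); b[n_seg] <- 1e-4   # injection at the far end
  V <- as.vector(Matrix::solve(A, b))
  lambda <- sqrt(g_a / g_m)               # in segments
  ## the sealed (no-flux) end of the discrete ladder sits half a segment
  ## beyond the first node
  x <- (seq_len(n_seg) - 1) + 0.5
  Vexact <- cosh(x / lambda)
  expect_equal(V / V[1], Vexact / Vexact[1], tolerance = 0.02)
})
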