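## Oracle equivalences of the coupled electrodiffusion solver: analytic
## diffusion, electrochemical (Boltzmann) equilibrium, Donnan equilibrium,
## and Darcy / osmotic permeation closed forms.

test_that("1-D diffusion reproduces the erfc solution at verified order", {
  ## diffusion of a concentration step via the package operators, started
  ## from the exact profile at t0 and compared with the erfc solution at
  ## t1 (the step sits mid-bar so the boundaries stay inert); the L2 error
  ## shrinks at second order in h
  Dc <- 0.3                                 # Ca-scale diffusivity, um^2/ms
  Deff <- Dc / 0.833                        # phi_w dC/dt = div D grad C
  t0 <- 0.2; t1 <- 0.8
  exact <- function(x, t) 0.5 * (1 - pracma::erf((x - 4) / (2 * sqrt(Deff * t))))
  err <- sapply(c(0.5, 0.25), function(h) {
    n <- round(8 / h)
    mesh <- box_mesh(n, 1, 1, h = h)
    mod <- build_model(mesh, subcell = inert_subcell())
    a <- which(mod$params$species$name == "Ca")
    K <- mod$ts_i$K_base * Dc
    m <- mod$ts_i$mass_phi
    x <- mesh$nodes[mesh$intra_nodes, 1]
    C <- exact(x, t0)
    dt <- 0.002 * (h / 0.25)^2              # fixed Fourier number
    t <- t0
    while (t < t1 - 1e-12) {
      C <- C - dt * as.vector(K %*% C) / m
      t <- t + dt
    }
    sqrt(mean((C - exact(x, t))^2))
  })
  expect_lt(err[2], 1e-3)
  order <- log2(err[1] / err[2])
  expect_gt(order, 1.5)
})

test_that("a Boltzmann-distributed ion is stationary under a fixed potential", {
  mesh <- box_mesh(8, 1, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  sp <- mod$params$species
  RTF <- mod$params$constants$RT_F
  x <- mesh$nodes[mesh$intra_nodes, 1]
  dPsi <- 0.5                             # mV across the bar
  Psi <- dPsi * x / max(x)
  a <- which(sp$name == "K")
  C <- 10 * exp(-sp$z[a] * Psi / RTF)
  ## total flux = diffusion + migration; independent row-sum check
  Am <- tricellfem:::migration_operator(mod$ts_i, mesh, mod$params, C, a)
  flux_div <- as.vector((mod$ts_i$K_base * sp$D_cyto[a]) %*% C) +
    as.vector(Am %*% Psi)
  expect_lt(max(abs(flux_div)) / max(abs((mod$ts_i$K_base * sp$D_cyto[a]) %*% x)),
            1e-4)
  ## and the stationarity tightens quadratically as the gradient shrinks
  C2 <- 10 * exp(-sp$z[a] * (Psi / 8) / RTF)
  Am2 <- tricellfem:::migration_operator(mod$ts_i, mesh, mod$params, C2, a)
  flux2 <- as.vector((mod$ts_i$K_base * sp$D_cyto[a]) %*% C2) +
    as.vector(Am2 %*% (Psi / 8))
  expect_lt(max(abs(flux2)), max(abs(flux_div)) / 16)
})

test_that("a two-compartment fixed-charge system reaches the Donnan equilibrium", {
  ## 1-D bar, left half carries fixed charge C_F, 1:1 electrolyte (K, Cl
  ## mobile); closed forms: C+ = -C_F/2 + sqrt((C_F/2)^2 + C_out^2) and
  ## dPsi = -RT/F ln(C+_in / C+_out)
  n <- 8
  mesh <- box_mesh(n, 1, 1)
  CFv <- ifelse(mesh$nodes[mesh$intra_nodes, 1] < 2 - 1e-9, -40,
                ifelse(mesh$nodes[mesh$intra_nodes, 1] > 2 + 1e-9, 0, -20))
  C0 <- 100
  mod <- build_model(mesh, subcell = inert_subcell(),
                     conductances = zero_conductances(),
                     C_i0 = c(Na = 0, K = C0 + 20, Ca = 0, Cl = C0,
                              ATP = 0, ADP = 0, Cr = 0, CrP = 0, Pi = 0),
                     CF_i0 = 0)
  ## start electroneutral per node: K = Cl - CF
  mod$state$Ci[, "K"] <- C0 - CFv
  mod$CF_i <- CFv
  st <- advance_electrical(mod, t_end = 120, refresh_every = 0.5)
  x <- mesh$nodes[mesh$intra_nodes, 1]
  Kin <- mean(st$Ci[x < 0.26, "K"]); Kout <- mean(st$Ci[x > 3.74, "K"])
  Clin <- mean(st$Ci[x < 0.26, "Cl"]); Clout <- mean(st$Ci[x > 3.74, "Cl"])
  dPsi <- mean(st$Psi_i[x < 0.26]) - mean(st$Psi_i[x > 3.74])
  RTF <- mod$params$constants$RT_F
  Kp_exact <- 40 / 2 + sqrt((40 / 2)^2 + Clout * Kout)
  expect_equal(Kin, Kp_exact, tolerance = 0.005)
  expect_equal(dPsi, -RTF * log(Kin / Kout), tolerance = 0.005)
  ## Donnan exclusion of the co-ion and the product rule K*Cl = const
  expect_lt(Clin, Clout)
  expect_equal(Kin * Clin, Kout * Clout, tolerance = 0.01)
})

test_that("uniform pressure, concentration and potential give zero Darcy flow", {
  mesh <- small_mesh()
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  st <- mod$state
  st$P <- rep(3.7, mech$E)
  dd <- tricellfem:::darcy_drive(mod, mech, st)
  W <- tricellfem:::gradFV_pairs(mech, st$P, dd$Ct_e, dd$Ps_e, dd$CF_e,
                                 mod$params)
  expect_lt(max(abs(W)), 1e-14)
  expect_lt(max(abs(dd$drive)), 1e-14)
})

test_that("Darcy flow matches the closed form for a pressure gradient", {
  ## prescribed linear pressure along x: W = -K dP/dx uniformly
  mesh <- box_mesh(6, 2, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  st <- mod$state
  xc <- (mech$ijk[, 1] + 0.5) * mesh$h
  p0 <- 50
  L <- 3
  st$P <- p0 * (1 - xc / L)
  dd <- tricellfem:::darcy_drive(mod, mech, st)
  W <- tricellfem:::gradFV_pairs(mech, st$P, dd$Ct_e * 0, dd$Ps_e, dd$CF_e * 0,
                                 mod$params)
  expect_equal(W[, 1], rep(mod$params$K_perm * p0 / L, mech$E),
               tolerance = 1e-10)
  expect_lt(max(abs(W[, 2:3])), 1e-14)
})

test_that("osmotic permeation balances RT(1-phi) grad C against friction", {
  ## zero pressure difference, linear concentration profile: steady
  ## W = -K RT(1-phi) dC/dx
  mesh <- box_mesh(6, 1, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  st <- mod$state
  xc <- (mech$ijk[, 1] + 0.5) * mesh$h
  dC <- 20                                  # mM over the bar length
  st$Ci[, "Cr"] <- st$Ci[, "Cr"] + dC * mesh$nodes[mesh$intra_nodes, 1] / 3
  dd <- tricellfem:::darcy_drive(mod, mech, st)
  W <- tricellfem:::gradFV_pairs(mech, numeric(mech$E), dd$Ct_e, dd$Ps_e,
                                 dd$CF_e * 0, mod$params)
  RT1p <- mod$params$constants$RT_kPa * (1 - mod$params$phi_osm)
  expect_equal(W[, 1], rep(-mod$params$K_perm * RT1p * dC / 3, mech$E),
               tolerance = 1e-8)
})

test_that("charge is injected and conserved globally after the potential re-solve", {
  mesh <- small_mesh()
  mod <- build_model(mesh, subcell = inert_subcell())
  z <- mod$params$species$z
  q0 <- sum((mod$state$Ci %*% z) * mod$ts_i$mass_phi)
  ## inject K at one interior node, then advance; total intracellular
  ## charge changes only by the injection and membrane currents
  mod$state$Ci[50, "K"] <- mod$state$Ci[50, "K"] + 5
  st <- advance_electrical(mod, t_end = 1,
                           stim_fn = NULL)
  q1 <- sum((st$Ci %*% z) * mod$ts_i$mass_phi)
  injected <- 5 * mod$ts_i$mass_phi[50]
  memb <- sum(st$cum_memb * z)
  expect_equal(q1 - q0 - memb, injected, tolerance = 1e-6 * abs(q0))
})
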