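Ci1 <- matrix(c(10, 140, 1e-4, 20), 1, 4,
              dimnames = list(NULL, c("Na", "K", "Ca", "Cl")))
Ce1 <- matrix(c(140, 5.4, 1.8, 126), 1, 4,
              dimnames = list(NULL, c("Na", "K", "Ca", "Cl")))
dens1 <- matrix(1, 1, 6, dimnames = list(NULL, tricellfem:::current_names))

test_that("currents vanish at their reversal potentials and with closed gates", {
  cst <- phys_constants()
  E_Na <- nernst(Ce1[, "Na"], Ci1[, "Na"], 1)
  g <- ionic_state_init(1, -85)
  cur <- compute_ionic_currents(g, E_Na, Ci1, Ce1, dens1)
  expect_equal(unname(cur$I[, "I_Na"]), 0)
  ## all gates zero -> all gated currents zero
  g0 <- g; g0[] <- 0
  cur0 <- compute_ionic_currents(g0, -20, Ci1, Ce1, dens1)
  expect_equal(unname(cur0$I[, c("I_Na", "I_CaL", "I_K")]),
               c(0, 0, 0))
  ## zero densities -> zero currents
  curz <- compute_ionic_currents(g, -20, Ci1, Ce1, dens1 * 0)
  expect_equal(max(abs(curz$I)), 0)
})

test_that("reversal potentials reject non-positive concentrations", {
  expect_error(nernst(0, 1, 1), "non-positive")
  expect_error(nernst(1, -2, 2), "non-positive")
})

test_that("the stimulus is a -100 A/F box pulse of 0.5 ms with exact integral", {
  expect_equal(apply_stimulus(0.25, onset = 0), -100)
  expect_equal(apply_stimulus(0.7, onset = 0), 0)
  expect_equal(apply_stimulus(-0.1, onset = 0), 0)
  for (dt in c(0.01, 0.005, 0.002)) {
    tt <- seq(0, 1 - dt, by = dt)
    expect_equal(sum(vapply(tt, apply_stimulus, 0, onset = 0)) * dt / 1000,
                 -0.05, tolerance = 1e-12)
  }
})

test_that("the lumped potential integrates the area-weighted current", {
  area <- c(1, 2, 3)
  ## uniform current: dV/dt = -I0
  expect_equal(lumped_potential_step(rep(4, 3), area, 0.01), -0.04)
  ## heterogeneous currents summing to zero over the cell
  I <- c(6, 0, -2)                      # sum(I * area) = 0
  expect_equal(lumped_potential_step(I, area, 0.5), 0)
  ## stimulus only, -100 A/F for 0.5 ms -> +50 mV
  V <- 0
  for (k in 1:50) V <- V + lumped_potential_step(rep(-100, 3), area, 0.01)
  expect_equal(V, 50, tolerance = 1e-12)
})

test_that("channel density maps conserve whole-cell conductance", {
  dm <- channel_density_map(c(I_Na = 2, I_CaL = 3), area_surface = 20,
                            area_ttubular = 55)
  for (r in seq_len(nrow(dm))) {
    wm <- (dm$surface[r] * 20 + dm$t_tubular[r] * 55) / 75
    expect_equal(wm, 1, tolerance = 1e-12)
  }
  expect_equal(dm$t_tubular[dm$current == "I_Na"] /
                 dm$surface[dm$current == "I_Na"], 2)
  expect_error(channel_density_map(c(I_Foo = 2), 1, 1), "unknown current")
})

test_that("membrane electroneutrality residuals mirror and cancel", {
  sp <- species_table()
  dC <- stats::setNames(rep(0, nrow(sp)), sp$name)
  ## no current, no concentration change -> dV/dt = 0 solves both sides
  r <- membrane_electroneutrality_residuals(dC, dC, 0, 0, 0.833, 1.0,
                                            I_total = 0, dVdt = 0,
                                            volume_i = 1, volume_e = 1,
                                            area = 1)
  expect_equal(unname(r), c(0, 0))
  ## membrane terms cancel in the sum for any current and dV/dt
  r2 <- membrane_electroneutrality_residuals(dC, dC, 0, 0, 0.833, 1.0,
                                             I_total = -37, dVdt = 12,
                                             volume_i = 2, volume_e = 3,
                                             area = 0.7)
  expect_equal(sum(r2), 0)
})

test_that("gates stay inside [0,1] for any step size and follow the closed form", {
  g <- ionic_state_init(3, -85)
  for (dt in c(1e-3, 0.1, 5, 100)) {
    g2 <- tricellfem:::gates_step(g, c(-90, 0, 40), dt)
    expect_true(all(g2 >= 0 & g2 <= 1))
  }
  ## Rush-Larsen is exact for frozen V: compare against the analytic gate
  gr <- tricellfem:::gate_rates(-30)
  m0 <- 0.2; dt <- 0.37
  gm <- tricellfem:::gates_step(matrix(m0, 1, 1, dimnames = list(NULL, "m")),
                                -30, dt)
  expect_equal(unname(gm[1, 1]),
               gr$m_inf + (m0 - gr$m_inf) * exp(-dt / gr$tau_m),
               tolerance = 1e-12)
})

test_that("a single-ion membrane relaxes to the Nernst potential", {
  ## 1x1x1 intracellular element with a bath shell; only the K-selective
  ## inward rectifier is conducting; concentrations effectively clamped by
  ## the bath and the short run
  mesh <- suppressWarnings(build_mesh(
    cell_geometry_spec(segment_length = 0.5, cross_section = c(0.5, 0.5),
                       n_myofibrils = 0, t_tubule_paths = list(),
                       extracellular_shell_thickness = 0.5),
    compartment_fractions(0, 0, 1, 0, 0)))
  mod <- build_model(mesh, conductances = zero_conductances("g_K1"),
                     subcell = inert_subcell(), V0 = -70)
  st <- advance_electrical(mod, t_end = 60)
  V <- st$Psi_i[mod$memb$idof] - st$Psi_e[mod$memb$edof]
  E_K <- phys_constants()$RT_F *
    log(st$Ce[mod$memb$edof[1], "K"] / st$Ci[mod$memb$idof[1], "K"])
  expect_lt(max(abs(V - E_K)), 0.1)
})

test_that("membrane charge and species bookkeeping agree (two-box)", {
  mesh <- suppressWarnings(build_mesh(
    cell_geometry_spec(segment_length = 0.5, cross_section = c(0.5, 0.5),
                       n_myofibrils = 0, t_tubule_paths = list(),
                       extracellular_shell_thickness = 0.5),
    compartment_fractions(0, 0, 1, 0, 0)))
  mod <- build_model(mesh, subcell = inert_subcell())
  n_i0 <- sum(mod$state$Ci[, "Na"] * mod$ts_i$mass_phi)
  k_i0 <- sum(mod$state$Ci[, "K"] * mod$ts_i$mass_phi)
  st <- advance_electrical(mod, t_end = 5,
                           stim_fn = function(t) apply_stimulus(t, onset = 0.5))
  ## every coulomb through the membrane appears as a matching species change
  dNa <- sum(st$Ci[, "Na"] * mod$ts_i$mass_phi) - n_i0
  dK <- sum(st$Ci[, "K"] * mod$ts_i$mass_phi) - k_i0
  expect_equal(dNa, unname(st$cum_memb["Na"]), tolerance = 1e-8)
  expect_equal(dK, unname(st$cum_memb["K"]), tolerance = 1e-8)
})
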