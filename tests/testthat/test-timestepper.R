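test_that("an exact equilibrium is preserved by the multirate loop", {
  ## uniform fields, passive membrane, no reactions, no stimulus: nothing
  ## may move over 100 ms of multirate stepping
  mesh <- small_mesh()
  mod <- build_model(mesh, conductances = zero_conductances(),
                     subcell = inert_subcell(), V0 = -80)
  st0 <- mod$state
  st <- advance_cycle(mod, t_end = 100,
                      cfg = stepping_config(output_stride = 10000L))
  expect_lt(max(abs(st$Ci - st0$Ci)), 1e-8)
  expect_lt(max(abs(st$Ce - st0$Ce)), 1e-8)
  expect_lt(max(abs((st$Psi_i[mod$memb$idof] - st$Psi_e[mod$memb$edof]) -
                      (-80))), 1e-5)
  expect_lt(max(abs(st$U)), 1e-10)
})

test_that("the stepping configuration validates its invariants", {
  expect_error(stepping_config(dt_mech = 0.5, dt_elec = 1), "dt_mech")
  expect_error(stepping_config(dt_chem_max = 1e-5, dt_chem_min = 1e-2))
  expect_error(stepping_config(dt_mech = 1, dt_elec = 0.3), "multiple")
})

test_that("adaptive chemistry accepts at dt_max for mild dynamics and shrinks under stiffness", {
  mesh <- small_mesh()
  mod <- build_model(mesh)
  y <- tricellfem:::chem_pack(mod$state, mod$subcell)
  ## near-diastolic state: a full-size step is accepted
  st1 <- adaptive_chemistry_step(mod, y, dt_try = 1e-2)
  expect_true(st1$accepted)
  expect_equal(st1$dt_used, 1e-2)
  ## a stiff state (open RyRs, emptying stores) forces error control to act
  y2 <- y
  y2$o[] <- 1
  y2$Ca[mod$site_idof] <- 0.05        # elevated total Ca at the sites
  st2 <- adaptive_chemistry_step(mod, y2, dt_try = 1e-2, rtol = 1e-6)
  expect_true(st2$dt_next < 1e-2 || !st2$accepted)
  ## step bounds respected
  st3 <- adaptive_chemistry_step(mod, y2, dt_try = 1e-5, rtol = 1e-10)
  expect_gte(st3$dt_next, 1e-5)
  expect_lte(st3$dt_next, 1e-2)
})

test_that("chemistry error scales with the controller tolerance", {
  ## global error of the Ca relaxation against a deSolve oracle, at two
  ## tolerances: tighter tolerance may not increase the error
  mesh <- small_mesh()
  mod <- build_model(mesh)
  run_chem <- function(rtol) {
    st <- mod$state
    st$Ci[, "Ca"] <- 4e-4                      # perturbed free Ca
    ctrl <- stepping_config(rtol_chem = rtol)
    for (k in 1:200) {
      ch <- tricellfem:::chem_advance(mod, st, 1e-2, ctrl)
      st <- ch$state; ctrl <- ch$ctrl
    }
    st$Ci[, "Ca"]
  }
  loose <- run_chem(0.05)
  tight <- run_chem(1e-4)
  ## oracle: the same 2 ms integrated by deSolve at tight tolerance
  st <- mod$state
  st$Ci[, "Ca"] <- 4e-4
  y0 <- tricellfem:::chem_pack(st, mod$subcell)
  unpack_len <- vapply(y0, length, 0L)
  rhs <- function(t, y, p) {
    yy <- utils::relist(y, y0)
    f <- tricellfem:::chem_rhs(mod, yy)
    list(unlist(f[names(y0)]))
  }
  out <- deSolve::ode(unlist(y0), c(0, 2), rhs, NULL,
                      rtol = 1e-9, atol = 1e-12)
  ref <- tricellfem:::ca_free_of_total(utils::relist(out[2, -1], y0)$Ca,
                                       mod$subcell)
  expect_lte(max(abs(tight - ref)), max(abs(loose - ref)) + 1e-12)
  expect_lt(max(abs(tight - ref)), 5e-6)
})

test_that("halving the splitting steps changes the potential trace at first order", {
  mesh <- small_mesh()
  run <- function(dt_mech, dt_elec) {
    mod <- build_model(mesh)
    vs <- c()
    obs <- function(st) vs <<- c(vs, mean(st$V_memb))
    cfg <- stepping_config(dt_mech = dt_mech, dt_elec = dt_elec,
                           dt_chem_max = dt_elec,
                           output_stride = round(1 / dt_elec))
    advance_cycle(mod, t_end = 10, cfg = cfg,
                  stim_fn = function(t) apply_stimulus(t, onset = 1),
                  observer = obs)
    vs
  }
  v1 <- run(1, 1e-2)
  v2 <- run(0.5, 5e-3)
  v4 <- run(0.25, 2.5e-3)
  d12 <- sqrt(mean((v1 - v2)^2)); d24 <- sqrt(mean((v2 - v4)^2))
  order <- log2(d12 / d24)
  expect_gt(order, 0.9)
  expect_lt(d12, 1)                      # mV, already close at the default
})

test_that("conservation: closed-system species mass and charge are constant", {
  ## no shell (no bath Dirichlet), no truss, passive membrane-free box with
  ## an interior concentration disturbance
  mesh <- box_mesh(4, 4, 2)
  mod <- build_model(mesh, subcell = inert_subcell())
  mod$state$Ci[10, "K"] <- mod$state$Ci[10, "K"] + 10
  mod$state$Ci[10, "Cl"] <- mod$state$Ci[10, "Cl"] + 10
  m <- mod$ts_i$mass_phi
  tot0 <- colSums(mod$state$Ci * m)
  z <- mod$params$species$z
  q0 <- sum((mod$state$Ci %*% z) * m)
  st <- advance_electrical(mod, t_end = 100, refresh_every = 1)
  tot1 <- colSums(st$Ci * m)
  expect_lt(max(abs(tot1 - tot0) / pmax(tot0, 1e-12)), 1e-6)
  q1 <- sum((st$Ci %*% z) * m)
  expect_lt(abs(q1 - q0) / abs(q0 + 1e-30), 1e-9)
})

test_that("conservation: electroneutrality, fluid volume and Ca bookkeeping on a debug run", {
  mesh <- small_mesh()
  mod <- build_model(mesh)
  inv0 <- ca_inventory(mod, mod$state)
  cfg <- stepping_config(debug_checks = TRUE, output_stride = 1000L)
  st <- advance_cycle(mod, t_end = 20, cfg = cfg,
                      stim_fn = function(t) apply_stimulus(t, onset = 1))
  ## per-node transport electroneutrality at every accepted electrical step
  expect_lt(st$eln_max, 1e-6)
  ## mixture incompressibility at every accepted mechanics step
  expect_lt(st$incomp_max, 1e-6)
  ## total Ca: the change of the intracellular pools equals the membrane
  ## exchange, to 1e-6 of the inventory
  inv1 <- ca_inventory(mod, st)
  gained <- inv1[["total_intra"]] - inv0[["total_intra"]]
  expect_lt(abs(gained - st$cum_memb[["Ca"]] - st$cum_adv[["Ca"]]),
            1e-6 * inv0[["total_intra"]])
  ## global fluid budget: lumen storage balances the integrated mouth
  ## outflow (network conservation); element-level volume bookkeeping is
  ## covered by the incompressibility residual above
  fb <- open_end_coupling(mod, st)
  expect_lt(abs(fb[["lumen_storage"]] + fb[["mouth_outflow_integral"]]),
            1e-6 * max(abs(fb)) + 1e-12)
})
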