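## Mechanics: momentum residual against an independent finite-difference
## energy oracle, equilibrium of the reference configuration, the
## compressibility closure, incompressibility bookkeeping and the
## isometric / free boundary modes.

## independent oracle: total stored energy of the neo-Hookean solid plus
## pressure and active work terms, evaluated by straight quadrature
energy_oracle <- function(model, mech, U, P_w, T_a) {
  ref <- model$ts_i$ref
  mu <- mech$mu; kappa <- model$params$kappa_S
  Ue <- matrix(U[t(mech$conn_u)], nrow = 24)
  Etot <- 0
  for (q in 1:8) {
    dN <- ref$dN_gp[q, , ]
    for (e in seq_len(mech$E)) {
      Fm <- diag(3)
      for (a in 1:8)
        Fm <- Fm + Ue[3 * (a - 1) + 1:3, e] %o% dN[a, ]
      J <- det(Fm)
      I1 <- sum(Fm^2)
      psi <- mu / 2 * (I1 - 3) - mu * log(J) + kappa / 2 * (J - 1)^2
      ## fluid pressure potential: -P_w (J - 1); active: T_a/2 |F e_z|^2
      psi <- psi - P_w[e] * (J - 1) + T_a[e] / 2 * sum(Fm[, 3]^2)
      Etot <- Etot + psi * ref$detJ
    }
  }
  Etot
}

test_that("momentum residual matches the finite-difference energy gradient", {
  mesh <- box_mesh(1, 1, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "rigid", 1.0)
  set.seed(3)
  U <- stats::rnorm(mech$nU, sd = 0.02)
  P_w <- stats::runif(mech$E, -1, 1)
  T_a <- stats::runif(mech$E, 0, 5)
  f <- tricellfem:::neo_internal_force(mech, mod$ts_i$ref, U, P_w, T_a,
                                       mech$mu, mod$params$kappa_S)
  h0 <- 1e-6
  for (j in sample(mech$nU, 6)) {
    Up <- U; Up[j] <- Up[j] + h0
    Um <- U; Um[j] <- Um[j] - h0
    dE <- (energy_oracle(mod, mech, Up, P_w, T_a) -
             energy_oracle(mod, mech, Um, P_w, T_a)) / (2 * h0)
    expect_equal(f[j], dE, tolerance = 1e-6)
  }
})

test_that("the reference configuration is in equilibrium", {
  mesh <- box_mesh(2, 2, 2)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  r <- mixture_momentum_residual(mod, mech, numeric(mech$nU))
  expect_lt(max(abs(r$momentum)), 1e-12)
  expect_lt(max(abs(r$compressibility)), 1e-12)
  expect_equal(r$J, rep(1, mech$E))
})

test_that("solid compressibility holds by construction and detects mismatched P_S", {
  mesh <- box_mesh(2, 1, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "rigid", 1.0)
  ## uniform expansion u = eps/3 * x gives J ~ 1 + eps
  eps <- 3e-3
  X <- mesh$nodes[mesh$intra_nodes, ]
  U <- as.vector(t(X * eps / 3))
  r <- mixture_momentum_residual(mod, mech, U)
  expect_equal(r$J, rep(1 + eps, mech$E), tolerance = 1e-5)
  expect_lt(max(abs(r$compressibility)), 1e-12)   # consistent P_S
  r2 <- mixture_momentum_residual(mod, mech, U, P_S = rep(0, mech$E))
  expect_equal(r2$compressibility, r2$J - 1, tolerance = 1e-12)
})

test_that("element inversion raises a diagnostic with the element id", {
  mesh <- box_mesh(1, 1, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "rigid", 1.0)
  U <- numeric(mech$nU)
  ## collapse the element along z
  zt <- which(mesh$nodes[mesh$intra_nodes, 3] > 0.25)
  U[3 * (zt - 1) + 3] <- -0.6
  expect_error(
    tricellfem:::neo_internal_force(mech, mod$ts_i$ref, U, numeric(1),
                                    numeric(1), mech$mu, 25),
    "element inversion.*element 1")
})

test_that("momentum residual is objective under rigid translation", {
  mesh <- box_mesh(2, 2, 1)
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "rigid", 1.0)
  set.seed(5)
  U <- stats::rnorm(mech$nU, sd = 0.01)
  P_w <- stats::runif(mech$E); T_a <- stats::runif(mech$E, 0, 2)
  r1 <- tricellfem:::neo_internal_force(mech, mod$ts_i$ref, U, P_w, T_a,
                                        mech$mu, 25)
  Ut <- U + rep(c(0.3, -0.2, 0.1), mech$nU / 3)
  r2 <- tricellfem:::neo_internal_force(mech, mod$ts_i$ref, Ut, P_w, T_a,
                                        mech$mu, 25)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("incompressibility residual vanishes at accepted steps of a loaded solve", {
  mesh <- small_mesh()
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  mod$cache$mech <- mech
  st <- mod$state
  st$act <- rep(0, length(mod$myo_e))
  ## ramp activation on the z-line layer only (z-gradient loads the solid)
  lay0 <- intersect(mod$myo_e, which(mech$ijk[, 3] == 0))
  for (k in 1:3) {
    st$act[match(lay0, mod$myo_e)] <- 0.1 * k
    st <- tricellfem:::mech_step(mod, mech, st, n_newton = 6)
  }
  expect_gt(max(abs(st$U)), 1e-5)            # something deformed
  r <- incompressibility_residual(mod, st)
  expect_lt(max(abs(r)), 1e-6)
  ## fluid momentum closure: the stored Darcy velocity satisfies its law
  expect_lt(max(abs(fluid_momentum_residual(mod, mech, st))), 1e-12)
})

test_that("isometric ends stay fixed and free ends move as a plane", {
  mesh <- small_mesh()
  for (bc in c("isometric", "free")) {
    mod <- build_model(mesh, subcell = inert_subcell())
    mech <- tricellfem:::mech_init(mod, bc, 1.0)
    st <- mod$state
    st$act <- rep(0, length(mod$myo_e))
    lay0 <- intersect(mod$myo_e, which(mech$ijk[, 3] == 0))
    st$act[match(lay0, mod$myo_e)] <- 0.4
    st <- tricellfem:::mech_step(mod, mech, st, n_newton = 6)
    nd <- mesh$nodes[mesh$intra_nodes, ]
    mline <- which(abs(nd[, 3] - mesh$L["Lz"]) < 1e-9)
    uz <- st$U[3 * (mline - 1) + 3]
    if (bc == "isometric") {
      expect_lt(max(abs(uz)), 1e-14)         # cell length fixed exactly
    } else {
      expect_lt(diff(range(uz)), 1e-12)      # planar motion, one DOF
      expect_gt(max(abs(uz)), 1e-8)          # and the plane actually moves
    }
  }
})

test_that("quiescent mechanics stays at rest (uniform fields, no tension)", {
  mesh <- small_mesh()
  mod <- build_model(mesh, subcell = inert_subcell())
  mech <- tricellfem:::mech_init(mod, "isometric", 1.0)
  st <- mod$state
  for (k in 1:3) st <- tricellfem:::mech_step(mod, mech, st)
  expect_lt(max(abs(st$U)), 1e-10)
  expect_lt(max(abs(st$P)), 1e-10)
  expect_lt(abs(st$cum_mouth), 1e-10)
})

test_that("newton_solve converges quadratically near a root and reports failures", {
  f <- function(x) c(x[1]^2 - 4, x[1] * x[2] - 2)
  sol <- newton_solve(f, c(3, 2))
  expect_equal(sol$x, c(2, 1), tolerance = 1e-8)
  ## converged input returns immediately
  sol2 <- newton_solve(f, sol$x)
  expect_lte(sol2$iterations, 1)
  ## linear problem: one iteration
  A <- matrix(c(2, 1, 0, 3), 2)
  g <- function(x) as.vector(A %*% x - c(1, 2))
  sol3 <- newton_solve(g, c(5, 5), jacobian = A)
  expect_lte(sol3$iterations, 1 + 1)
  expect_error(newton_solve(function(x) x^2 + 1, 0.5, max_iter = 8),
               "did not converge")
})
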