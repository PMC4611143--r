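## Shared fixtures: small meshes and models built in code.

## a small quarter-section mesh with shell, tubules and all compartments
small_mesh <- function(seed = 1L, ...) {
  suppressWarnings(build_mesh(
    cell_geometry_spec(cross_section = c(6, 6), n_myofibrils = 9,
                       mito_placement_seed = seed, ...)))
}

## a bare box of pure cytosol: nx x ny x nz elements, no shell, no tubules
box_mesh <- function(nx = 4, ny = 1, nz = 1, h = 0.5) {
  suppressWarnings(build_mesh(
    cell_geometry_spec(segment_length = nz * h,
                       cross_section = c(nx * h, ny * h),
                       n_myofibrils = 0, element_size = h,
                       t_tubule_paths = list(),
                       extracellular_shell_thickness = 0),
    compartment_fractions(0, 0, 1, 0, 0)))
}

## model on a bare box with no membranes; optionally single-species setup
box_model <- function(mesh, C_i0 = NULL, ...) {
  build_model(mesh, mode = "triphasic", C_i0 = C_i0, ...)
}

## subcellular reactions switched off (pure transport oracles)
inert_subcell <- function() {
  sc <- subcell_params()
  sc$ryr_k_open <- 0; sc$g_rel <- 0; sc$serca_Vmax <- 0; sc$leak_rate <- 0
  sc$refill_rate <- 0; sc$mito_V_uni <- 0; sc$mito_V_ncx <- 0
  sc$buf_Bmax <- 0
  sc
}

## conductances all zero (passive membrane)
zero_conductances <- function(except = NULL, value = NULL) {
  g <- ionic_conductances()
  g[] <- 0
  if (!is.null(except)) g[except] <- value %||% ionic_conductances()[except]
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## advance only the electrical/chemical system (frozen geometry)
advance_electrical <- function(model, t_end, dt = 1e-2, stim_fn = NULL,
                               clamp = NULL, refresh_every = 1,
                               chem = FALSE) {
  state <- model$state
  ctrl <- stepping_config(dt_mech = refresh_every, dt_elec = dt)
  n <- round(t_end / dt)
  per <- round(refresh_every / dt)
  for (k in seq_len(n)) {
    if ((k - 1) %% per == 0)
      tricellfem:::refresh_cache(model, state, dt, clamp)
    state <- tricellfem:::elec_step(model, state, dt, ctrl,
                                    stim_fn = stim_fn, clamp = clamp)
    ctrl <- attr(state, "ctrl")
  }
  state
}
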