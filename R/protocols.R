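## End-to-end simulation protocols: paced twitches (isometric or free),
## voltage-clamp solution-switch experiments, field stimulation, and the
## triphasic-versus-reaction-diffusion comparison.

#' Protocol configuration
#'
#' @param mode one of \code{isometric_twitch}, \code{free_twitch},
#'   \code{voltage_clamp_switch_K}, \code{voltage_clamp_switch_Ca},
#'   \code{field_stimulation}, \code{comparison_rd}.
#' @param duration simulated time, ms.
#' @param pacing_rate pacing frequency, Hz (twitch modes).
#' @param stim_onset first stimulus onset, ms.
#' @param bath_schedule list(species =, from =, to =, t_switch =) for the
#'   solution-switch protocols (defaults per mode: K+ 5.4 -> 8.1 mM, or
#'   Ca2+ 0.45 -> 1.8 mM).
#' @param clamp_hold,clamp_test holding / test potential, mV.
#' @param clamp_step time of the step to the test potential, ms (NA = hold
#'   throughout).
#' @param field_amplitude,field_window boundary potential offset (mV) and
#'   c(start, end) times for field stimulation.
#' @param seed RNG seed recorded with the run.
#' @param output_stride observable sampling stride, in electrical steps.
#' @param track_decomposition record the transport-term decomposition.
#' @return list of class \code{protocol_config}.
#' @export
protocol_config <- function(mode = c("isometric_twitch", "free_twitch",
                                     "voltage_clamp_switch_K",
                                     "voltage_clamp_switch_Ca",
                                     "field_stimulation", "comparison_rd"),
                            duration = 300,
                            pacing_rate = 1,
                            stim_onset = 1,
                            bath_schedule = NULL,
                            clamp_hold = -80, clamp_test = 0,
                            clamp_step = NA,
                            field_amplitude = 12, field_window = c(5, 10),
                            seed = 1L,
                            output_stride = 100L,
                            track_decomposition = FALSE) {
  mode <- match.arg(mode)
  if (is.null(bath_schedule)) {
    bath_schedule <- switch(mode,
      voltage_clamp_switch_K = list(species = "K", from = 5.4, to = 8.1,
                                    t_switch = 10),
      voltage_clamp_switch_Ca = list(species = "Ca", from = 0.45, to = 1.8,
                                     t_switch = 10),
      NULL)
  }
  if (mode == "voltage_clamp_switch_Ca" && missing(clamp_hold)) clamp_hold <- -45
  structure(list(mode = mode, duration = duration, pacing_rate = pacing_rate,
                 stim_onset = stim_onset, bath_schedule = bath_schedule,
                 clamp_hold = clamp_hold, clamp_test = clamp_test,
                 clamp_step = clamp_step,
                 field_amplitude = field_amplitude,
                 field_window = field_window,
                 seed = as.integer(seed),
                 output_stride = as.integer(output_stride),
                 track_decomposition = track_decomposition),
            class = "protocol_config")
}

## observable recorder shared by the protocols
make_recorder <- function(model, cfg) {
  mesh <- model$mesh
  env <- new.env(parent = emptyenv())
  env$rows <- list(); env$decomp <- list(); env$profiles <- list()
  env$delay <- rep(NA_real_, length(model$site_idof))
  env$ca0 <- model$state$Ci[1, "Ca"]
  memb <- model$memb
  surf <- memb$type == "surface"; tub <- memb$type == "t_tubular"
  a_s <- memb$area[surf]; a_t <- memb$area[tub]
  m_i <- model$ts_i$mass_phi

  ## loci along the first t-tubule path (deep = 1 ... mouth), and bundle
  ## center nodes for the per-myofibril observables
  tr <- mesh$truss
  env$path_rows <- integer(0)
  if (nrow(tr$nodes) > 0) {
    pr <- which(tr$nodes$path == tr$nodes$path[1])
    env$path_rows <- pr[order(tr$nodes$arc[pr])]
    ## membrane pair of each path node (NA at the mouth)
    tpair <- which(memb$type == "t_tubular")
    env$path_pair <- tpair[match(tr$nodes$edof[env$path_rows],
                                 memb$edof[tpair])]
  }
  env$bundle_node <- integer(0)
  cb <- mesh$col_info
  if (any(!is.na(cb$bundle))) {
    for (b in sort(unique(stats::na.omit(cb$bundle)))) {
      sel <- cb$bundle == b & !is.na(cb$bundle)
      cx <- round(mean(cb$i[sel])) ; cy <- round(mean(cb$j[sel]))
      g <- which(abs(mesh$nodes[, 1] - (cx + 0.5) * mesh$h) < mesh$h / 1.9 &
                   abs(mesh$nodes[, 2] - (cy + 0.5) * mesh$h) < mesh$h / 1.9 &
                   abs(mesh$nodes[, 3] - mesh$L["Lz"] / 2) < mesh$h)
      g <- g[!is.na(mesh$intra_dof[g])]
      if (length(g))
        env$bundle_node <- c(env$bundle_node, mesh$intra_dof[g[1]])
    }
  }

  observer <- function(state) {
    V <- state$V_memb
    Imat <- state$I_last
    cmean <- colSums(state$Ci * m_i) / sum(m_i)
    names(cmean) <- paste0("Cmean_", colnames(state$Ci))
    row <- c(t = state$t,
             V_mean = sum(V * memb$area) / sum(memb$area),
             Ca_mean = sum(state$Ci[, "Ca"] * m_i) / sum(m_i),
             cmean,
             Ca_nsr = state$Ca_nsr,
             tension_mean = if (length(state$act)) mean(state$act) *
               model$params$T_max_active else 0,
             I_stim = state$I_stim_last)
    for (cn in colnames(Imat)) {
      row[paste0(cn, "_surf")] <- if (any(surf))
        sum(Imat[surf, cn] * a_s) / sum(a_s) else 0
      row[paste0(cn, "_tt")] <- if (any(tub))
        sum(Imat[tub, cn] * a_t) / sum(a_t) else 0
      row[paste0(cn, "_cell")] <- sum(Imat[, cn] * memb$area) / sum(memb$area)
    }
    if (length(env$bundle_node)) {
      ca_b <- state$Ci[env$bundle_node, "Ca"]
      names(ca_b) <- paste0("Ca_myo", seq_along(ca_b))
      row <- c(row, ca_b)
    }
    nte <- nrow(mesh$truss$elems)
    if (nte > 0) {
      k <- unique(round(seq(1, nte, length.out = 4)))
      wt <- if (!is.null(state$w_truss) && length(state$w_truss))
        state$w_truss[k] else numeric(length(k))
      names(wt) <- paste0("w_truss", seq_along(wt))
      row <- c(row, wt)
    }
    env$rows[[length(env$rows) + 1L]] <- row

    ## release delays: first crossing of 2x diastolic free Ca
    ca_site <- state$Ci[model$site_idof, "Ca"]
    hit <- is.na(env$delay) & ca_site > 2 * env$ca0
    env$delay[hit] <- state$t

    if (!is.null(state$decomp))
      env$decomp[[length(env$decomp) + 1L]] <-
        c(t = state$t, diff = state$decomp$diff, mig = state$decomp$mig,
          conv = state$decomp$conv)

    if (length(env$path_rows) && model$mode == "triphasic") {
      tt <- model$mesh$truss$nodes[env$path_rows, ]
      idof <- model$mesh$intra_dof[tt$gnode]
      edof <- tt$edof
      ina <- rep(NA_real_, length(env$path_pair))
      ok <- !is.na(env$path_pair)
      ina[ok] <- state$I_last[env$path_pair[ok], "I_Na"]
      env$profiles[[length(env$profiles) + 1L]] <-
        list(t = state$t, Psi_i = state$Psi_i[idof],
             Psi_e = state$Psi_e[edof],
             V_m = state$Psi_i[idof] - state$Psi_e[edof],
             arc = tt$arc, I_Na = ina)
    }
    invisible(NULL)
  }
  list(env = env, observer = observer)
}

#' Run a simulation protocol
#'
#' Installs the boundary conditions of the requested mode (symmetry on the
#' center planes; bath concentrations and zero potential fixed on the
#' outermost extracellular plane; isometric or free mechanical ends;
#' Dirichlet clamp potentials for the voltage-clamp modes), builds the
#' model, advances it and collects the observable set.
#'
#' @param mesh a \code{tricell_mesh}.
#' @param params [material_params()].
#' @param cfg [protocol_config()].
#' @param stepping [stepping_config()].
#' @param mode_override force model mode ("triphasic"/"rd").
#' @param ... passed to [build_model()].
#' @return list of class \code{tricell_result}: \code{observables}
#'   (data.frame), \code{delays}, \code{decomp}, \code{profiles},
#'   \code{state}, \code{model}, \code{config}.
#' @export
run_protocol <- function(mesh, params = material_params(),
                         cfg = protocol_config(),
                         stepping = stepping_config(),
                         mode_override = NULL, ...) {
  clamp_mode <- cfg$mode %in% c("voltage_clamp_switch_K",
                                "voltage_clamp_switch_Ca")
  if (clamp_mode && mesh$shell_layers == 0)
    stop("voltage clamp protocols need a mesh with an extracellular shell")
  mmode <- mode_override %||% if (cfg$mode == "comparison_rd") "rd" else "triphasic"

  bs <- cfg$bath_schedule
  C_e0 <- NULL
  if (!is.null(bs)) C_e0 <- stats::setNames(bs$from, bs$species)
  model <- build_model(mesh, params, mode = mmode, C_e0 = C_e0, ...)
  stepping$output_stride <- cfg$output_stride
  stepping$track_decomposition <- cfg$track_decomposition &&
    mmode == "triphasic"

  rec <- make_recorder(model, cfg)

  stim_fn <- NULL; clamp <- NULL; bath_fn <- NULL
  mech <- NULL; mechanics <- TRUE
  if (cfg$mode %in% c("isometric_twitch", "free_twitch", "comparison_rd")) {
    period <- 1000 / cfg$pacing_rate
    onset <- cfg$stim_onset
    stim_fn <- function(t) {
      apply_stimulus((t - onset) %% period + onset, onset = onset)
    }
    bc <- if (cfg$mode == "free_twitch") "free" else "isometric"
    mech <- mech_init(model, bc, stepping$dt_mech)
  } else if (clamp_mode) {
    mechanics <- FALSE
    clamp <- function(t) {
      V <- if (!is.na(cfg$clamp_step) && t >= cfg$clamp_step)
        cfg$clamp_test else cfg$clamp_hold
      apply_voltage_clamp(mesh, V)
    }
    bath_fn <- function(t) {
      if (t >= bs$t_switch) stats::setNames(bs$to, bs$species)
      else stats::setNames(bs$from, bs$species)
    }
  } else if (cfg$mode == "field_stimulation") {
    mechanics <- FALSE
    ## boundary potential offset on one outer plane during the window
    clamp <- function(t) {
      on <- t >= cfg$field_window[1] && t < cfg$field_window[2]
      list(intra_dof = integer(0), intra_val = numeric(0),
           field_offset = if (on) cfg$field_amplitude else 0)
    }
  }

  state <- advance_cycle(model, model$state, t_end = cfg$duration,
                         cfg = stepping, stim_fn = stim_fn, clamp = clamp,
                         bath_fn = bath_fn, mechanics = mechanics,
                         observer = rec$observer, mech = mech)

  obs <- as.data.frame(do.call(rbind, rec$env$rows))
  structure(list(observables = obs,
                 delays = rec$env$delay,
                 decomp = if (length(rec$env$decomp))
                   as.data.frame(do.call(rbind, rec$env$decomp)) else NULL,
                 profiles = rec$env$profiles,
                 state = state, model = model, config = cfg),
            class = "tricell_result")
}

#' @export
print.tricell_result <- function(x, ...) {
  ob <- x$observables
  cat("tricell_result:", x$config$mode, "-", nrow(ob), "samples over",
      max(ob$t), "ms\n")
  cat(sprintf("  V_m mean: [%.1f, %.1f] mV; mean [Ca]: [%.3g, %.3g] mM\n",
              min(ob$V_mean), max(ob$V_mean),
              min(ob$Ca_mean), max(ob$Ca_mean)))
  invisible(x)
}

#' Pre-pace a model toward its limit cycle
#'
#' Runs N full pacing cycles (default 3) and returns the model with its
#' state replaced, approximating the periodic steady state used as the
#' initial condition of analysis runs.
#'
#' @param model a \code{tricell_model}.
#' @param cycles number of pacing cycles.
#' @param pacing_rate Hz.
#' @param stepping [stepping_config()].
#' @return the model with updated \code{$state}.
#' @export
pre_pace <- function(model, cycles = 3, pacing_rate = 1,
                     stepping = stepping_config()) {
  period <- 1000 / pacing_rate
  stim_fn <- function(t) apply_stimulus(t %% period, onset = 1)
  mech <- mech_init(model, "isometric", stepping$dt_mech)
  st <- model$state
  for (k in seq_len(cycles)) {
    st$t <- 0
    st <- advance_cycle(model, st, t_end = period, cfg = stepping,
                        stim_fn = stim_fn, mech = mech)
  }
  st$t <- 0
  model$state <- st
  model
}
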