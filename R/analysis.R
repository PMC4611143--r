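## Analysis operators behind the figure-style outputs: transport-term
## decomposition, triphasic-vs-reaction-diffusion comparison, release-delay
## versus distance, and potential profiles along a t-tubule.

#' Decompose the ion-balance transport terms
#'
#' From a tracked run ([protocol_config()] with
#' \code{track_decomposition = TRUE}): the node-integrated magnitudes of
#' the diffusion, electromigration and convection terms per species over
#' time, and each term's maximum as a percentage of the diffusion-term
#' maximum.
#'
#' @param result a \code{tricell_result}.
#' @param species species to include (default: the four ions).
#' @return list: \code{series} (data.frame over time), \code{summary}
#'   (percent of diffusion maximum per species and term), and scalars
#'   \code{electromigration_pct}, \code{convection_pct} (maxima over the
#'   requested species).
#' @export
decompose_ion_fluxes <- function(result, species = c("Na", "K", "Ca", "Cl")) {
  d <- result$decomp
  dc <- result$state$decomp
  if (is.null(d) || is.null(dc))
    stop("run the protocol with track_decomposition = TRUE")
  summ <- NULL
  for (s in species) {
    dmax <- max(d[[paste0("diff.", s)]])
    mmax <- max(d[[paste0("mig.", s)]])
    cmax <- max(d[[paste0("conv.", s)]])
    summ <- rbind(summ, data.frame(
      species = s,
      diffusion_max = dmax,
      ## instantaneous maxima: electromigration rivals diffusion during the
      ## few ms of depolarization
      peak_electromigration_pct = 100 * mmax / dmax,
      peak_convection_pct = 100 * cmax / dmax,
      ## cycle-integrated contribution to the concentration changes (the
      ## headline percentages)
      electromigration_pct = 100 * dc$int_mig[[s]] / dc$int_diff[[s]],
      convection_pct = 100 * dc$int_conv[[s]] / dc$int_diff[[s]]))
  }
  list(series = d, summary = summ,
       electromigration_pct = max(summ$electromigration_pct),
       convection_pct = max(summ$convection_pct))
}

#' Compare the triphasic model with its reaction-diffusion limit
#'
#' Runs the full triphasic model and the degenerate reaction-diffusion
#' model (electromigration and convection off, lumped membrane potential)
#' on the same mesh and protocol with identical seeds, and reports the
#' maximum relative difference of the spatially averaged concentrations
#' per species over the window.
#'
#' @param mesh a \code{tricell_mesh}.
#' @param params [material_params()].
#' @param cfg [protocol_config()] (a paced twitch).
#' @param stepping [stepping_config()].
#' @param ... passed to [run_protocol()].
#' @return list: \code{per_species} (named max relative differences, %),
#'   \code{max_pct}, and the two results (\code{tri}, \code{rd}).
#' @export
compare_triphasic_vs_rd <- function(mesh, params = material_params(),
                                    cfg = protocol_config("comparison_rd"),
                                    stepping = stepping_config(), ...) {
  cfg_tri <- cfg; cfg_tri$mode <- "isometric_twitch"
  tri <- run_protocol(mesh, params, cfg_tri, stepping,
                      mode_override = "triphasic", ...)
  rd <- run_protocol(mesh, params, cfg_tri, stepping,
                     mode_override = "rd", ...)
  sp <- params$species$name
  per <- avg_concentration_diff(tri, rd, sp)
  list(per_species = per, max_pct = max(per), tri = tri, rd = rd)
}

## max over time of |mean_tri - mean_rd| / mean_rd per species, in percent,
## from the spatially averaged intracellular concentration series
avg_concentration_diff <- function(tri, rd, species) {
  out <- numeric(0)
  for (s in species) {
    a <- tri$observables[[paste0("Cmean_", s)]]
    b <- rd$observables[[paste0("Cmean_", s)]]
    out[s] <- 100 * max(abs(a - b) / pmax(abs(b), 1e-30))
  }
  out
}

#' Release-delay versus membrane-distance analysis
#'
#' Table of JSR release units with their distance to the nearest membrane
#' (surface sarcolemma or t-tubule) and the delay of Ca release after the
#' stimulus (first crossing of twice the diastolic free [Ca]), plus the
#' rank correlation of delay with distance.
#'
#' @param result a \code{tricell_result} from a paced twitch.
#' @param stim_onset stimulus onset used in the run, ms.
#' @return list: \code{table} (site, distance um, delay ms),
#'   \code{rank_correlation}, \code{max_delay_adjacent} (max delay among
#'   units within one element size of a membrane).
#' @export
release_delay_analysis <- function(result, stim_onset = result$config$stim_onset) {
  mesh <- result$model$mesh
  sites <- mesh$release_sites
  delay <- (result$state$release_t %||% result$delays) - stim_onset
  tab <- data.frame(site = seq_len(nrow(sites)),
                    x = sites$x, y = sites$y,
                    distance = sites$dist, delay = delay)
  ok <- !is.na(delay)
  rc <- if (sum(ok) > 2 && stats::sd(tab$distance[ok]) > 0)
    stats::cor(tab$distance[ok], tab$delay[ok], method = "spearman") else NA
  adj <- ok & sites$dist < mesh$h
  list(table = tab,
       rank_correlation = rc,
       max_delay_adjacent = if (any(adj)) max(delay[adj]) else NA,
       n_released = sum(ok))
}

#' Potential profiles along a t-tubule
#'
#' Extracts the intracellular, extracellular (intra-t-tubular) and membrane
#' potential along the recorded tubule path and reports the maximum spatial
#' spread (max - min along the path) of each within a time window after
#' stimulus onset.
#'
#' @param result a \code{tricell_result}.
#' @param window c(start, end) relative to stimulus onset, ms (default the
#'   first 2 ms of depolarization).
#' @param stim_onset stimulus onset, ms.
#' @return list: \code{spread} (named maxima: Psi_i, Psi_e, V_m in mV),
#'   \code{profiles} (the raw profile records within the window).
#' @export
potential_profile_analysis <- function(result, window = c(0, 2),
                                       stim_onset = result$config$stim_onset) {
  pr <- result$profiles
  if (!length(pr)) stop("no tubule profiles recorded (rd mode or no truss)")
  tsel <- vapply(pr, function(p) p$t, 0) - stim_onset
  keep <- which(tsel >= window[1] & tsel <= window[2])
  if (!length(keep)) stop("no profile samples inside the window")
  spread <- c(Psi_i = 0, Psi_e = 0, V_m = 0)
  for (k in keep) {
    p <- pr[[k]]
    spread["Psi_i"] <- max(spread["Psi_i"], diff(range(p$Psi_i)))
    spread["Psi_e"] <- max(spread["Psi_e"], diff(range(p$Psi_e)))
    spread["V_m"] <- max(spread["V_m"], diff(range(p$V_m)))
  }
  ## deep-vs-near-mouth peak Na current along the tubule
  ina <- vapply(pr[keep], function(p) p$I_Na, pr[[keep[1]]]$I_Na)
  peak <- suppressWarnings(apply(-ina, 1, max, na.rm = TRUE))
  arc <- pr[[keep[1]]]$arc
  ok <- is.finite(peak) & peak > 0
  deep <- which.max(arc[ok]); shallow <- which.min(arc[ok])
  ina_reduction <- if (any(ok))
    100 * (1 - peak[ok][deep] / peak[ok][shallow]) else NA
  list(spread = spread, profiles = pr[keep],
       peak_I_Na = data.frame(arc = arc, peak = peak),
       ina_reduction_pct = ina_reduction)
}
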