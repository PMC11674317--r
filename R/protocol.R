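#' Input-drive protocol grid
#'
#' The full protocol crosses 12 scenarios (PD0, PD2, five strengthening
#' levels, five rewiring levels) with 10 input rates (0.5-5 Hz in 0.5 Hz
#' steps) and 6 input correlations (0-0.5 in 0.1 steps): 720 simulation
#' sets. The desk scale keeps the endpoints of each axis (PD0, PD2 and
#' the 100% compensations; 3 rates; 3 correlations) so the qualitative
#' comparisons stay visible at a small fraction of the cost.
#'
#' @param scale `"desk"` (reduced) or `"full"`.
#' @return data.frame with columns `scenario`, `rate`, `correlation`.
#' @export
protocol_grid <- function(scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    scenarios <- c("PD0", "PD2",
                   paste0("PD2_s", c(20, 40, 60, 80, 100)),
                   paste0("PD2_r", c(20, 40, 60, 80, 100)))
    rates <- seq(0.5, 5, by = 0.5)
    correlations <- seq(0, 0.5, by = 0.1)
  } else {
    scenarios <- c("PD0", "PD2", "PD2_s100", "PD2_r100")
    rates <- c(1, 3, 5)
    correlations <- c(0, 0.2, 0.5)
  }
  out <- expand.grid(scenario = scenarios, rate = rates,
                     correlation = correlations,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[order(out$scenario, out$rate, out$correlation), , drop = FALSE]
}

scenario_placement <- function(scenario, pl_pd0, pl_pd2, morph_pd2,
                               n_syn_PD0, seed) {
  if (scenario == "PD0") return(pl_pd0)
  if (scenario == "PD2") return(pl_pd2)
  level <- as.numeric(sub("^PD2_[sr]", "", scenario))
  strategy <- if (grepl("^PD2_s", scenario)) "strengthen" else "rewire"
  spec <- compensation_spec(strategy, level, n_syn_PD0 = n_syn_PD0,
                            n_syn_PD2 = nrow(pl_pd2))
  if (strategy == "strengthen") strengthen(pl_pd2, spec)
  else rewire(pl_pd2, morph_pd2, spec, seed = seed)
}

#' Run the corticostriatal drive protocol
#'
#' For one cell type: places `n_syn_PD0` input synapses on the healthy
#' morphology, derives the surviving PD2 placement, builds each
#' scenario's placement (strengthened or rewired at its level) and
#' simulates the matching surrogate preset under every (rate,
#' correlation) combination of the grid, with `repeats` independent
#' synapse distributions per combination.
#'
#' @param cell_type `"dSPN"` or `"iSPN"`.
#' @param morph_pd0,morph_pd2 healthy and degenerated morphology (same
#'   node ids).
#' @param n_syn_PD0 healthy input synapse count (see
#'   [calibrate_input_count()]).
#' @param grid a [protocol_grid()].
#' @param repeats synapse-distribution repeats per combination.
#' @param duration stimulation length per simulation, s.
#' @param seed integer seed.
#' @return data.frame with one row per (scenario, rate, correlation,
#'   repeat): columns `scenario`, `rate`, `correlation`, `rep`,
#'   `n_sites`, `output_rate`.
#' @export
run_drive_protocol <- function(cell_type = c("dSPN", "iSPN"),
                               morph_pd0, morph_pd2, n_syn_PD0,
                               grid = protocol_grid("desk"), repeats = 2L,
                               duration = 3, seed = 1L) {
  cell_type <- match.arg(cell_type)
  rows <- vector("list", nrow(grid) * repeats)
  k <- 0L
  for (r in seq_len(repeats)) {
    pl_seed <- seed + 101L * r
    pl_pd0 <- place_synapses(morph_pd0, n_syn_PD0, seed = pl_seed)
    pl_pd2 <- filter_placement(pl_pd0, morph_pd2)
    for (i in seq_len(nrow(grid))) {
      sc <- grid$scenario[i]
      neuron <- surrogate_neuron(paste0(
        cell_type, if (sc == "PD0") "_PD0" else "_PD2"))
      pl <- scenario_placement(sc, pl_pd0, pl_pd2, morph_pd2,
                               n_syn_PD0, seed = pl_seed + 13L)
      tr <- correlated_spike_trains(nrow(pl), grid$rate[i],
                                    grid$correlation[i], duration,
                                    seed = seed + 1000L * r + i)
      sim <- simulate_surrogate(neuron, pl, tr, duration)
      k <- k + 1L
      rows[[k]] <- data.frame(scenario = sc, rate = grid$rate[i],
                              correlation = grid$correlation[i], rep = r,
                              n_sites = nrow(pl),
                              output_rate = sim$rate)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Marginal response curves of a protocol run
#'
#' Output rate as a function of input rate (averaged over correlations)
#' and as a function of correlation (averaged over rates), per scenario.
#'
#' @param results a [run_drive_protocol()] result.
#' @return A list of two data.frames, `by_rate` and `by_correlation`.
#' @export
protocol_marginals <- function(results) {
  by_rate <- stats::aggregate(output_rate ~ scenario + rate, results, mean)
  by_corr <- stats::aggregate(output_rate ~ scenario + correlation, results,
                              mean)
  list(by_rate = by_rate[order(by_rate$scenario, by_rate$rate), ],
       by_correlation = by_corr[order(by_corr$scenario,
                                      by_corr$correlation), ])
}
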