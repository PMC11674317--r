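#' Surrogate point-neuron presets
#'
#' A deliberately simple adaptive leaky integrate-and-fire neuron with
#' conductance-based excitatory synapses, standing in for detailed
#' multicompartment models so that input-drive experiments stay cheap
#' and deterministic. Disease presets implement the reported direction
#' of excitability change by scaling the leak and the threshold
#' distance by 15%: `dSPN_PD2` is more excitable than `dSPN_PD0`,
#' `iSPN_PD2` less excitable than `iSPN_PD0`.
#'
#' @param preset one of `"dSPN_PD0"`, `"dSPN_PD2"`, `"iSPN_PD0"`,
#'   `"iSPN_PD2"`.
#' @return A list of class `surrogate_neuron` with fields `C_pF`,
#'   `gL_nS`, `EL_mV`, `Vth_mV`, `Vreset_mV`, `Ee_mV`, `refrac_s`,
#'   `tau_syn_s`, `b_pA` (spike-triggered adaptation increment),
#'   `tau_w_s`, and Tsodyks-Markram depression parameters `U`,
#'   `tau_rec_s`.
#' @export
surrogate_neuron <- function(preset = c("dSPN_PD0", "dSPN_PD2",
                                        "iSPN_PD0", "iSPN_PD2")) {
  preset <- match.arg(preset)
  base <- list(C_pF = 100, gL_nS = 5, EL_mV = -80, Vth_mV = -50,
               Vreset_mV = -65, Ee_mV = 0, refrac_s = 0.005,
               tau_syn_s = 0.002, b_pA = 60, tau_w_s = 0.3,
               U = 0.3, tau_rec_s = 0.8, preset = preset)
  shift <- 0.15
  if (preset == "dSPN_PD2") {          # more excitable
    base$gL_nS <- base$gL_nS * (1 - shift)
    base$Vth_mV <- base$EL_mV + (base$Vth_mV - base$EL_mV) * (1 - shift)
  } else if (preset == "iSPN_PD0") {   # slightly leakier than dSPN
    base$gL_nS <- 4.5
  } else if (preset == "iSPN_PD2") {   # less excitable
    base$gL_nS <- 4.5 * (1 + shift)
    base$Vth_mV <- base$EL_mV + (base$Vth_mV - base$EL_mV) * (1 + shift)
  }
  if (base$Vth_mV <= base$Vreset_mV) stop("threshold must exceed reset")
  structure(base, class = "surrogate_neuron")
}

# Tsodyks-Markram depression: per-site sequence of release efficacies
# for the site's spike times. Resources recover exponentially between
# spikes; each spike releases U * R.
tm_efficacies <- function(times, U, tau_rec) {
  n <- length(times)
  if (!n) return(numeric(0))
  eff <- numeric(n)
  R <- 1
  eff[1] <- U * R
  if (n > 1) {
    for (k in 2:n) {
      dt <- times[k] - times[k - 1]
      R <- 1 - (1 - R * (1 - U)) * exp(-dt / tau_rec)
      eff[k] <- U * R
    }
  }
  eff
}

#' Simulate the surrogate neuron under synaptic drive
#'
#' Fixed-step (0.1 ms) integration of a conductance-based adaptive
#' leaky integrate-and-fire neuron. Each placement site is driven by
#' one spike train (recycled if fewer trains than sites) through a
#' depressing Tsodyks-Markram synapse; all synaptic conductances share
#' one exponential decay. Deterministic given the inputs.
#'
#' @param neuron a [surrogate_neuron()].
#' @param placement a `synapse_placement` (site conductances in nS).
#' @param trains list of spike-time vectors, s.
#' @param duration simulated time, s.
#' @param dt time step, s (must be <= 1e-4).
#' @return A list with `spike_times` (s), `rate` (Hz) and `duration`.
#' @export
simulate_surrogate <- function(neuron, placement, trains, duration,
                               dt = 1e-4) {
  stopifnot(inherits(neuron, "surrogate_neuron"), dt <= 1e-4, dt > 0,
            duration > 0)
  n_sites <- nrow(placement)
  nstep <- ceiling(duration / dt)
  g_inc <- numeric(nstep)
  if (n_sites > 0 && length(trains) > 0) {
    for (i in seq_len(n_sites)) {
      tt <- trains[[(i - 1L) %% length(trains) + 1L]]
      tt <- tt[tt >= 0 & tt < duration]
      if (!length(tt)) next
      eff <- tm_efficacies(tt, neuron$U, neuron$tau_rec_s)
      idx <- pmin(floor(tt / dt) + 1L, nstep)
      w <- placement$cond[i] * eff
      agg <- rowsum(w, idx)
      pos <- as.integer(rownames(agg))
      g_inc[pos] <- g_inc[pos] + agg[, 1]
    }
  }
  decay <- exp(-dt / neuron$tau_syn_s)
  wdecay <- exp(-dt / neuron$tau_w_s)
  V <- neuron$EL_mV
  g <- 0
  w <- 0
  refrac_until <- -1
  spikes <- numeric(0)
  C <- neuron$C_pF
  for (k in seq_len(nstep)) {
    t <- (k - 1) * dt
    g <- g * decay + g_inc[k]
    w <- w * wdecay
    if (t >= refrac_until) {
      # dV in mV: currents in pA = nS * mV; dt in s, C in pF
      dV <- (-neuron$gL_nS * (V - neuron$EL_mV) -
               g * (V - neuron$Ee_mV) - w) * dt / C * 1000
      V <- V + dV
      if (V >= neuron$Vth_mV) {
        spikes <- c(spikes, t)
        V <- neuron$Vreset_mV
        w <- w + neuron$b_pA
        refrac_until <- t + neuron$refrac_s
      }
    }
  }
  list(spike_times = spikes, rate = length(spikes) / duration,
       duration = duration)
}

#' Calibrate the healthy input synapse count to a target output rate
#'
#' Bisection on the number of input synapses so the healthy surrogate
#' fires at `target_rate` under uncorrelated Poisson drive at
#' `input_rate` per synapse.
#'
#' @param neuron a healthy-preset [surrogate_neuron()].
#' @param morph the healthy morphology to place synapses on.
#' @param target_rate desired output rate, Hz.
#' @param input_rate per-synapse input rate, Hz.
#' @param duration per-trial duration, s.
#' @param seed integer seed.
#' @param bounds search interval for the synapse count.
#' @param iterations bisection iterations.
#' @return Calibrated integer synapse count.
#' @export
calibrate_input_count <- function(neuron, morph, target_rate = 10,
                                  input_rate = 5, duration = 3, seed = 1L,
                                  bounds = c(500L, 16000L),
                                  iterations = 10L) {
  rate_at <- function(n) {
    pl <- place_synapses(morph, n, seed = seed)
    tr <- correlated_spike_trains(n, input_rate, 0, duration,
                                  seed = seed + 1L)
    simulate_surrogate(neuron, pl, tr, duration)$rate
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (rate_at(hi) < target_rate) return(as.integer(hi))
  for (i in seq_len(iterations)) {
    mid <- round((lo + hi) / 2)
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
    if (hi - lo <= 1) break
  }
  as.integer(hi)
}
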