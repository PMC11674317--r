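#' A pruning rule for one ordered type pair
#'
#' The pruning stages, applied in order to the putative synapses of an
#' ordered (pre type, post type) pair:
#' \enumerate{
#'   \item keep each synapse independently with `f_keep_random`;
#'   \item keep each synapse with probability `distance_keep(d)` of its
#'     postsynaptic arc distance to the soma `d` (µm) — used to express
#'     proximal or distal targeting preferences;
#'   \item if a neuron pair retains more than `pair_soft_max` synapses,
#'     a random subset of that size is kept;
#'   \item if a neuron pair retains fewer than `few_synapse_threshold`
#'     synapses, all of them are removed with probability
#'     `max(0, 1 - n / threshold)` (more likely the fewer they are);
#'   \item all synapses of a pair are removed with probability
#'     `pair_removal_probability`.
#' }
#'
#' @param f_keep_random probability in `[0, 1]`.
#' @param distance_keep `NULL` or a vectorized function d -> probability.
#' @param pair_soft_max per-pair synapse cap (Inf disables).
#' @param few_synapse_threshold minimum viable synapse count (0 disables).
#' @param pair_removal_probability probability in `[0, 1]`.
#' @return A list of class `pruning_rule`.
#' @export
pruning_rule <- function(f_keep_random = 1, distance_keep = NULL,
                         pair_soft_max = Inf, few_synapse_threshold = 0,
                         pair_removal_probability = 0) {
  stopifnot(f_keep_random >= 0, f_keep_random <= 1,
            pair_removal_probability >= 0, pair_removal_probability <= 1,
            few_synapse_threshold >= 0)
  structure(list(f_keep_random = f_keep_random,
                 distance_keep = distance_keep,
                 pair_soft_max = pair_soft_max,
                 few_synapse_threshold = few_synapse_threshold,
                 pair_removal_probability = pair_removal_probability),
            class = "pruning_rule")
}

#' Default pruning rule set for the striatal type pairs
#'
#' The functional forms encode the known targeting biases: FS synapses
#' are perisomatic/proximal on SPNs (exponentially decaying keep
#' probability in arc distance, 40 µm scale), LTS synapses prefer
#' distal dendrites, and SPN collateral connectivity is sparse and
#' asymmetric (iSPN output connects much more readily than dSPN
#' output). The per-pair removal probabilities are set so a
#' full-density build lands near published pairwise connection
#' probabilities for nearby somata; re-fit with
#' [calibrate_keep_fraction()] when matching different targets.
#'
#' @param f_keep_spn baseline random-keep fraction for SPN-SPN pairs.
#' @return A named list of [pruning_rule()]s with a `default` entry.
#' @export
default_pruning_rules <- function(f_keep_spn = 0.25) {
  fs_proximal <- function(d) exp(-d / 40)
  lts_distal <- function(d) 1 - exp(-d / 120)
  spn <- function(pair_removal) {
    pruning_rule(f_keep_random = f_keep_spn, pair_soft_max = 8,
                 few_synapse_threshold = 2,
                 pair_removal_probability = pair_removal)
  }
  rules <- list(default = pruning_rule(f_keep_random = 0.3,
                                       pair_soft_max = 8,
                                       pair_removal_probability = 0.5))
  rules[["dSPN>dSPN"]] <- spn(0.60)
  rules[["dSPN>iSPN"]] <- spn(0.80)
  rules[["iSPN>dSPN"]] <- spn(0.25)
  rules[["iSPN>iSPN"]] <- spn(0.15)
  for (post in c("dSPN", "iSPN")) {
    rules[[paste0("FS>", post)]] <-
      pruning_rule(f_keep_random = 0.9, distance_keep = fs_proximal,
                   pair_soft_max = 15)
    rules[[paste0("LTS>", post)]] <-
      pruning_rule(f_keep_random = 0.5, distance_keep = lts_distal,
                   pair_soft_max = 8, pair_removal_probability = 0.4)
    rules[[paste0("ChIN>", post)]] <-
      pruning_rule(f_keep_random = 0.3, pair_soft_max = 8,
                   pair_removal_probability = 0.5)
  }
  rules
}

lookup_rule <- function(rules, pre_type, post_type) {
  key <- paste0(pre_type, ">", post_type)
  r <- rules[[key]]
  if (is.null(r)) r <- rules[["default"]]
  if (is.null(r)) {
    stop("no pruning rule for type pair ", key, " and no default rule")
  }
  r
}

#' Prune putative synapses to target connectivity
#'
#' Applies the per-type-pair [pruning_rule()] stages in their stated
#' order. The synapse count never increases and the result is
#' deterministic per seed.
#'
#' @param putative a putative synapse table from [touch_detect()].
#' @param rules named list of rules keyed `"pre>post"` (plus optional
#'   `"default"`), e.g. from [default_pruning_rules()].
#' @param seed integer seed.
#' @param base_conductance conductance assigned to surviving synapses,
#'   nS.
#' @return A synapse table (putative columns plus `cond`).
#' @export
prune <- function(putative, rules, seed = 1L, base_conductance = 0.5) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  if (!nrow(putative)) {
    out <- putative
    out$cond <- numeric(0)
    return(out)
  }
  pair_types <- unique(putative[, c("pre_type", "post_type")])
  for (i in seq_len(nrow(pair_types))) {
    lookup_rule(rules, pair_types$pre_type[i], pair_types$post_type[i])
  }
  tab <- putative
  n <- nrow(tab)
  type_key <- paste0(tab$pre_type, ">", tab$post_type)
  keep <- rep(TRUE, n)

  # stages 1-2: independent per-synapse keeps
  for (tk in unique(type_key)) {
    idx <- which(type_key == tk)
    r <- lookup_rule(rules, tab$pre_type[idx[1]], tab$post_type[idx[1]])
    p <- rep(r$f_keep_random, length(idx))
    if (!is.null(r$distance_keep)) {
      p <- p * pmin(pmax(r$distance_keep(tab$post_distance_to_soma[idx]), 0), 1)
    }
    keep[idx] <- stats::runif(length(idx)) < p
  }

  # stages 3-5: per neuron-pair decisions
  pair_id <- paste(tab$pre_id, tab$post_id)
  kept_idx <- which(keep)
  groups <- split(kept_idx, pair_id[kept_idx])
  for (idx in groups) {
    r <- lookup_rule(rules, tab$pre_type[idx[1]], tab$post_type[idx[1]])
    if (length(idx) > r$pair_soft_max) {
      drop <- sample(idx, length(idx) - r$pair_soft_max)
      keep[drop] <- FALSE
      idx <- setdiff(idx, drop)
    }
    if (length(idx) < r$few_synapse_threshold) {
      p_remove <- max(0, 1 - length(idx) / r$few_synapse_threshold)
      if (stats::runif(1) < p_remove) {
        keep[idx] <- FALSE
        next
      }
    }
    if (r$pair_removal_probability > 0 &&
        stats::runif(1) < r$pair_removal_probability) {
      keep[idx] <- FALSE
    }
  }
  out <- tab[keep, , drop = FALSE]
  out$cond <- rep(base_conductance, nrow(out))
  rownames(out) <- NULL
  out
}

#' Calibrate the random-keep fraction of one type pair
#'
#' Bisection on `f_keep_random` so that the pruned connection
#' probability of `pre_type -> post_type` pairs within `max_pair_dist`
#' of each other matches `target_p`.
#'
#' @param putative putative synapse table.
#' @param placement the placement the synapses came from.
#' @param rules rule set to adjust.
#' @param pre_type,post_type the ordered type pair.
#' @param target_p target connection probability.
#' @param max_pair_dist soma distance window, µm.
#' @param seed seed used for the trial prunes.
#' @param iterations bisection iterations.
#' @return The rules list with the pair's `f_keep_random` replaced.
#' @export
calibrate_keep_fraction <- function(putative, placement, rules, pre_type,
                                    post_type, target_p,
                                    max_pair_dist = 100, seed = 1L,
                                    iterations = 12L) {
  key <- paste0(pre_type, ">", post_type)
  base <- lookup_rule(rules, pre_type, post_type)
  p_at <- function(f) {
    base$f_keep_random <- f
    rules[[key]] <- base
    tab <- prune(putative, rules, seed = seed)
    cp <- connection_probability(tab, placement, pre_type, post_type,
                                 distance_bins = c(0, max_pair_dist))
    if (!nrow(cp) || is.na(cp$p_hat[1])) return(0)
    cp$p_hat[1]
  }
  lo <- 0; hi <- 1
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (p_at(mid) < target_p) lo <- mid else hi <- mid
  }
  base$f_keep_random <- (lo + hi) / 2
  rules[[key]] <- base
  rules
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes; `n` trials; `z` normal quantile (1.96 for 95%).
#' @param n number of trials.
#' @param z critical value.
#' @return data.frame `p_hat`, `lower`, `upper`.
#' @export
wilson_interval <- function(k, n, z = 1.96) {
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  data.frame(p_hat = p, lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}

#' Distance-resolved connection probability
#'
#' For every ordered (pre, post) neuron pair of the requested types,
#' computes the soma-to-soma distance and whether at least one synapse
#' connects them, then reports per-bin connection probability with its
#' Wilson 95% score interval.
#'
#' @param table a synapse table.
#' @param placement the placement (for positions and types).
#' @param pre_type,post_type cell types.
#' @param distance_bins bin edges, µm.
#' @return data.frame with `bin_lo`, `bin_hi`, `n_pairs`, `n_connected`,
#'   `p_hat`, `lower`, `upper` (NA rows flag empty bins).
#' @export
connection_probability <- function(table, placement, pre_type, post_type,
                                   distance_bins = seq(0, 200, by = 50)) {
  if (is.unsorted(distance_bins)) stop("distance_bins must be ordered")
  inst <- placement$instances
  pre <- inst[inst$cell_type == pre_type, ]
  post <- inst[inst$cell_type == post_type, ]
  if (!nrow(pre) || !nrow(post)) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      n_pairs = integer(0), n_connected = integer(0),
                      p_hat = numeric(0), lower = numeric(0),
                      upper = numeric(0)))
  }
  dx <- outer(pre$x, post$x, "-")
  dy <- outer(pre$y, post$y, "-")
  dz <- outer(pre$z, post$z, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  same <- outer(pre$id, post$id, "==")
  connected_key <- unique(paste(table$pre_id, table$post_id))
  conn <- matrix(paste(rep(pre$id, ncol(dist)),
                       rep(post$id, each = nrow(dist))) %in% connected_key,
                 nrow = nrow(dist))
  d <- dist[!same]
  cn <- conn[!same]
  bins <- cut(d, distance_bins, include.lowest = TRUE, right = FALSE)
  out <- lapply(levels(bins), function(b) {
    sel <- which(bins == b)
    lo <- distance_bins[match(b, levels(bins))]
    hi <- distance_bins[match(b, levels(bins)) + 1]
    if (!length(sel)) {
      return(data.frame(bin_lo = lo, bin_hi = hi, n_pairs = 0L,
                        n_connected = 0L, p_hat = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    }
    k <- sum(cn[sel])
    wi <- wilson_interval(k, length(sel))
    data.frame(bin_lo = lo, bin_hi = hi, n_pairs = length(sel),
               n_connected = k, p_hat = wi$p_hat, lower = wi$lower,
               upper = wi$upper)
  })
  do.call(rbind, out)
}
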