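#' Place input synapses uniformly on the dendrites
#'
#' Sites are drawn uniformly per unit dendritic arc length: a segment is
#' chosen with probability proportional to its length and the position
#' along it uniformly. Each site records the node anchoring its segment
#' and its arc distance to the soma, so survival under dendritic
#' degeneration can be decided later.
#'
#' @param morph a [morphology()] with dendrites.
#' @param n number of synapses.
#' @param seed integer seed.
#' @param conductance per-site base conductance, nS.
#' @return A data.frame of class `synapse_placement`: `site`, `node`,
#'   `offset` (µm along the segment from its parent), `arc` (µm to
#'   soma), `cond` (nS).
#' @export
place_synapses <- function(morph, n, seed = 1L, conductance = 0.5) {
  validate_morphology(morph)
  pidx <- parent_index(morph)
  seg <- segment_lengths(morph)
  arc <- arc_to_soma(morph)
  cand <- which(is_dendrite_type(morph$type) & !is.na(pidx) & seg > 0)
  if (!length(cand) && n > 0) stop("morphology has no dendrite to place on")
  if (n == 0) {
    out <- data.frame(site = integer(0), node = integer(0),
                      offset = numeric(0), arc = numeric(0),
                      cond = numeric(0))
    class(out) <- c("synapse_placement", "data.frame")
    return(out)
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  pick <- sample(cand, n, replace = TRUE, prob = seg[cand])
  u <- stats::runif(n)
  out <- data.frame(site = seq_len(n), node = morph$id[pick],
                    offset = u * seg[pick],
                    arc = arc[pidx[pick]] + u * seg[pick],
                    cond = conductance)
  class(out) <- c("synapse_placement", "data.frame")
  out
}

# which sites survive on a degenerated version of the morphology the
# placement was built on (node ids preserved by degenerate())
sites_survive <- function(placement, morph_degenerated) {
  arc <- stats::setNames(arc_to_soma(morph_degenerated),
                         morph_degenerated$id)
  node_arc <- arc[as.character(placement$node)]
  !is.na(node_arc) & placement$arc <= node_arc + 1e-9
}

#' Fraction of input synapses surviving dendritic degeneration
#'
#' A site survives if the node anchoring its segment is still present
#' and its arc position does not exceed the node's (possibly shortened)
#' arc distance.
#'
#' @param placement a [place_synapses()] placement built on the healthy
#'   morphology.
#' @param morph_degenerated the degenerated morphology (same node ids).
#' @return Surviving fraction in `[0, 1]`.
#' @export
surviving_fraction <- function(placement, morph_degenerated) {
  if (!nrow(placement)) return(NA_real_)
  mean(sites_survive(placement, morph_degenerated))
}

#' Restrict a placement to the sites surviving degeneration
#'
#' @inheritParams surviving_fraction
#' @return The surviving `synapse_placement`.
#' @export
filter_placement <- function(placement, morph_degenerated) {
  out <- placement[sites_survive(placement, morph_degenerated), ,
                   drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("synapse_placement", "data.frame")
  out
}

#' Compensation specification (strengthening or rewiring)
#'
#' Encodes the gradual compensation protocol: with `n_syn_PD0` healthy
#' input synapses and `n_syn_PD2` surviving ones, total conductances are
#' `cond_PD0 = n_syn_PD0 * base` and `cond_PD2 = n_syn_PD2 * base` nS.
#' Strengthening at level x% raises each surviving synapse by
#' `(cond_PD0 - cond_PD2) * x/100 / n_syn_PD2`; rewiring adds
#' `round(x/100 * (n_syn_PD0 - n_syn_PD2))` new base-conductance
#' synapses on the surviving dendrites. At x = 100, strengthening
#' restores the total conductance exactly and rewiring restores the
#' synapse count exactly.
#'
#' @param strategy `"strengthen"` or `"rewire"`.
#' @param level percentage x in `[0, 100]`.
#' @param n_syn_PD0,n_syn_PD2 synapse counts.
#' @param base_conductance per-synapse base conductance, nS.
#' @return A list of class `compensation_spec` (with `cond_PD0`,
#'   `cond_PD2` filled in).
#' @export
compensation_spec <- function(strategy = c("strengthen", "rewire"),
                              level = 100, n_syn_PD0, n_syn_PD2,
                              base_conductance = 0.5) {
  strategy <- match.arg(strategy)
  stopifnot(level >= 0, level <= 100, n_syn_PD2 <= n_syn_PD0)
  structure(list(strategy = strategy, level = level,
                 n_syn_PD0 = n_syn_PD0, n_syn_PD2 = n_syn_PD2,
                 base_conductance = base_conductance,
                 cond_PD0 = n_syn_PD0 * base_conductance,
                 cond_PD2 = n_syn_PD2 * base_conductance),
            class = "compensation_spec")
}

#' Strengthen surviving synapses
#'
#' @param placement the surviving `synapse_placement`.
#' @param spec a [compensation_spec()] with strategy `"strengthen"`.
#' @return The placement with incremented conductances (site count
#'   unchanged).
#' @export
strengthen <- function(placement, spec) {
  stopifnot(inherits(spec, "compensation_spec"),
            spec$strategy == "strengthen")
  if (spec$n_syn_PD2 == 0) stop("no surviving synapses to strengthen")
  inc <- (spec$cond_PD0 - spec$cond_PD2) * (spec$level / 100) / spec$n_syn_PD2
  placement$cond <- placement$cond + inc
  placement
}

#' Rewire lost synapses onto surviving dendrites
#'
#' @param placement the surviving `synapse_placement`.
#' @param morph_degenerated the degenerated morphology to place on.
#' @param spec a [compensation_spec()] with strategy `"rewire"`.
#' @param seed integer seed.
#' @return The placement with added base-conductance sites.
#' @export
rewire <- function(placement, morph_degenerated, spec, seed = 1L) {
  stopifnot(inherits(spec, "compensation_spec"), spec$strategy == "rewire")
  n_add <- round(spec$level / 100 * (spec$n_syn_PD0 - spec$n_syn_PD2))
  if (n_add == 0) return(placement)
  added <- place_synapses(morph_degenerated, n_add, seed = seed,
                          conductance = spec$base_conductance)
  added$site <- max(c(0L, placement$site)) + added$site
  out <- rbind(placement, added)
  rownames(out) <- NULL
  class(out) <- c("synapse_placement", "data.frame")
  out
}
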