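#' PD-stage network construction method
#'
#' @param method `"degeneration"` (drop PD0 synapses orphaned by
#'   dendritic loss), `"de_novo"` (re-detect and prune on the stage
#'   morphologies) or `"hybrid"` (degeneration synapses retained, de
#'   novo synapses added per type pair until the de novo counts are
#'   matched).
#' @return A list of class `pd_build_method`.
#' @export
pd_build_method <- function(method = c("hybrid", "degeneration", "de_novo")) {
  structure(list(method = match.arg(method)), class = "pd_build_method")
}

# synapses of `table` that remain attached to a dendrite (or soma) of
# the stage morphologies: the anchoring post node must survive and the
# synapse's arc position must not exceed the node's (possibly shortened)
# arc distance
surviving_synapses <- function(table, placement, morphologies_stage) {
  if (!nrow(table)) return(table)
  inst <- placement$instances
  ref_of <- stats::setNames(inst$morph_ref, inst$id)
  arcs <- lapply(morphologies_stage, function(m) {
    stats::setNames(arc_to_soma(m), m$id)
  })
  post_ref <- ref_of[as.character(table$post_id)]
  ok <- logical(nrow(table))
  for (ref in unique(post_ref)) {
    idx <- which(post_ref == ref)
    arc <- arcs[[ref]]
    node_arc <- arc[as.character(table$post_node[idx])]
    ok[idx] <- !is.na(node_arc) &
      table$post_distance_to_soma[idx] <= node_arc + 1e-6
  }
  out <- table[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a PD-stage synapse table
#'
#' Three construction routes from a healthy (PD0) network to a disease
#' stage:
#' \describe{
#'   \item{degeneration}{keep the PD0 synapses whose postsynaptic anchor
#'     survives dendritic atrophy; no synapses are added, so the result
#'     is a subset of the PD0 table (sprouted axon segments contribute
#'     nothing).}
#'   \item{de_novo}{run touch detection and pruning from scratch on the
#'     stage morphologies (degenerated SPN dendrites, grown FS axons).}
#'   \item{hybrid}{degeneration-route synapses keep their positions;
#'     per ordered type pair, randomly drawn de novo synapses are added
#'     (or excess randomly removed) until the per-pair counts equal the
#'     de novo totals. The fraction of each pair's final synapses taken
#'     from the de novo set is reported in the `remapping_fraction`
#'     attribute.}
#' }
#'
#' Stage `"PD0"` returns the input unchanged for every method.
#'
#' @param pd0_table the pruned PD0 synapse table.
#' @param placement the shared neuron placement.
#' @param morphologies_stage named morphology list for the stage (same
#'   `morph_ref` keys as at PD0).
#' @param stage stage label, `"PD0"`..`"PD3"`.
#' @param method a [pd_build_method()].
#' @param rules pruning rules (for the de novo route).
#' @param seed integer seed.
#' @param max_distance,voxel_size touch-detection parameters.
#' @return A synapse table.
#' @export
build_pd_network <- function(pd0_table, placement, morphologies_stage,
                             stage, method = pd_build_method(),
                             rules = default_pruning_rules(), seed = 1L,
                             max_distance = 3, voxel_size = 10) {
  if (!stage %in% c("PD0", "PD1", "PD2", "PD3")) {
    stop("unknown stage: ", stage)
  }
  if (stage == "PD0") return(pd0_table)
  meth <- method$method
  if (meth == "degeneration") {
    return(surviving_synapses(pd0_table, placement, morphologies_stage))
  }
  putative <- touch_detect(placement, morphologies_stage,
                           max_distance = max_distance,
                           voxel_size = voxel_size)
  de_novo <- prune(putative, rules, seed = seed)
  if (meth == "de_novo") return(de_novo)

  deg <- surviving_synapses(pd0_table, placement, morphologies_stage)
  old <- withr_seed(seed + 7L)
  on.exit(restore_seed(old), add = TRUE)
  pair_key <- function(tab) {
    if (!nrow(tab)) return(character(0))
    paste0(tab$pre_type, ">", tab$post_type)
  }
  dn_key <- pair_key(de_novo)
  dg_key <- pair_key(deg)
  keys <- unique(c(dn_key, dg_key))
  pieces <- list()
  remap <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    dn_idx <- which(dn_key == k)
    dg_idx <- which(dg_key == k)
    target <- length(dn_idx)
    kept <- deg[dg_idx, , drop = FALSE]
    if (nrow(kept) > target) {
      kept <- kept[sample(nrow(kept), target), , drop = FALSE]
    }
    need <- target - nrow(kept)
    added <- if (need > 0) {
      de_novo[sample(dn_idx, need), , drop = FALSE]
    } else NULL
    remap[k] <- if (target > 0) need / target else 0
    pieces[[k]] <- rbind(kept, added)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- de_novo[0, , drop = FALSE]
  out <- out[order(out$pre_id, out$post_id, out$post_node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "remapping_fraction") <- remap
  out
}

#' Remove all synapses touching given cell types
#'
#' @param table a synapse table.
#' @param types cell types to ablate (both as pre and post).
#' @return The synapse table without rows involving those types.
#' @export
ablate_types <- function(table, types) {
  out <- table[!(table$pre_type %in% types | table$post_type %in% types), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomly erode a fraction of synapses
#'
#' Each in-scope synapse is removed independently with probability
#' `fraction`; synapses outside the scope are untouched.
#'
#' @param table a synapse table.
#' @param fraction removal probability in `[0, 1]`.
#' @param scope `"all"` or `"SPN_only"` (only rows with both endpoints
#'   SPN are eligible).
#' @param seed integer seed.
#' @return The eroded synapse table.
#' @export
erode_synapses <- function(table, fraction, scope = c("all", "SPN_only"),
                           seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(fraction >= 0, fraction <= 1)
  if (!nrow(table)) return(table)
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  in_scope <- if (scope == "SPN_only") {
    table$pre_type %in% c("dSPN", "iSPN") &
      table$post_type %in% c("dSPN", "iSPN")
  } else rep(TRUE, nrow(table))
  removed <- in_scope & (stats::runif(nrow(table)) < fraction)
  out <- table[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degenerate or grow a whole morphology library to a PD stage
#'
#' SPN morphologies (dSPN, iSPN) are dendritically degenerated to the
#' stage; FS morphologies get their axonal terminals extended (the
#' sprouting is applied once, at every diseased stage); other types are
#' unchanged.
#'
#' @param morphologies named list keyed `"type_variant"`.
#' @param stage stage label.
#' @param schedule a [degeneration_schedule()].
#' @param growth a [growth_spec()] for FS axons (`NULL` disables
#'   sprouting).
#' @return The stage morphology list (same names).
#' @export
stage_morphologies <- function(morphologies, stage,
                               schedule = degeneration_schedule(),
                               growth = growth_spec()) {
  if (stage == "PD0") return(morphologies)
  out <- morphologies
  for (nm in names(morphologies)) {
    ct <- sub("_.*$", "", nm)
    if (ct %in% c("dSPN", "iSPN")) {
      out[[nm]] <- degenerate(morphologies[[nm]], stage, schedule)
    } else if (ct == "FS" && !is.null(growth)) {
      g <- growth
      g$seed <- g$seed + match(nm, names(morphologies))
      if (is.na(g$radius_cap)) {
        # sprouting densifies the arbor without extending its envelope:
        # reflect the growth walk at the initial axonal radius
        m <- morphologies[[nm]]
        soma <- soma_position(m)
        ax <- is_axon_type(m$type)
        if (any(ax)) {
          g$radius_cap <- max(sqrt((m$x[ax] - soma[1])^2 +
                                     (m$y[ax] - soma[2])^2 +
                                     (m$z[ax] - soma[3])^2))
        }
      }
      out[[nm]] <- grow_axon_terminals(morphologies[[nm]], g)
    }
  }
  out
}
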