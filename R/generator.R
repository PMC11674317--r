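#' Terminal count implied by a stage-to-stage length loss
#'
#' Under stepwise truncation, each step removes `step_length` µm at
#' every terminal, so a drop from `L0` to `L1` over `steps` steps
#' implies a mean effective terminal count of
#' `(L0 - L1) / (steps * step_length)`, rounded to the nearest integer.
#' Used to calibrate generator terminal counts from published mean
#' total-length tables.
#'
#' @param L0,L1 total dendritic length before/after, µm.
#' @param steps number of truncation steps between the two stages.
#' @param step_length µm removed per terminal per step.
#' @return Integer terminal count.
#' @export
calibrate_terminal_count <- function(L0, L1, steps = 10, step_length = 3) {
  stopifnot(steps > 0, step_length > 0)
  if (L0 <= L1) stop("length loss must be positive (L0 > L1)")
  as.integer(round((L0 - L1) / (steps * step_length)))
}

#' Generator specification for synthetic morphologies
#'
#' Defaults are calibrated to published morphometrics of the striatal
#' cell types: dSPN dendrites 3,997.9 µm over 8 primaries, iSPN
#' 3,116.7 µm over 6 primaries, FS axon 25,572 µm with 257 terminals.
#' SPN dendritic terminal counts default to the value implied by the
#' published first-stage degeneration loss (see
#' [calibrate_terminal_count()]): 37 for dSPN, 25 for iSPN. Interneuron
#' dendrites and SPN local axon collaterals use generic parameters; only
#' their connectivity role matters downstream.
#'
#' @param cell_type one of "dSPN", "iSPN", "FS", "ChIN", "LTS".
#' @param n_primary number of primary dendrites.
#' @param target_total_length target total dendritic length, µm.
#' @param target_terminal_count dendritic terminal count.
#' @param axon_total_length,axon_terminal_count axonal arbor targets.
#' @param segment_step geometry step, µm (3 µm: transforms can be
#'   applied without resampling).
#' @param dendrite_extent,axon_extent soft radial bounds of the arbors,
#'   µm (the growth walks reflect there).
#' @param tortuosity persistence of the neurite walks in `[0, 1]`.
#' @param scale_jitter sd of a per-draw log-normal scaling of section
#'   lengths (0 disables; population means stay on target).
#' @param seed integer seed.
#' @return A list of class `morphgen_spec`.
#' @export
morphgen_spec <- function(cell_type = c("dSPN", "iSPN", "FS", "ChIN", "LTS"),
                          n_primary = NULL, target_total_length = NULL,
                          target_terminal_count = NULL,
                          axon_total_length = NULL, axon_terminal_count = NULL,
                          segment_step = 3, dendrite_extent = NULL,
                          axon_extent = NULL, tortuosity = 0.85,
                          scale_jitter = 0, seed = 1L) {
  cell_type <- match.arg(cell_type)
  defaults <- list(
    dSPN = list(n_primary = 8L, dend_len = 3997.9,
                dend_term = calibrate_terminal_count(3997.9, 2890.8),
                axon_len = 6000, axon_term = 30L,
                dend_extent = 150, axon_extent = 250),
    iSPN = list(n_primary = 6L, dend_len = 3116.7,
                dend_term = calibrate_terminal_count(3116.7, 2362.5),
                axon_len = 6000, axon_term = 30L,
                dend_extent = 150, axon_extent = 250),
    FS   = list(n_primary = 5L, dend_len = 2000,
                dend_term = 12L,
                axon_len = 25572, axon_term = 257L,
                dend_extent = 120, axon_extent = 200),
    ChIN = list(n_primary = 4L, dend_len = 3000,
                dend_term = 15L,
                axon_len = 12000, axon_term = 80L,
                dend_extent = 200, axon_extent = 300),
    LTS  = list(n_primary = 4L, dend_len = 1500,
                dend_term = 10L,
                axon_len = 8000, axon_term = 50L,
                dend_extent = 150, axon_extent = 300))[[cell_type]]
  spec <- list(
    cell_type = cell_type,
    n_primary = as.integer(n_primary %||% defaults$n_primary),
    target_total_length = target_total_length %||% defaults$dend_len,
    target_terminal_count = as.integer(target_terminal_count %||% defaults$dend_term),
    axon_total_length = axon_total_length %||% defaults$axon_len,
    axon_terminal_count = as.integer(axon_terminal_count %||% defaults$axon_term),
    segment_step = segment_step,
    dendrite_extent = dendrite_extent %||% defaults$dend_extent,
    axon_extent = axon_extent %||% defaults$axon_extent,
    tortuosity = tortuosity,
    scale_jitter = scale_jitter,
    seed = as.integer(seed))
  if (spec$n_primary < 1L) stop("n_primary must be >= 1")
  if (spec$target_terminal_count < spec$n_primary) {
    stop("infeasible spec: terminal count (", spec$target_terminal_count,
         ") < n_primary (", spec$n_primary, ")")
  }
  if (spec$target_total_length <= 0) stop("target_total_length must be > 0")
  class(spec) <- "morphgen_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build the section tree of an arbor: n_primary root sections, binary
# branching until `terminals` tips. Returns a data.frame of sections
# (parent section index, is_terminal) with lengths summing exactly to
# `total_length`. Terminal sections are drawn longer than internal ones
# (gamma-distributed, terminal mean three times the internal mean),
# reflecting the predominantly distal placement of long unbranched
# segments in these arbors; all lengths are rescaled so the total is
# exact per draw.
arbor_plan <- function(n_primary, terminals, total_length,
                       terminal_shape = 4, internal_shape = 3) {
  n_branch <- terminals - n_primary
  # grow the topology: start with n_primary open tips; each branching
  # event splits a random open tip into two
  parent <- rep(0L, n_primary)        # 0 = soma
  open <- seq_len(n_primary)
  for (b in seq_len(n_branch)) {
    pick <- open[sample.int(length(open), 1L)]
    k <- length(parent)
    parent <- c(parent, pick, pick)
    open <- c(setdiff(open, pick), k + 1L, k + 2L)
  }
  n_sec <- length(parent)
  is_term <- !(seq_len(n_sec) %in% parent)
  # mean section lengths: internal m, terminal 3m, scaled to the target
  n_int <- sum(!is_term)
  n_term <- sum(is_term)
  m <- total_length / (n_int + 3 * n_term)
  len <- numeric(n_sec)
  len[!is_term] <- stats::rgamma(n_int, shape = internal_shape,
                                 scale = m / internal_shape)
  len[is_term] <- stats::rgamma(n_term, shape = terminal_shape,
                                scale = 3 * m / terminal_shape)
  len <- pmax(len, 1)                  # no degenerate zero-length sections
  len <- len * total_length / sum(len)
  data.frame(parent = parent, is_terminal = is_term, length = len)
}

# Realize a planned arbor in 3-D as node rows appended to `nodes`.
# Sections are persistent random walks in steps <= segment_step, exact
# in path length, reflecting at `extent` from the soma.
realize_arbor <- function(plan, soma_id, soma_pos, type, radius,
                          segment_step, extent, tortuosity) {
  n_sec <- nrow(plan)
  sec_end_id <- integer(n_sec)         # node id of each section's end
  sec_end_pos <- matrix(0, n_sec, 3)
  sec_end_dir <- matrix(0, n_sec, 3)
  rows <- vector("list", n_sec)
  next_id <- soma_id
  order_idx <- order(plan$parent)      # parents are always created first
  for (s in order_idx) {
    p <- plan$parent[s]
    if (p == 0L) {
      start_id <- soma_id
      start_pos <- soma_pos
      dir <- random_unit_vector()
    } else {
      start_id <- sec_end_id[p]
      start_pos <- sec_end_pos[p, ]
      # diverge from the parent heading
      dir <- tortuosity * sec_end_dir[p, ] + (1 - tortuosity) * random_unit_vector()
      dir <- dir / sqrt(sum(dir^2))
    }
    L <- plan$length[s]
    k <- max(1L, ceiling(L / segment_step))
    slen <- L / k
    xyz <- matrix(0, k, 3)
    pos <- start_pos
    for (i in seq_len(k)) {
      h <- tortuosity * dir + (1 - tortuosity) * random_unit_vector()
      nh <- sqrt(sum(h^2))
      h <- if (nh > 1e-9) h / nh else random_unit_vector()
      cand <- pos + h * slen
      if (sqrt(sum((cand - soma_pos)^2)) > extent) {
        rad <- pos - soma_pos
        nr <- sqrt(sum(rad^2))
        if (nr > 1e-9) {
          rad <- rad / nr
          h <- h - 2 * max(0, sum(h * rad)) * rad
          h <- h / sqrt(sum(h^2))
          cand <- pos + h * slen
        }
      }
      xyz[i, ] <- cand
      dir <- h
      pos <- cand
    }
    ids <- next_id + seq_len(k)
    next_id <- next_id + k
    rows[[s]] <- data.frame(id = ids, type = type,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            radius = radius,
                            parent = c(start_id, ids[-k]))
    sec_end_id[s] <- ids[k]
    sec_end_pos[s, ] <- pos
    sec_end_dir[s, ] <- dir
  }
  # renumber ids consecutively is unnecessary: parents precede children
  do.call(rbind, rows[order_idx])
}

#' Generate a synthetic neuron morphology
#'
#' Draws a morphology whose population-mean morphometrics match the
#' spec targets: the section tree is built by random binary branching to
#' the target terminal count, section lengths are gamma-distributed with
#' longer terminal sections and rescaled so the per-draw total length is
#' exact, and geometry is laid down as persistent random walks in
#' `segment_step` µm steps (so transforms requiring 3 µm sampling apply
#' directly). Deterministic per seed.
#'
#' @param spec a [morphgen_spec()].
#' @return A [morphology()] with soma, dendrites and (if specified) an
#'   axonal arbor.
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "morphgen_spec"))
  old <- withr_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)

  jit <- if (spec$scale_jitter > 0)
    stats::rlnorm(1, -spec$scale_jitter^2 / 2, spec$scale_jitter) else 1
  soma <- data.frame(id = 1L, type = SWC_SOMA, x = 0, y = 0, z = 0,
                     radius = 6, parent = -1L)
  dplan <- arbor_plan(spec$n_primary, spec$target_terminal_count,
                      spec$target_total_length * jit)
  dend <- realize_arbor(dplan, 1L, c(0, 0, 0), SWC_DEND, 0.6,
                        spec$segment_step, spec$dendrite_extent,
                        spec$tortuosity)
  parts <- list(soma, dend)
  if (!is.null(spec$axon_total_length) && spec$axon_total_length > 0 &&
      spec$axon_terminal_count >= 1L) {
    aplan <- arbor_plan(1L, spec$axon_terminal_count,
                        spec$axon_total_length * jit)
    axon <- realize_arbor(aplan, 1L, c(0, 0, 0), SWC_AXON, 0.3,
                          spec$segment_step, spec$axon_extent,
                          spec$tortuosity)
    axon$id <- axon$id + max(dend$id) - 1L
    axon$parent[axon$parent != 1L] <- axon$parent[axon$parent != 1L] + max(dend$id) - 1L
    parts <- c(parts, list(axon))
  }
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  morphology(tab)
}

#' Generate a library of morphologies for network construction
#'
#' Produces `n_each` seeded draws per requested cell type, optionally
#' writing SWC files and a CSV manifest of their morphometrics.
#'
#' @param cell_types character vector of cell types.
#' @param n_each draws per type.
#' @param seed base seed; draw seeds are derived deterministically.
#' @param out_dir optional directory for SWC files + `manifest.csv`.
#' @param specs optional named list of [morphgen_spec()] overrides.
#' @return Named list of morphologies (`"dSPN_1"`, ...), with the
#'   manifest data.frame attached as attribute `"manifest"`.
#' @export
generate_morphology_library <- function(cell_types = c("dSPN", "iSPN", "FS"),
                                        n_each = 3L, seed = 1L,
                                        out_dir = NULL, specs = NULL) {
  morphs <- list()
  rows <- list()
  for (ct in cell_types) {
    for (i in seq_len(n_each)) {
      draw_seed <- (seed * 1000L + match(ct, c("dSPN", "iSPN", "FS", "ChIN", "LTS")) * 100L + i) %% .Machine$integer.max
      sp <- if (!is.null(specs[[ct]])) specs[[ct]] else morphgen_spec(ct)
      sp$seed <- as.integer(draw_seed)
      nm <- paste0(ct, "_", i)
      m <- generate_morphology(sp)
      morphs[[nm]] <- m
      mm <- morphometry(m)
      rows[[nm]] <- data.frame(file = paste0(nm, ".swc"), cell_type = ct,
                               seed = draw_seed,
                               total_dendritic_length = mm$total_dendritic_length,
                               total_axonal_length = mm$total_axonal_length,
                               n_primary_dendrites = mm$n_primary_dendrites,
                               n_branch_points = mm$n_branch_points)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_swc(m, file.path(out_dir, paste0(nm, ".swc")))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  attr(morphs, "manifest") <- manifest
  morphs
}
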