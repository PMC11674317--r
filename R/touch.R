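# Touch detection: geometric location of putative synapses where a
# presynaptic axon passes within max_distance of a postsynaptic
# dendrite or soma.

# Per-morphology segment template: one row per parent->child segment
# plus one zero-length row for the soma point (so axons passing near
# the soma yield somatic touches at arc distance 0).
segment_template <- function(morph) {
  pidx <- parent_index(morph)
  arc <- arc_to_soma(morph)
  has_parent <- !is.na(pidx)
  tpl <- data.frame(
    x0 = morph$x[pidx[has_parent]], y0 = morph$y[pidx[has_parent]],
    z0 = morph$z[pidx[has_parent]],
    x1 = morph$x[has_parent], y1 = morph$y[has_parent],
    z1 = morph$z[has_parent],
    node = morph$id[has_parent], type = morph$type[has_parent],
    arc0 = arc[pidx[has_parent]], pad = 0)
  root <- which(!has_parent)
  # the soma is a sphere, not a point: pad its touch distance by the
  # somatic radius so perisomatic contacts are represented
  soma <- data.frame(x0 = morph$x[root], y0 = morph$y[root], z0 = morph$z[root],
                     x1 = morph$x[root], y1 = morph$y[root], z1 = morph$z[root],
                     node = morph$id[root], type = SWC_SOMA, arc0 = 0,
                     pad = morph$radius[root])
  rbind(tpl, soma)
}

# Vectorized minimum distance between segment sets P0->P1 and Q0->Q1
# (matrices, one row per pair). Returns dist and the parameters s, t of
# the closest points.
segseg_distance <- function(P0, P1, Q0, Q1) {
  d1 <- P1 - P0
  d2 <- Q1 - Q0
  r <- P0 - Q0
  a <- rowSums(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  c_ <- rowSums(d1 * r)
  b <- rowSums(d1 * d2)
  denom <- a * e - b * b
  s <- numeric(length(a))
  pos <- denom > 1e-12
  s[pos] <- pmin.int(pmax.int((b[pos] * f[pos] - c_[pos] * e[pos]) /
                                denom[pos], 0), 1)
  t <- numeric(length(a))
  epos <- e > 1e-12
  t[epos] <- (b[epos] * s[epos] + f[epos]) / e[epos]
  t_cl <- pmin.int(pmax.int(t, 0), 1)
  need <- (t_cl != t) & a > 1e-12
  s[need] <- pmin.int(pmax.int((b[need] * t_cl[need] - c_[need]) / a[need],
                               0), 1)
  t <- t_cl
  cp <- P0 + d1 * s
  cq <- Q0 + d2 * t
  list(dist = sqrt(rowSums((cp - cq)^2)), s = s, t = t,
       mid = (cp + cq) / 2)
}

# all transformed segments of a placement, split into axonal (pre side)
# and dendritic/somatic (post side): lists of matrices/vectors for fast
# pairwise indexing
placement_segments <- function(placement, morphologies) {
  inst <- placement$instances
  templates <- lapply(morphologies, segment_template)
  pre_list <- list()
  post_list <- list()
  for (i in seq_len(nrow(inst))) {
    ref <- inst$morph_ref[i]
    if (is.na(ref)) next
    tpl <- templates[[ref]]
    if (is.null(tpl)) stop("no morphology for reference ", ref)
    R <- placement$rotations[[i]]
    p <- c(inst$x[i], inst$y[i], inst$z[i])
    a <- as.matrix(tpl[, c("x0", "y0", "z0")]) %*% t(R)
    b <- as.matrix(tpl[, c("x1", "y1", "z1")]) %*% t(R)
    a <- sweep(a, 2, p, "+")
    b <- sweep(b, 2, p, "+")
    mk <- function(sel) list(
      p0 = a[sel, , drop = FALSE], p1 = b[sel, , drop = FALSE],
      node = tpl$node[sel], arc0 = tpl$arc0[sel], pad = tpl$pad[sel],
      neuron = rep(inst$id[i], sum(sel)),
      cell_type = rep(inst$cell_type[i], sum(sel)))
    is_axon <- is_axon_type(tpl$type)
    is_post <- is_dendrite_type(tpl$type) | tpl$type == SWC_SOMA
    if (any(is_axon)) pre_list[[length(pre_list) + 1L]] <- mk(is_axon)
    if (any(is_post)) post_list[[length(post_list) + 1L]] <- mk(is_post)
  }
  cat_side <- function(lst) {
    if (!length(lst)) return(NULL)
    list(p0 = do.call(rbind, lapply(lst, `[[`, "p0")),
         p1 = do.call(rbind, lapply(lst, `[[`, "p1")),
         node = unlist(lapply(lst, `[[`, "node")),
         arc0 = unlist(lapply(lst, `[[`, "arc0")),
         pad = unlist(lapply(lst, `[[`, "pad")),
         neuron = unlist(lapply(lst, `[[`, "neuron")),
         cell_type = unlist(lapply(lst, `[[`, "cell_type")))
  }
  list(pre = cat_side(pre_list), post = cat_side(post_list))
}

putative_from_pairs <- function(pre, post, ai, di, max_distance) {
  res <- segseg_distance(pre$p0[ai, , drop = FALSE],
                         pre$p1[ai, , drop = FALSE],
                         post$p0[di, , drop = FALSE],
                         post$p1[di, , drop = FALSE])
  hit <- which(res$dist <= max_distance + post$pad[di])
  if (!length(hit)) return(NULL)
  ah <- ai[hit]; dh <- di[hit]
  post_len <- sqrt(rowSums((post$p1[dh, , drop = FALSE] -
                              post$p0[dh, , drop = FALSE])^2))
  data.frame(
    pre_id = pre$neuron[ah], post_id = post$neuron[dh],
    x = res$mid[hit, 1], y = res$mid[hit, 2], z = res$mid[hit, 3],
    post_distance_to_soma = post$arc0[dh] + res$t[hit] * post_len,
    pre_type = pre$cell_type[ah], post_type = post$cell_type[dh],
    pre_node = pre$node[ah], post_node = post$node[dh])
}

canonical_synapse_order <- function(tab) {
  tab <- tab[do.call(order, tab[c("pre_id", "post_id", "post_node",
                                  "post_distance_to_soma", "pre_node")]), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Detect putative synapses by axo-dendritic proximity
#'
#' A putative synapse is recorded for every (presynaptic axonal segment,
#' postsynaptic dendritic or somatic segment) pair of distinct neurons
#' whose minimum distance is at most `max_distance`. A uniform voxel
#' grid accelerates the candidate search; the voxel size does not affect
#' the result (the distance test is exact and the neighbourhood shell is
#' sized to cover `max_distance` plus the longest half-segments).
#'
#' @param placement a [place_neurons()] placement.
#' @param morphologies named list of morphologies keyed by `morph_ref`.
#' @param max_distance touch distance threshold, µm.
#' @param voxel_size acceleration grid pitch, µm.
#' @return A putative synapse table: data.frame with `pre_id`,
#'   `post_id`, `x`, `y`, `z`, `post_distance_to_soma`, `pre_type`,
#'   `post_type`, `pre_node`, `post_node`.
#' @export
touch_detect <- function(placement, morphologies, max_distance = 3,
                         voxel_size = 10) {
  stopifnot(max_distance > 0, voxel_size > 0)
  segs <- placement_segments(placement, morphologies)
  pre <- segs$pre
  post <- segs$post
  if (is.null(pre) || is.null(post)) return(empty_synapse_table())

  half_len <- function(s) sqrt(rowSums((s$p1 - s$p0)^2)) / 2
  reach <- max_distance + max(post$pad) + max(half_len(pre)) +
    max(half_len(post))
  shells <- ceiling(reach / voxel_size)

  vox <- function(s) {
    mid <- (s$p0 + s$p1) / 2
    data.table::data.table(
      ix = as.integer(floor(mid[, 1] / voxel_size)),
      iy = as.integer(floor(mid[, 2] / voxel_size)),
      iz = as.integer(floor(mid[, 3] / voxel_size)),
      row = seq_along(s$node))
  }
  dpost <- vox(post)
  data.table::setkey(dpost, ix, iy, iz)
  dpre <- vox(pre)
  offs <- expand.grid(dx = -shells:shells, dy = -shells:shells,
                      dz = -shells:shells)
  out <- list()
  chunk <- 1000000L
  for (o in seq_len(nrow(offs))) {
    q <- data.table::data.table(ix = dpre$ix + offs$dx[o],
                                iy = dpre$iy + offs$dy[o],
                                iz = dpre$iz + offs$dz[o],
                                arow = dpre$row)
    hits <- dpost[q, on = c("ix", "iy", "iz"), nomatch = NULL,
                  allow.cartesian = TRUE]
    if (!nrow(hits)) next
    ai <- hits$arow
    di <- hits$row
    keep <- pre$neuron[ai] != post$neuron[di]
    ai <- ai[keep]; di <- di[keep]
    if (!length(ai)) next
    for (st in seq(1L, length(ai), by = chunk)) {
      en <- min(st + chunk - 1L, length(ai))
      piece <- putative_from_pairs(pre, post, ai[st:en], di[st:en],
                                   max_distance)
      if (!is.null(piece)) out[[length(out) + 1L]] <- piece
    }
  }
  if (!length(out)) return(empty_synapse_table())
  canonical_synapse_order(do.call(rbind, out))
}

#' All-pairs touch detection (test oracle)
#'
#' Identical contract to [touch_detect()] but scans every axonal x
#' dendritic segment pair without spatial indexing. Intended to verify
#' that the voxel acceleration is exact; use on small networks only.
#'
#' @inheritParams touch_detect
#' @return A putative synapse table.
#' @export
touch_detect_bruteforce <- function(placement, morphologies,
                                    max_distance = 3) {
  segs <- placement_segments(placement, morphologies)
  pre <- segs$pre
  post <- segs$post
  if (is.null(pre) || is.null(post)) return(empty_synapse_table())
  np <- length(pre$node)
  pieces <- list()
  chunk <- max(1L, floor(2e6 / np))
  nd <- length(post$node)
  for (st in seq(1L, nd, by = chunk)) {
    en <- min(st + chunk - 1L, nd)
    di <- rep(st:en, each = np)
    ai <- rep(seq_len(np), times = en - st + 1L)
    keep <- pre$neuron[ai] != post$neuron[di]
    piece <- putative_from_pairs(pre, post, ai[keep], di[keep],
                                 max_distance)
    if (!is.null(piece)) pieces[[length(pieces) + 1L]] <- piece
  }
  if (!length(pieces)) return(empty_synapse_table())
  canonical_synapse_order(do.call(rbind, pieces))
}

empty_synapse_table <- function() {
  data.frame(pre_id = integer(0), post_id = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0),
             post_distance_to_soma = numeric(0), pre_type = character(0),
             post_type = character(0), pre_node = integer(0),
             post_node = integer(0))
}

#' Write / read the TSV mirror of a synapse table
#'
#' @param table a synapse table.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_synapse_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
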