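#' @useDynLib striatnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# SWC structure type codes used throughout. Types 3 and 4 (basal/apical)
# are both treated as dendrite.
SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_DEND <- 3L

is_dendrite_type <- function(type) type >= 3L
is_axon_type <- function(type) type == SWC_AXON

#' Construct a morphology from an SWC-style node table
#'
#' A morphology is a rooted tree of typed 3-D points with SWC semantics:
#' one soma root, and every node's parent defined earlier in the table.
#' Node ids are arbitrary positive integers and are preserved by the
#' degeneration and growth transforms, so that synapse locations anchored
#' to a node can be followed across disease stages.
#'
#' @param nodes data.frame with columns `id`, `type` (1 soma, 2 axon,
#'   3/4 dendrite), `x`, `y`, `z`, `radius` (all µm) and `parent`
#'   (id of the parent node, or -1 for the root).
#' @param validate check the tree invariants (default `TRUE`).
#' @return An object of class `morphology` (a data.frame).
#' @export
morphology <- function(nodes, validate = TRUE) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("morphology nodes need columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  class(nodes) <- c("morphology", "data.frame")
  if (validate) validate_morphology(nodes)
  nodes
}

#' Validate morphology invariants
#'
#' Checks: exactly one root, the root is a soma node, parents are defined
#' before their children, ids unique, coordinates finite.
#'
#' @param morph a [morphology()].
#' @return The morphology, invisibly; errors on violation.
#' @export
validate_morphology <- function(morph) {
  if (anyDuplicated(morph$id)) stop("duplicate node ids")
  root <- which(morph$parent == -1L)
  if (length(root) != 1L) stop("morphology must have exactly one root, found ", length(root))
  if (morph$type[root] != SWC_SOMA) stop("root node must be soma (type 1)")
  if (!all(is.finite(as.matrix(morph[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  pos <- match(morph$parent, morph$id)
  bad <- which(morph$parent != -1L & (is.na(pos) | pos >= seq_len(nrow(morph))))
  if (length(bad)) {
    stop("node id ", morph$id[bad[1]], " references parent ", morph$parent[bad[1]],
         " which is not defined earlier (line ", bad[1], ")")
  }
  invisible(morph)
}

#' @export
print.morphology <- function(x, ...) {
  cat(sprintf("<morphology> %d nodes (%d axon, %d dendrite)\n",
              nrow(x), sum(is_axon_type(x$type)), sum(is_dendrite_type(x$type))))
  invisible(x)
}

# index of each node's parent row (NA for root)
parent_index <- function(morph) {
  idx <- match(morph$parent, morph$id)
  idx[morph$parent == -1L] <- NA_integer_
  idx
}

# Euclidean length of the segment ending at each node (NA for root)
segment_lengths <- function(morph) {
  pidx <- parent_index(morph)
  dx <- morph$x - morph$x[pidx]
  dy <- morph$y - morph$y[pidx]
  dz <- morph$z - morph$z[pidx]
  sqrt(dx^2 + dy^2 + dz^2)
}

# arc length from soma to each node along the tree
arc_to_soma <- function(morph) {
  pidx <- parent_index(morph)
  seg <- segment_lengths(morph)
  arc <- numeric(nrow(morph))
  for (i in seq_len(nrow(morph))) {
    arc[i] <- if (is.na(pidx[i])) 0 else arc[pidx[i]] + seg[i]
  }
  arc
}

# number of children per node (same order as morph rows)
child_counts <- function(morph) {
  tab <- tabulate(match(morph$parent, morph$id), nbins = nrow(morph))
  tab
}

soma_position <- function(morph) {
  r <- which(morph$parent == -1L)
  c(morph$x[r], morph$y[r], morph$z[r])
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent), coordinates
#' in µm. Comment lines start with `#`.
#'
#' @param path path to an SWC file.
#' @return A [morphology()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    i <- which(nf != 7L)[1]
    stop("malformed SWC line ", lineno[i], ": expected 7 fields, found ", nf[i])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    i <- which(apply(is.na(m), 1, any))[1]
    stop("malformed SWC line ", lineno[i], ": non-numeric field")
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  roots <- which(nodes$parent == -1L)
  if (length(roots) > 1L) {
    stop("multiple roots in SWC file (lines ",
         paste(lineno[roots], collapse = ", "), ")")
  }
  pos <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & (is.na(pos) | pos >= seq_len(nrow(nodes))))
  if (length(bad)) {
    stop("SWC line ", lineno[bad[1]], ": parent ", nodes$parent[bad[1]],
         " is not defined on an earlier line")
  }
  morphology(nodes)
}

#' Write a morphology to an SWC file
#'
#' Node ids are re-emitted as 1..n in topological (table) order; parents
#' are remapped accordingly. Units are µm.
#'
#' @param morph a [morphology()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  validate_morphology(morph)
  newid <- seq_len(nrow(morph))
  pidx <- parent_index(morph)
  newparent <- ifelse(is.na(pidx), -1L, newid[pidx])
  lines <- sprintf("%d %d %.6g %.6g %.6g %.6g %d",
                   newid, morph$type, morph$x, morph$y, morph$z,
                   morph$radius, newparent)
  ok <- tryCatch({
    writeLines(c("# SWC morphology (striatnet)", lines), path)
    TRUE
  }, error = function(e) stop("cannot write SWC file ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Resample a morphology at a fixed spatial resolution
#'
#' Every unbranched section (path between soma, branch points and
#' terminals) is re-divided into equal steps no longer than `resolution`,
#' with new nodes interpolated along the original polyline. Section
#' endpoints are preserved, so tree topology and per-section path length
#' are unchanged up to chord shortening at interior bends.
#'
#' @param morph a [morphology()].
#' @param resolution maximum node spacing, µm.
#' @return A resampled [morphology()] (node ids renumbered).
#' @export
resample <- function(morph, resolution = 3) {
  if (!is.numeric(resolution) || resolution <= 0) stop("resolution must be > 0")
  validate_morphology(morph)
  pidx <- parent_index(morph)
  nchild <- child_counts(morph)
  root <- which(is.na(pidx))
  n <- nrow(morph)

  # section start nodes: children of the soma, children of branch points,
  # and nodes whose structure type differs from their parent's
  children_of <- split(seq_len(n), factor(pidx, levels = seq_len(n)))
  is_break <- rep(FALSE, n)        # a node at which sections end
  is_break[root] <- TRUE
  is_break[nchild >= 2L] <- TRUE
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(pidx[i])) next
    p <- pidx[i]
    if (is_break[p] || morph$type[i] != morph$type[p]) starts <- c(starts, i)
  }

  rootrow <- morph[root, , drop = FALSE]
  rootrow$id <- 1L
  rootrow$parent <- -1L
  out <- list(rootrow)
  next_id <- 1L
  id_map <- integer(n)  # old row -> new id (filled for section endpoints)
  id_map[root] <- next_id

  # walk sections in table order of their start node so parents come first
  # (sections starting deeper always start after their parent's section)
  for (s in starts[order(starts)]) {
    chain <- s
    i <- s
    while (nchild[i] == 1L) {
      j <- children_of[[i]]
      if (morph$type[j] != morph$type[i]) break
      chain <- c(chain, j)
      i <- j
    }
    anchor <- pidx[s]  # endpoint of an earlier section (or root)
    pts <- rbind(as.matrix(morph[anchor, c("x", "y", "z")]),
                 as.matrix(morph[chain, c("x", "y", "z")]))
    rad <- c(morph$radius[anchor], morph$radius[chain])
    seg <- sqrt(rowSums(diff(pts)^2))
    L <- sum(seg)
    if (max(seg) <= resolution + 1e-9) {
      # already sampled at least this finely: keep the nodes as they are
      k <- length(chain)
      ids <- next_id + seq_len(k)
      next_id <- next_id + k
      out[[length(out) + 1L]] <- data.frame(
        id = ids, type = morph$type[i], x = pts[-1, 1], y = pts[-1, 2],
        z = pts[-1, 3], radius = rad[-1],
        parent = c(id_map[anchor], ids[-k]))
      id_map[i] <- ids[k]
      next
    }
    k <- max(1L, ceiling(L / resolution))
    tgt <- seq_len(k) / k * L
    cum <- c(0, cumsum(seg))
    # interpolate positions along the polyline at arc positions tgt
    piece <- findInterval(tgt, cum, rightmost.closed = TRUE)
    piece <- pmin(piece, length(seg))
    frac <- ifelse(seg[piece] > 0, (tgt - cum[piece]) / seg[piece], 1)
    newpts <- pts[piece, , drop = FALSE] +
      (pts[piece + 1, , drop = FALSE] - pts[piece, , drop = FALSE]) * frac
    newrad <- rad[piece] + (rad[piece + 1] - rad[piece]) * frac
    ids <- next_id + seq_len(k)
    next_id <- next_id + k
    parents <- c(id_map[anchor], ids[-k])
    out[[length(out) + 1L]] <- data.frame(
      id = ids, type = morph$type[i], x = newpts[, 1], y = newpts[, 2],
      z = newpts[, 3], radius = newrad, parent = parents)
    id_map[i] <- ids[k]   # section end keeps identity for downstream chains
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$id), ]
  rownames(tab) <- NULL
  morphology(tab)
}

#' Morphometric summary of a morphology
#'
#' Reports total dendritic and axonal path length, branch point and
#' primary-dendrite counts, the maximum Euclidean distance of any node
#' from the soma, and a Sholl profile (number of segments crossing
#' concentric spheres centred on the soma).
#'
#' @param morph a [morphology()].
#' @param sholl_radii radii (µm) for the Sholl profile; default every
#'   10 µm out to the arbor's maximal extent.
#' @return A list of class `morphometry_report` with fields
#'   `total_dendritic_length`, `total_axonal_length`, `n_branch_points`,
#'   `n_primary_dendrites`, `max_euclidean_distance_from_soma`, and
#'   `sholl` (data.frame radius/crossings).
#' @export
morphometry <- function(morph, sholl_radii = NULL) {
  validate_morphology(morph)
  pidx <- parent_index(morph)
  seg <- segment_lengths(morph)
  dend <- is_dendrite_type(morph$type) & !is.na(pidx)
  axon <- is_axon_type(morph$type) & !is.na(pidx)
  soma <- soma_position(morph)
  root <- which(is.na(pidx))

  # branch point: node with >= 2 children of the same structure class
  kids <- data.frame(p = pidx, dend = is_dendrite_type(morph$type),
                     axon = is_axon_type(morph$type))
  kids <- kids[!is.na(kids$p) & kids$p != root, ]
  nb <- 0L
  if (nrow(kids)) {
    dtab <- table(kids$p[kids$dend])
    atab <- table(kids$p[kids$axon])
    nb <- sum(dtab >= 2) + sum(atab >= 2)
  }
  n_primary <- sum(morph$parent == morph$id[root] & is_dendrite_type(morph$type))

  euclid <- sqrt((morph$x - soma[1])^2 + (morph$y - soma[2])^2 + (morph$z - soma[3])^2)
  maxdist <- if (nrow(morph) > 1) max(euclid[-root]) else 0

  if (is.null(sholl_radii)) {
    top <- max(10, ceiling(maxdist / 10) * 10)
    sholl_radii <- seq(10, top, by = 10)
  }
  neurite <- !is.na(pidx)
  r_child <- euclid[neurite]
  r_parent <- euclid[pidx[neurite]]
  lo <- pmin(r_child, r_parent)
  hi <- pmax(r_child, r_parent)
  crossings <- vapply(sholl_radii, function(r) sum(lo < r & hi >= r), numeric(1))

  structure(list(
    total_dendritic_length = sum(seg[dend]),
    total_axonal_length = sum(seg[axon]),
    n_branch_points = as.integer(nb),
    n_primary_dendrites = as.integer(n_primary),
    max_euclidean_distance_from_soma = maxdist,
    sholl = data.frame(radius = sholl_radii, crossings = as.integer(crossings))
  ), class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<morphometry> dendrite %.1f um (%d primaries, %d branch points), ",
    "axon %.1f um, max radius %.1f um\n"),
    x$total_dendritic_length, x$n_primary_dendrites, x$n_branch_points,
    x$total_axonal_length, x$max_euclidean_distance_from_soma))
  invisible(x)
}

#' Tabulate morphometry for a set of morphologies
#'
#' @param morphs named list of [morphology()] objects.
#' @return data.frame, one row per morphology.
#' @export
morphometry_table <- function(morphs) {
  rows <- lapply(names(morphs), function(nm) {
    m <- morphometry(morphs[[nm]])
    data.frame(name = nm,
               total_dendritic_length = m$total_dendritic_length,
               total_axonal_length = m$total_axonal_length,
               n_branch_points = m$n_branch_points,
               n_primary_dendrites = m$n_primary_dendrites,
               max_euclidean_distance_from_soma = m$max_euclidean_distance_from_soma)
  })
  do.call(rbind, rows)
}
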