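#' Directed graph of a synapse table
#'
#' Vertices are neurons (typed); there is a directed edge `u -> v` iff
#' at least one synapse connects presynaptic `u` to postsynaptic `v`,
#' with the synapse count kept as the edge weight. Reciprocally
#' connected pairs yield two edges; self-loops are rejected.
#'
#' @param table a synapse table (see [touch_detect()]/[prune()]): a
#'   data.frame with `pre_id`, `post_id` and optionally
#'   `pre_type`/`post_type` columns.
#' @param instances optional placement data.frame (`id`, `cell_type`)
#'   supplying the full vertex set, including unconnected neurons.
#' @return An object of class `striatal_digraph`: list with `vertices`
#'   (data.frame `id`, `cell_type`) and `edges` (data.frame `from`,
#'   `to`, `weight`).
#' @export
digraph_from_synapses <- function(table, instances = NULL) {
  if (any(table$pre_id == table$post_id)) {
    stop("self-synapses are not allowed in a directed graph")
  }
  if (!is.null(instances)) {
    vertices <- data.frame(id = instances$id,
                           cell_type = as.character(instances$cell_type))
  } else {
    ids <- sort(unique(c(table$pre_id, table$post_id)))
    type_of <- c(stats::setNames(as.character(table$pre_type), table$pre_id),
                 stats::setNames(as.character(table$post_type), table$post_id))
    vertices <- data.frame(id = ids,
                           cell_type = unname(type_of[as.character(ids)]))
  }
  if (nrow(table)) {
    key <- paste(table$pre_id, table$post_id)
    w <- table(key)
    parts <- do.call(rbind, strsplit(names(w), " "))
    edges <- data.frame(from = as.integer(parts[, 1]),
                        to = as.integer(parts[, 2]),
                        weight = as.integer(w))
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = integer(0), to = integer(0), weight = integer(0))
  }
  structure(list(vertices = vertices, edges = edges),
            class = "striatal_digraph")
}

#' Construct a digraph directly from vertex and edge sets
#'
#' Convenience constructor for tests and small examples.
#'
#' @param n_vertices number of vertices (ids 1..n).
#' @param edges two-column matrix or data.frame of (from, to) pairs;
#'   an optional third column gives weights (default 1).
#' @param types optional character vector of vertex types.
#' @return A `striatal_digraph`.
#' @export
make_digraph <- function(n_vertices, edges, types = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) == 2) edges$weight <- 1L
  names(edges) <- c("from", "to", "weight")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (anyDuplicated(edges[, 1:2])) stop("at most one edge per ordered pair")
  vertices <- data.frame(id = seq_len(n_vertices),
                         cell_type = if (is.null(types)) NA_character_ else types)
  structure(list(vertices = vertices,
                 edges = edges[order(edges$from, edges$to), , drop = FALSE]),
            class = "striatal_digraph")
}

#' @export
print.striatal_digraph <- function(x, ...) {
  cat(sprintf("<striatal_digraph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

# out-adjacency as list of vertex indices (1-based, sorted)
graph_adjacency <- function(graph) {
  n <- nrow(graph$vertices)
  fi <- match(graph$edges$from, graph$vertices$id)
  ti <- match(graph$edges$to, graph$vertices$id)
  adj <- split(ti, factor(fi, levels = seq_len(n)))
  lapply(adj, function(v) as.integer(sort(v)))
}

#' Count directed cliques (directed flag complex)
#'
#' Counts ordered tuples `(v0, ..., vn)` of distinct vertices with an
#' edge `vi -> vj` for every `i < j` — the simplices of the directed
#' flag complex, the convention used by flag-complex counting tools. A
#' directed n-clique has `n + 1` neurons; `counts[dimension 0]` is the
#' number of (counted) vertices and `counts[dimension 1]` the number of
#' (counted) edges. With a `kernel`, only tuples containing at least one
#' kernel vertex are counted (and dimension-0 counts are kernel
#' vertices), which removes boundary artifacts when the graph is a
#' spatially clipped network.
#'
#' @param graph a `striatal_digraph`.
#' @param kernel optional vector of vertex ids; count only cliques
#'   intersecting this set.
#' @param max_dim maximum clique dimension to count (default 13).
#' @param convention `"tuple"` (default; directed flag complex) or
#'   `"set"` (vertex sets that are all-to-all connected with a unique
#'   source and unique sink; exhaustive, only for small graphs).
#' @param keep_cliques also return the clique tuples (vertex ids) per
#'   dimension; guarded by `keep_limit`.
#' @param keep_limit maximum number of cliques retained.
#' @return A list of class `clique_counts` with `counts` (named numeric
#'   vector, one entry per dimension 0..max_dim), `max_dimension` (the
#'   largest dimension with a nonzero count) and, if requested,
#'   `cliques` (list of integer matrices of vertex ids per dimension).
#' @export
count_directed_cliques <- function(graph, kernel = NULL, max_dim = 13L,
                                   convention = c("tuple", "set"),
                                   keep_cliques = FALSE, keep_limit = 5e6) {
  convention <- match.arg(convention)
  if (convention == "set") {
    return(brute_force_cliques(graph, kernel = kernel, max_dim = max_dim,
                               convention = "set"))
  }
  n <- nrow(graph$vertices)
  adj <- graph_adjacency(graph)
  mask <- integer(0)
  if (!is.null(kernel)) {
    mask <- as.integer(graph$vertices$id %in% kernel)
    if (sum(mask) == 0) stop("kernel contains no graph vertices")
  }
  res <- flag_count_cpp(n, adj, mask, as.integer(max_dim),
                        keep_cliques, keep_limit)
  counts <- res$counts
  names(counts) <- as.character(0:max_dim)
  out <- list(counts = counts,
              max_dimension = max(c(-1L, which(counts > 0) - 1L)))
  if (keep_cliques) {
    out$cliques <- lapply(res$cliques, function(m) {
      if (is.null(m)) return(NULL)
      matrix(graph$vertices$id[m], nrow = nrow(m))
    })
    names(out$cliques) <- as.character(0:max_dim)
  }
  structure(out, class = "clique_counts")
}

#' @export
print.clique_counts <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat("<clique_counts> max dimension", x$max_dimension, "\n")
  print(nz)
  invisible(x)
}

# all permutations of a vector (small k only)
all_permutations <- function(v) {
  k <- length(v)
  if (k == 1L) return(matrix(v, 1))
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sub <- all_permutations(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

#' Exhaustive directed-clique enumeration (test oracle)
#'
#' Independent brute-force counter: iterates over all vertex subsets,
#' and for the tuple convention counts the orderings of each subset in
#' which every edge points forward. Intended as the oracle against the
#' recursive counter; guarded to small graphs.
#'
#' @inheritParams count_directed_cliques
#' @param guard refuse graphs with more vertices than this.
#' @return A `clique_counts` list (with `cliques` for the tuple
#'   convention).
#' @export
brute_force_cliques <- function(graph, kernel = NULL, max_dim = 13L,
                                convention = c("tuple", "set"), guard = 15L) {
  convention <- match.arg(convention)
  n <- nrow(graph$vertices)
  if (n > guard) stop("brute_force_cliques is guarded to ", guard, " vertices")
  ids <- graph$vertices$id
  A <- matrix(FALSE, n, n)
  fi <- match(graph$edges$from, ids)
  ti <- match(graph$edges$to, ids)
  A[cbind(fi, ti)] <- TRUE
  kern_idx <- if (is.null(kernel)) seq_len(n) else which(ids %in% kernel)
  counts <- stats::setNames(numeric(max_dim + 1), as.character(0:max_dim))
  cliques <- stats::setNames(vector("list", max_dim + 1), as.character(0:max_dim))
  counts["0"] <- length(kern_idx)
  cliques[["0"]] <- matrix(ids[kern_idx], ncol = 1)
  conn <- A | t(A)
  for (k in 2:min(n, max_dim + 1)) {
    if (n < k) break
    subs <- utils::combn(n, k)
    found <- list()
    for (j in seq_len(ncol(subs))) {
      s <- subs[, j]
      if (!is.null(kernel) && !any(s %in% kern_idx)) next
      pairs_ok <- all(conn[s, s][upper.tri(matrix(0, k, k))])
      if (convention == "tuple") {
        if (!pairs_ok) next
        perms <- all_permutations(s)
        for (r in seq_len(nrow(perms))) {
          p <- perms[r, ]
          ok <- TRUE
          for (a in 1:(k - 1)) {
            if (!all(A[p[a], p[(a + 1):k]])) { ok <- FALSE; break }
          }
          if (ok) found[[length(found) + 1L]] <- p
        }
      } else {
        if (!pairs_ok) next
        # set convention: unique source (no incoming within s) and
        # unique sink (no outgoing within s)
        inside <- A[s, s, drop = FALSE]
        src <- sum(colSums(inside) == 0)
        snk <- sum(rowSums(inside) == 0)
        if (src == 1 && snk == 1) found[[length(found) + 1L]] <- s
      }
    }
    counts[as.character(k - 1)] <- length(found)
    if (length(found)) {
      cliques[[as.character(k - 1)]] <- matrix(ids[do.call(rbind, found)],
                                               ncol = k)
    }
  }
  structure(list(counts = counts,
                 max_dimension = max(c(-1L, which(counts > 0) - 1L)),
                 cliques = cliques),
            class = "clique_counts")
}

#' Kernel/core selection for boundary-free clique analysis
#'
#' Picks the `k` neurons nearest the centre of the placement volume with
#' the requested type composition (ties broken by lower id) as the
#' kernel; the core is the kernel plus every pre- and postsynaptic
#' partner of a kernel neuron.
#'
#' @param placement a placement from [place_neurons()].
#' @param graph a `striatal_digraph` built on the same neurons.
#' @param composition named integer vector, e.g. `c(dSPN = 4, iSPN = 4)`.
#' @return A list of class `kernel_core` with `kernel` and `core`
#'   (vertex id vectors).
#' @export
select_kernel_core <- function(placement, graph,
                               composition = c(dSPN = 4L, iSPN = 4L)) {
  inst <- placement$instances
  centre <- rep(attr(placement, "cube_side") / 2, 3)
  d <- sqrt((inst$x - centre[1])^2 + (inst$y - centre[2])^2 +
              (inst$z - centre[3])^2)
  kernel <- integer(0)
  for (ct in names(composition)) {
    cand <- which(inst$cell_type == ct)
    if (length(cand) < composition[[ct]]) {
      stop("not enough ", ct, " neurons for the requested kernel")
    }
    ord <- cand[order(d[cand], inst$id[cand])]
    kernel <- c(kernel, inst$id[ord[seq_len(composition[[ct]])]])
  }
  e <- graph$edges
  partners <- unique(c(e$to[e$from %in% kernel], e$from[e$to %in% kernel]))
  core <- sort(unique(c(kernel, partners)))
  structure(list(kernel = sort(kernel), core = core), class = "kernel_core")
}

#' Restrict a digraph to an induced vertex subset
#'
#' @param graph a `striatal_digraph`.
#' @param ids vertex ids to keep.
#' @return The induced `striatal_digraph`.
#' @export
induced_subgraph <- function(graph, ids) {
  v <- graph$vertices[graph$vertices$id %in% ids, , drop = FALSE]
  e <- graph$edges[graph$edges$from %in% ids & graph$edges$to %in% ids, ,
                   drop = FALSE]
  rownames(v) <- rownames(e) <- NULL
  structure(list(vertices = v, edges = e), class = "striatal_digraph")
}

#' Classify cliques by cell-type composition
#'
#' Partitions cliques into the exhaustive, mutually exclusive classes:
#' `all_dSPN`, `all_iSPN`, `contains_interneuron` (FS, ChIN or LTS;
#' takes precedence) and `mixed_dSPN_iSPN`.
#'
#' @param cliques an integer matrix of clique vertex ids (one row per
#'   clique) or a list of such matrices keyed by dimension (as returned
#'   in `clique_counts$cliques`).
#' @param types named character vector mapping vertex id to cell type.
#' @return data.frame with columns `dimension`, `class`, `count`.
#' @export
classify_cliques <- function(cliques, types) {
  interneurons <- c("FS", "ChIN", "LTS")
  classify_mat <- function(m, dim) {
    if (is.null(m) || nrow(m) == 0) return(NULL)
    tm <- matrix(types[as.character(m)], nrow = nrow(m))
    if (anyNA(tm)) stop("clique contains a vertex with unknown type")
    has_in <- apply(tm, 1, function(r) any(r %in% interneurons))
    all_d <- apply(tm, 1, function(r) all(r == "dSPN"))
    all_i <- apply(tm, 1, function(r) all(r == "iSPN"))
    cls <- ifelse(has_in, "contains_interneuron",
                  ifelse(all_d, "all_dSPN",
                         ifelse(all_i, "all_iSPN", "mixed_dSPN_iSPN")))
    data.frame(dimension = dim, class = factor(
      cls, levels = c("all_dSPN", "all_iSPN", "contains_interneuron",
                      "mixed_dSPN_iSPN")))
  }
  if (is.matrix(cliques)) {
    rows <- list(classify_mat(cliques, ncol(cliques) - 1L))
  } else {
    rows <- lapply(names(cliques), function(d)
      classify_mat(cliques[[d]], as.integer(d)))
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) {
    return(data.frame(dimension = integer(0), class = character(0),
                      count = integer(0)))
  }
  agg <- as.data.frame(table(dimension = long$dimension, class = long$class))
  names(agg) <- c("dimension", "class", "count")
  agg$dimension <- as.integer(as.character(agg$dimension))
  agg[order(agg$dimension, agg$class), ]
}

#' Histogram of per-clique synapse totals
#'
#' For each clique, sums the synapse multiplicities (edge weights) over
#' every ordered vertex pair of the clique that is an edge of the graph
#' (including reciprocal edges, when present).
#'
#' @param cliques integer matrix of clique vertex ids (one row per
#'   clique), e.g. one dimension slice of `clique_counts$cliques`.
#' @param graph the weighted `striatal_digraph`.
#' @return data.frame `n_synapses`/`n_cliques`; total mass equals the
#'   clique count.
#' @export
synapse_count_histogram <- function(cliques, graph) {
  if (is.null(cliques) || nrow(cliques) == 0) {
    return(data.frame(n_synapses = integer(0), n_cliques = integer(0)))
  }
  wmap <- stats::setNames(graph$edges$weight,
                          paste(graph$edges$from, graph$edges$to))
  k <- ncol(cliques)
  tot <- numeric(nrow(cliques))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      w <- wmap[paste(cliques[, a], cliques[, b])]
      tot <- tot + ifelse(is.na(w), 0, w)
    }
  }
  tab <- table(tot)
  data.frame(n_synapses = as.integer(names(tab)),
             n_cliques = as.integer(tab))
}

#' Clique-count decay under random synapse erosion
#'
#' For each erosion fraction, repeatedly removes a random fraction of
#' synapses ([erode_synapses()]), rebuilds the digraph and counts
#' directed cliques; reports per-dimension mean counts. Used to ask how
#' much random synapse loss mimics interneuron ablation.
#'
#' @param table a synapse table.
#' @param fractions erosion fractions in `[0, 1]`.
#' @param scope `"all"` or `"SPN_only"` (erode only SPN-SPN synapses).
#' @param reps repetitions per fraction.
#' @param seed integer seed.
#' @param instances optional placement instances for the vertex set.
#' @inheritParams count_directed_cliques
#' @return data.frame with `fraction`, `dimension`, `mean_count`.
#' @export
erosion_curves <- function(table, fractions, scope = c("all", "SPN_only"),
                           reps = 3L, seed = 1L, instances = NULL,
                           kernel = NULL, max_dim = 13L) {
  scope <- match.arg(scope)
  rows <- list()
  for (f in fractions) {
    acc <- matrix(0, reps, max_dim + 1)
    for (r in seq_len(reps)) {
      eroded <- erode_synapses(table, f, scope = scope,
                               seed = seed + 1000L * r + round(1e4 * f))
      g <- digraph_from_synapses(eroded, instances = instances)
      cc <- count_directed_cliques(g, kernel = kernel, max_dim = max_dim)
      acc[r, ] <- cc$counts
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, dimension = 0:max_dim, mean_count = colMeans(acc))
  }
  do.call(rbind, rows)
}
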