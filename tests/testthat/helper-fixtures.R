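# Hand-built morphologies with known geometry ------------------------------

# soma at origin + one straight dendrite along x
straight_dendrite <- function(length = 30, n_points = 1) {
  xs <- seq(0, length, length.out = n_points + 1)[-1]
  morphology(data.frame(
    id = seq_len(n_points + 1), type = c(1L, rep(3L, n_points)),
    x = c(0, xs), y = 0, z = 0, radius = c(6, rep(0.6, n_points)),
    parent = c(-1L, seq_len(n_points))))
}

# 30 um stem along x, then two 15 um children, both heading outward so
# each crosses the 35 um sphere
y_tree <- function() {
  morphology(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 30, 45, 39), y = c(0, 0, 0, 12), z = 0,
    radius = c(6, 0.6, 0.6, 0.6), parent = c(-1L, 1L, 2L, 2L)))
}

# k straight radial dendrites of the given length
star_morphology <- function(k = 8, length = 500) {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  morphology(data.frame(
    id = 1:(k + 1), type = c(1L, rep(3L, k)),
    x = c(0, length * cos(ang)), y = c(0, length * sin(ang)), z = 0,
    radius = c(6, rep(0.6, k)), parent = c(-1L, rep(1L, k))))
}

# small morphology library + placement for touch-detection toys
toy_network <- function(n_neurons = 10, cube = 100, seed = 2,
                        dend_len = 400, axon_len = 600) {
  specs <- list(
    dSPN = morphgen_spec("dSPN", target_total_length = dend_len,
                         target_terminal_count = 8,
                         axon_total_length = axon_len,
                         axon_terminal_count = 5,
                         dendrite_extent = 80, axon_extent = 100),
    iSPN = morphgen_spec("iSPN", target_total_length = dend_len,
                         target_terminal_count = 8,
                         axon_total_length = axon_len,
                         axon_terminal_count = 5,
                         dendrite_extent = 80, axon_extent = 100))
  morphs <- generate_morphology_library(c("dSPN", "iSPN"), n_each = 1,
                                        seed = seed, specs = specs)
  pc <- placement_config(cube_side = cube,
                         density = n_neurons / (cube / 1000)^3,
                         composition = c(dSPN = 0.5, iSPN = 0.5),
                         seed = seed)
  list(placement = place_neurons(pc), morphologies = morphs)
}

canon_tab <- function(x) {
  x <- x[do.call(order, x), , drop = FALSE]
  rownames(x) <- NULL
  x
}

# random digraph with edge probability p (no self-loops)
random_digraph <- function(n, p, seed, types = NULL) {
  old <- striatnet:::withr_seed(seed)
  on.exit(striatnet:::restore_seed(old))
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  make_digraph(n, pairs[keep, c("from", "to")], types = types)
}

# transitive tournament: edge i -> j for all i < j
transitive_tournament <- function(n) {
  e <- t(utils::combn(n, 2))
  make_digraph(n, e)
}

# Desk-scale striatal network fixture, built once per test session -------
# (about 270 neurons at full striatal density in a 150 um cube, full-size
# synthetic morphologies, PD0 plus hybrid-method PD2)
.network_cache <- new.env(parent = emptyenv())

desk_network <- function() {
  if (!is.null(.network_cache$net)) return(.network_cache$net)
  morphs <- generate_morphology_library(
    c("dSPN", "iSPN", "FS", "ChIN", "LTS"), n_each = 2, seed = 11)
  pl <- place_neurons(placement_config(cube_side = 150, seed = 12,
                                       morph_variants = 2))
  rules <- default_pruning_rules()
  putative <- touch_detect(pl, morphs, 3, 10)
  pd0 <- prune(putative, rules, seed = 13)
  ms2 <- stage_morphologies(morphs, "PD2")
  pd2 <- build_pd_network(pd0, pl, ms2, "PD2", pd_build_method("hybrid"),
                          rules, seed = 13)
  net <- list(morphologies = morphs, placement = pl, rules = rules,
              putative = putative, pd0 = pd0, ms2 = ms2, pd2 = pd2)
  .network_cache$net <- net
  net
}

# kernel-filtered clique counts on the core; the core is always chosen
# from the full network so ablated and full counts are comparable
kernel_counts <- function(table, placement, max_dim = 13,
                          ablate = FALSE) {
  g_full <- digraph_from_synapses(table, instances = placement$instances)
  sel <- select_kernel_core(placement, g_full)
  g <- if (ablate) {
    digraph_from_synapses(ablate_types(table, c("FS", "ChIN", "LTS")),
                          instances = placement$instances)
  } else g_full
  count_directed_cliques(induced_subgraph(g, sel$core),
                         kernel = sel$kernel, max_dim = max_dim)
}
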