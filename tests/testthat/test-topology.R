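test_that("synapse multiplicity collapses to weighted edges", {
  tab <- data.frame(pre_id = c(1, 1, 1, 1, 2), post_id = c(2, 2, 2, 2, 1),
                    pre_type = "dSPN", post_type = "iSPN")
  g <- digraph_from_synapses(tab)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$weight[g$edges$from == 1], 4)
  expect_equal(g$edges$weight[g$edges$from == 2], 1)
  expect_error(digraph_from_synapses(data.frame(pre_id = 1, post_id = 1)),
               "self-synapses")
  # empty table with an instance list still yields all vertices
  inst <- data.frame(id = 1:5, cell_type = "dSPN")
  g0 <- digraph_from_synapses(tab[0, ], instances = inst)
  expect_equal(nrow(g0$vertices), 5)
  expect_equal(nrow(g0$edges), 0)
})

test_that("transitive tournaments have binomial clique counts", {
  for (n in 4:8) {
    cc <- count_directed_cliques(transitive_tournament(n), max_dim = n)
    expect_equal(unname(cc$counts[1:n]), choose(n, 1:n))
    expect_equal(cc$max_dimension, n - 1L)
  }
})

test_that("cycles and reciprocal pairs form no directed 2-cliques", {
  cyc <- make_digraph(3, rbind(c(1, 2), c(2, 3), c(3, 1)))
  cc <- count_directed_cliques(cyc, max_dim = 3)
  expect_equal(unname(cc$counts[["2"]]), 0)
  recip <- make_digraph(2, rbind(c(1, 2), c(2, 1)))
  cr <- brute_force_cliques(recip, max_dim = 3)
  expect_equal(unname(cr$counts[["1"]]), 2)
  expect_equal(unname(cr$counts[["2"]]), 0)
  # complete symmetric digraph on 3 vertices: all 3! orderings count
  full3 <- make_digraph(3, expand.grid(from = 1:3, to = 1:3)[
    expand.grid(from = 1:3, to = 1:3)$from != expand.grid(from = 1:3, to = 1:3)$to, ])
  expect_equal(unname(count_directed_cliques(full3, max_dim = 3)$counts[["2"]]), 6)
  # ... but as a vertex set it has no unique source or sink
  expect_equal(unname(count_directed_cliques(full3, max_dim = 3,
                                             convention = "set")$counts[["2"]]), 0)
})

test_that("the flag counter agrees with brute force on random digraphs", {
  for (seed in 1:50) {
    n <- 5 + seed %% 6
    g <- random_digraph(n, 0.3, seed = seed)
    fast <- count_directed_cliques(g, max_dim = 12)
    slow <- brute_force_cliques(g, max_dim = 12)
    expect_equal(fast$counts, slow$counts)
  }
})

test_that("counts at dimensions 0 and 1 equal vertex and edge counts", {
  for (seed in c(3, 17)) {
    g <- random_digraph(9, 0.35, seed = seed)
    cc <- count_directed_cliques(g, max_dim = 8)
    expect_equal(unname(cc$counts[["0"]]), nrow(g$vertices))
    expect_equal(unname(cc$counts[["1"]]), nrow(g$edges))
  }
})

test_that("the kernel filter keeps exactly the cliques meeting the kernel", {
  for (seed in 1:10) {
    g <- random_digraph(8, 0.4, seed = 100 + seed)
    kernel <- c(1, 2)
    fast <- count_directed_cliques(g, kernel = kernel, max_dim = 8)
    slow <- brute_force_cliques(g, kernel = kernel, max_dim = 8)
    expect_equal(fast$counts, slow$counts)
    expect_equal(unname(fast$counts[["0"]]), length(kernel))
  }
})

test_that("vertex ablation never increases counts at any dimension", {
  g <- random_digraph(10, 0.45, seed = 7, types = rep(c("dSPN", "FS"), 5))
  cc_all <- count_directed_cliques(g, max_dim = 9)
  sub <- induced_subgraph(g, g$vertices$id[g$vertices$cell_type == "dSPN"])
  cc_sub <- count_directed_cliques(sub, max_dim = 9)
  expect_true(all(cc_sub$counts <= cc_all$counts))
})

test_that("clique composition classes partition the clique set", {
  types <- c(`1` = "dSPN", `2` = "dSPN", `3` = "iSPN", `4` = "FS",
             `5` = "iSPN")
  g <- random_digraph(5, 0.7, seed = 12,
                      types = unname(types[as.character(1:5)]))
  cc <- count_directed_cliques(g, max_dim = 4, keep_cliques = TRUE)
  cls <- classify_cliques(cc$cliques, types)
  for (d in 1:4) {
    expect_equal(sum(cls$count[cls$dimension == d]),
                 unname(cc$counts[[as.character(d)]]))
  }
  # precedence: any interneuron wins over mixed SPN content
  one <- matrix(c(4, 1, 3), nrow = 1)
  cls1 <- classify_cliques(one, types)
  expect_equal(cls1$count[cls1$class == "contains_interneuron"], 1)
  pure <- classify_cliques(matrix(c(3, 5), nrow = 1), types)
  expect_equal(pure$count[pure$class == "all_iSPN"], 1)
})

test_that("per-clique synapse totals sum the weights of internal edges", {
  g <- make_digraph(3, data.frame(from = c(1, 1, 2), to = c(2, 3, 3),
                                  weight = c(4, 1, 2)))
  cc <- count_directed_cliques(g, max_dim = 2, keep_cliques = TRUE)
  h <- synapse_count_histogram(cc$cliques[["2"]], g)
  expect_equal(h$n_synapses, 7)
  expect_equal(h$n_cliques, 1)
  # histogram mass equals the clique count at that dimension
  gr <- random_digraph(7, 0.5, seed = 3)
  ccr <- count_directed_cliques(gr, max_dim = 6, keep_cliques = TRUE)
  for (d in 2:3) {
    m <- ccr$cliques[[as.character(d)]]
    if (is.null(m) || nrow(m) == 0) next
    hh <- synapse_count_histogram(m, gr)
    expect_equal(sum(hh$n_cliques), unname(ccr$counts[[as.character(d)]]))
    # unit weights concentrate at the feedforward edge count
    expect_true(all(hh$n_synapses >= d * (d + 1) / 2))
  }
})

test_that("kernel and core selection obeys the adjacency definition", {
  net <- toy_network(n_neurons = 12, seed = 6)
  tab <- touch_detect(net$placement, net$morphologies, 3, 10)
  g <- digraph_from_synapses(tab, instances = net$placement$instances)
  sel <- select_kernel_core(net$placement, g,
                            composition = c(dSPN = 2, iSPN = 2))
  expect_length(sel$kernel, 4)
  expect_true(all(sel$kernel %in% sel$core))
  e <- g$edges
  for (v in setdiff(sel$core, sel$kernel)) {
    expect_true(any(e$from == v & e$to %in% sel$kernel) ||
                  any(e$to == v & e$from %in% sel$kernel))
  }
  expect_error(select_kernel_core(net$placement, g,
                                  composition = c(FS = 1)),
               "not enough")
})

test_that("erosion curves shrink from the baseline to vertices only", {
  g <- random_digraph(10, 0.5, seed = 4, types = rep("dSPN", 10))
  tab <- data.frame(pre_id = g$edges$from, post_id = g$edges$to,
                    pre_type = "dSPN", post_type = "dSPN")
  inst <- data.frame(id = 1:10, cell_type = "dSPN")
  cur <- erosion_curves(tab, fractions = c(0, 0.5, 1), reps = 2,
                        seed = 9, instances = inst, max_dim = 6)
  base <- cur$mean_count[cur$fraction == 0]
  full <- cur$mean_count[cur$fraction == 1]
  cc <- count_directed_cliques(digraph_from_synapses(tab, instances = inst),
                               max_dim = 6)
  expect_equal(base, unname(cc$counts))
  expect_equal(full[1], 10)        # vertices survive
  expect_equal(sum(full[-1]), 0)   # nothing else does
  mid <- cur$mean_count[cur$fraction == 0.5]
  expect_true(all(mid <= base + 1e-9))
})
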