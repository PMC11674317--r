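# PD-stage network construction on a small toy circuit; the desk-scale
# directional reproductions live in test-acceptance.R.

toy_pd_setup <- function() {
  net <- toy_network(n_neurons = 12, seed = 8, dend_len = 600,
                     axon_len = 900)
  rules <- list(default = pruning_rule(f_keep_random = 0.8,
                                       pair_soft_max = 10))
  put <- touch_detect(net$placement, net$morphologies, 3, 10)
  pd0 <- prune(put, rules, seed = 3)
  ms2 <- stage_morphologies(net$morphologies, "PD2")
  list(net = net, rules = rules, pd0 = pd0, ms2 = ms2)
}

test_that("stage PD0 returns the input table for every method", {
  s <- toy_pd_setup()
  for (m in c("degeneration", "de_novo", "hybrid")) {
    expect_identical(build_pd_network(s$pd0, s$net$placement, s$ms2, "PD0",
                                      pd_build_method(m), s$rules, seed = 1),
                     s$pd0)
  }
  expect_error(build_pd_network(s$pd0, s$net$placement, s$ms2, "PDX",
                                pd_build_method(), s$rules, seed = 1),
               "unknown stage")
})

test_that("the degeneration method is a subset of the PD0 table", {
  s <- toy_pd_setup()
  deg <- build_pd_network(s$pd0, s$net$placement, s$ms2, "PD2",
                          pd_build_method("degeneration"), s$rules, seed = 1)
  expect_lt(nrow(deg), nrow(s$pd0))
  key <- function(t) paste(t$pre_id, t$post_id, t$post_node,
                           round(t$post_distance_to_soma, 6))
  expect_true(all(key(deg) %in% key(s$pd0)))
  # every surviving synapse sits on surviving dendrite
  for (ref in unique(s$net$placement$instances$morph_ref)) {
    ids <- s$net$placement$instances$id[
      s$net$placement$instances$morph_ref %in% ref]
    rows <- deg[deg$post_id %in% ids, ]
    expect_true(all(rows$post_node %in% s$ms2[[ref]]$id))
  }
})

test_that("the hybrid method matches de novo per-type-pair counts exactly", {
  s <- toy_pd_setup()
  dn <- build_pd_network(s$pd0, s$net$placement, s$ms2, "PD2",
                         pd_build_method("de_novo"), s$rules, seed = 1)
  hy <- build_pd_network(s$pd0, s$net$placement, s$ms2, "PD2",
                         pd_build_method("hybrid"), s$rules, seed = 1)
  cdn <- table(paste(dn$pre_type, dn$post_type))
  chy <- table(paste(hy$pre_type, hy$post_type))
  expect_identical(as.vector(cdn[sort(names(cdn))]),
                   as.vector(chy[sort(names(chy))]))
  rf <- attr(hy, "remapping_fraction")
  expect_true(all(rf >= 0 & rf <= 1))
  # hybrid rows come from the PD0 table or the de novo table
  key <- function(t) paste(t$pre_id, t$post_id, t$post_node,
                           round(t$post_distance_to_soma, 6))
  expect_true(all(key(hy) %in% c(key(s$pd0), key(dn))))
})
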