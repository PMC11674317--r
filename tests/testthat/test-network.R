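test_that("placement count, composition and determinism follow the config", {
  pc <- placement_config(cube_side = 500, seed = 3)
  pl <- place_neurons(pc)
  expect_equal(nrow(pl$instances), round(80500 * 0.5^3))
  tab <- table(pl$instances$cell_type)
  spn <- (tab[["dSPN"]] + tab[["iSPN"]]) / nrow(pl$instances)
  expect_lt(abs(spn - 0.95), 0.01)
  expect_true(all(pl$instances$x >= 0 & pl$instances$x <= 500))
  pl2 <- place_neurons(pc)
  expect_identical(pl$instances, pl2$instances)
  # zero volume -> empty network
  empty <- place_neurons(placement_config(cube_side = 0, seed = 1))
  expect_equal(nrow(empty$instances), 0)
})

test_that("largest-remainder type apportionment matches fractions", {
  pc <- placement_config(cube_side = 1000, seed = 5)
  pl <- place_neurons(pc)
  n <- nrow(pl$instances)
  tab <- table(pl$instances$cell_type)
  for (ct in names(pc$composition)) {
    expect_lt(abs(tab[[ct]] - pc$composition[[ct]] * n), 1.5)
  }
})

test_that("orthogonal crossing neurites touch once; distant ones never", {
  # pre: one axon segment along x at z = 1; post: one dendrite segment
  # along y at z = 0; they cross mid-segment at distance 1
  pre_m <- morphology(data.frame(
    id = 1:2, type = c(1L, 2L), x = c(-50, 50), y = 0,
    z = c(1, 1), radius = c(1, 0.3), parent = c(-1L, 1L)))
  post_m <- morphology(data.frame(
    id = 1:2, type = c(1L, 3L), x = 0, y = c(-50, 50), z = 0,
    radius = c(1, 0.6), parent = c(-1L, 1L)))
  pl <- list(instances = data.frame(id = 1:2, cell_type = c("dSPN", "iSPN"),
                                    morph_ref = c("pre", "post"),
                                    x = c(0, 0), y = c(0, 0), z = c(0, 0)),
             rotations = list(diag(3), diag(3)))
  class(pl) <- "placement"
  attr(pl, "cube_side") <- 100
  touches <- touch_detect(pl, list(pre = pre_m, post = post_m),
                          max_distance = 3, voxel_size = 10)
  touches <- touches[touches$pre_id == 1 & touches$post_id == 2, ]
  expect_equal(nrow(touches), 1)
  expect_equal(touches$post_distance_to_soma, 50, tolerance = 1)
  # separation beyond twice the threshold: no touches
  pl$instances$z[1] <- 10
  far <- touch_detect(pl, list(pre = pre_m, post = post_m), 3, 10)
  expect_equal(nrow(far[far$pre_id == 1 & far$post_id == 2, ]), 0)
})

test_that("voxel-accelerated touch detection equals the all-pairs scan", {
  net <- toy_network(n_neurons = 10, seed = 2)
  v10 <- touch_detect(net$placement, net$morphologies, 3, 10)
  v7 <- touch_detect(net$placement, net$morphologies, 3, 7)
  brute <- touch_detect_bruteforce(net$placement, net$morphologies, 3)
  expect_gt(nrow(brute), 0)
  expect_equal(canon_tab(v10), canon_tab(brute))
  expect_equal(canon_tab(v7), canon_tab(brute))
})

test_that("pruning stages behave as specified", {
  net <- toy_network(n_neurons = 10, seed = 4)
  put <- touch_detect(net$placement, net$morphologies, 3, 10)
  # all-permissive rules are the identity (plus conductance)
  kept <- prune(put, list(default = pruning_rule()), seed = 1)
  expect_equal(nrow(kept), nrow(put))
  expect_true(all(kept$cond == 0.5))
  # missing rule for an occurring pair errors
  expect_error(prune(put, list(`dSPN>dSPN` = pruning_rule()), seed = 1),
               "no pruning rule")
  # random-keep fraction stays inside binomial bounds
  big <- put[sample(nrow(put), 10000, replace = TRUE), ]
  half <- prune(big, list(default = pruning_rule(f_keep_random = 0.5)),
                seed = 7)
  expect_lt(abs(nrow(half) - 5000), 2.58 * sqrt(10000 * 0.25) + 1)
  # per-pair soft cap
  capped <- prune(put, list(default = pruning_rule(pair_soft_max = 3)),
                  seed = 2)
  per_pair <- table(paste(capped$pre_id, capped$post_id))
  expect_lte(max(per_pair), 3)
  # determinism
  rules <- default_pruning_rules()
  expect_identical(prune(put, rules, seed = 5), prune(put, rules, seed = 5))
})

test_that("the Wilson interval matches its closed form", {
  wi <- wilson_interval(3, 10)
  expect_equal(wi$p_hat, 0.3)
  expect_equal(wi$lower, 0.108, tolerance = 1e-2)
  expect_equal(wi$upper, 0.603, tolerance = 1e-2)
  wi0 <- wilson_interval(0, 12)
  expect_equal(wi0$lower, 0)
})

test_that("connection probability bins pairs by soma distance", {
  inst <- data.frame(id = 1:4, cell_type = c("dSPN", "dSPN", "iSPN", "iSPN"),
                     morph_ref = NA, x = c(0, 10, 20, 200), y = 0, z = 0)
  pl <- structure(list(instances = inst, rotations = vector("list", 4)),
                  class = "placement")
  attr(pl, "cube_side") <- 300
  tab <- data.frame(pre_id = 1, post_id = 3, pre_type = "dSPN",
                    post_type = "iSPN")
  cp <- connection_probability(tab, pl, "dSPN", "iSPN",
                               distance_bins = c(0, 100, 300))
  expect_equal(cp$n_pairs, c(2L, 2L))
  expect_equal(cp$n_connected, c(1L, 0L))
  expect_equal(cp$p_hat[1], 0.5)
})

test_that("ablation and erosion act on the right rows", {
  tab <- data.frame(pre_id = 1:6, post_id = 7:12,
                    pre_type = c("dSPN", "iSPN", "FS", "ChIN", "LTS", "iSPN"),
                    post_type = c("iSPN", "dSPN", "iSPN", "dSPN", "dSPN", "iSPN"))
  ab <- ablate_types(tab, c("FS", "ChIN", "LTS"))
  expect_equal(nrow(ab), 3)
  expect_true(all(ab$pre_type %in% c("dSPN", "iSPN")))
  expect_identical(erode_synapses(tab, 0, seed = 1), tab)
  expect_equal(nrow(erode_synapses(tab, 1, seed = 1)), 0)
  spn_only <- erode_synapses(tab, 1, scope = "SPN_only", seed = 1)
  expect_equal(nrow(spn_only), 3)
  big <- tab[sample(6, 10000, replace = TRUE), ]
  er <- erode_synapses(big, 0.3, seed = 5)
  expect_lt(abs((10000 - nrow(er)) - 3000), 2.58 * sqrt(10000 * 0.21) + 1)
})
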