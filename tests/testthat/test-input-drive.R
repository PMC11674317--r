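test_that("mother-child trains hit their rate and correlation limits", {
  # p = 0: independent children, near-zero mean pairwise correlation
  tr0 <- correlated_spike_trains(50, 5, 0, 50, seed = 8)
  expect_lt(abs(spike_train_correlation(tr0)), 0.02)
  # p = 1: all children identical to the mother
  tr1 <- correlated_spike_trains(5, 5, 1, 20, seed = 9)
  expect_true(all(vapply(tr1, identical, logical(1), tr1[[1]])))
  expect_gt(spike_train_correlation(tr1), 0.99)
  # child rates converge to the target
  trm <- correlated_spike_trains(100, 5, 0.3, 100, seed = 10)
  expect_lt(abs(mean(spike_train_rates(trm)) - 5), 0.4)
  expect_error(correlated_spike_trains(10, 5, 1.2, 10), "correlation")
})

test_that("synapse placement is uniform per arc length and seeded", {
  two <- morphology(data.frame(
    id = 1:3, type = c(1L, 3L, 3L), x = c(0, 100, -100), y = 0, z = 0,
    radius = c(6, 0.6, 0.6), parent = c(-1L, 1L, 1L)))
  pl <- place_synapses(two, 1000, seed = 3)
  on_first <- sum(pl$node == 2)
  expect_lt(abs(on_first - 500), 2.58 * sqrt(1000 * 0.25) + 1)
  expect_identical(pl, place_synapses(two, 1000, seed = 3))
  expect_equal(nrow(place_synapses(two, 0)), 0)
  expect_true(all(pl$arc >= 0 & pl$arc <= 100))
  expect_error(place_synapses(star_morphology(1, 10)[1, ], 5),
               "no dendrite")
})

test_that("surviving fractions track degeneration and the printed estimates", {
  m0 <- generate_morphology(morphgen_spec("dSPN", seed = 21,
                                          axon_total_length = 0))
  expect_equal(surviving_fraction(place_synapses(m0, 500, seed = 1), m0), 1)
  fr <- vapply(1:5, function(i) {
    m <- generate_morphology(morphgen_spec("dSPN", seed = 20 + i,
                                           axon_total_length = 0))
    surviving_fraction(place_synapses(m, 2000, seed = i), degenerate(m, "PD2"))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.475), 0.1)
  # monotone non-increasing across stages at a fixed placement seed
  m <- generate_morphology(morphgen_spec("iSPN", seed = 30,
                                         axon_total_length = 0))
  pl <- place_synapses(m, 1500, seed = 4)
  fs <- vapply(c("PD0", "PD1", "PD2", "PD3"), function(st) {
    surviving_fraction(pl, degenerate(m, st))
  }, numeric(1))
  expect_true(all(diff(fs) <= 1e-12))
})

test_that("strengthening follows the conductance formula exactly", {
  pl <- data.frame(site = 1:95, node = 1L, offset = 0, arc = 0, cond = 0.5)
  class(pl) <- c("synapse_placement", "data.frame")
  spec <- compensation_spec("strengthen", 20, n_syn_PD0 = 200,
                            n_syn_PD2 = 95)
  out <- strengthen(pl, spec)
  expect_equal(out$cond[1] - 0.5, 0.1105, tolerance = 1e-3)
  expect_equal(sum(out$cond), 58.0, tolerance = 1e-9)
  expect_equal(nrow(out), 95)
  # x = 0 is the identity; x = 100 restores the healthy total exactly
  expect_identical(strengthen(pl, compensation_spec("strengthen", 0, 200, 95)),
                   pl)
  full <- strengthen(pl, compensation_spec("strengthen", 100, 200, 95))
  expect_equal(sum(full$cond), 200 * 0.5, tolerance = 1e-12)
})

test_that("rewiring restores counts on surviving dendrite", {
  m0 <- generate_morphology(morphgen_spec("dSPN", seed = 41,
                                          axon_total_length = 0))
  m2 <- degenerate(m0, "PD2")
  pl0 <- place_synapses(m0, 400, seed = 2)
  pl2 <- filter_placement(pl0, m2)
  spec <- compensation_spec("rewire", 100, n_syn_PD0 = 400,
                            n_syn_PD2 = nrow(pl2))
  out <- rewire(pl2, m2, spec, seed = 3)
  expect_equal(nrow(out), 400)
  expect_identical(rewire(pl2, m2, compensation_spec("rewire", 0, 400,
                                                     nrow(pl2)), seed = 3),
                   pl2)
  # every added site anchors to a node of the degenerated morphology
  expect_true(all(out$node %in% m2$id))
  expect_equal(surviving_fraction(out, m2), 1)
})

test_that("the surrogate neuron is silent without input and monotone in drive", {
  neuron <- surrogate_neuron("dSPN_PD0")
  pl <- data.frame(site = 1:10, node = 1L, offset = 0, arc = 0, cond = 0.5)
  class(pl) <- c("synapse_placement", "data.frame")
  quiet <- simulate_surrogate(neuron, pl, list(numeric(0)), 1)
  expect_equal(quiet$rate, 0)
  # output rate is monotone in total synaptic conductance
  m <- generate_morphology(morphgen_spec("dSPN", seed = 51,
                                         axon_total_length = 0))
  base <- place_synapses(m, 3000, seed = 5)
  tr <- correlated_spike_trains(3000, 5, 0, 2, seed = 6)
  rates <- vapply(c(0.5, 1.5, 3), function(scale) {
    p <- base
    p$cond <- p$cond * scale
    simulate_surrogate(neuron, p, tr, 2)$rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("disease presets order excitability as reported", {
  d0 <- surrogate_neuron("dSPN_PD0"); d2 <- surrogate_neuron("dSPN_PD2")
  i0 <- surrogate_neuron("iSPN_PD0"); i2 <- surrogate_neuron("iSPN_PD2")
  expect_lt(d2$Vth_mV, d0$Vth_mV)  # dSPN more excitable in disease
  expect_gt(i2$Vth_mV, i0$Vth_mV)  # iSPN less excitable
  expect_lt(d2$gL_nS, d0$gL_nS)
  expect_gt(i2$gL_nS, i0$gL_nS)
})
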