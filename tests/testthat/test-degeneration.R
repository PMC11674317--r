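test_that("one truncation step removes exactly the step length at a terminal", {
  m <- resample(straight_dendrite(30, 1), 3)
  m1 <- degenerate_step(m, 3)
  expect_equal(morphometry(m1)$total_dendritic_length, 27)
  # a 2 um stub hanging off a branch point is removed entirely
  stub <- morphology(data.frame(
    id = 1:4, type = c(1L, 3L, 3L, 3L),
    x = c(0, 3, 6, 3), y = c(0, 0, 0, 2), z = 0,
    radius = c(6, 0.6, 0.6, 0.6), parent = c(-1L, 1L, 2L, 2L)))
  s1 <- degenerate_step(stub, 3)
  expect_equal(morphometry(s1)$total_dendritic_length, 3)
  expect_false(4L %in% s1$id)
})

test_that("Y-tree truncation dissolves the branch point then erodes the stem", {
  y <- resample(y_tree(), 3)
  m <- y
  for (i in 1:5) m <- degenerate_step(m, 3)
  expect_equal(morphometry(m)$total_dendritic_length, 30)
  expect_equal(morphometry(m)$n_branch_points, 0L)
  for (i in 6:10) m <- degenerate_step(m, 3)
  expect_equal(morphometry(m)$total_dendritic_length, 15)
})

test_that("stage degeneration follows the schedule and PD0 is the identity", {
  m <- generate_morphology(morphgen_spec("dSPN", seed = 3,
                                         axon_total_length = 0))
  expect_identical(degenerate(m, "PD0"), m)
  expect_error(degenerate(m, "PD9"), "unknown stage")
  sched <- degeneration_schedule()
  m10 <- m
  for (i in 1:10) m10 <- degenerate_step(m10, sched$step_length)
  expect_equal(morphometry(degenerate(m, "PD1"))$total_dendritic_length,
               morphometry(m10)$total_dendritic_length)
})

test_that("dendritic length decreases strictly and structure counts never rise", {
  for (seed in c(2, 9)) {
    m <- generate_morphology(morphgen_spec("iSPN", seed = seed))
    prev <- morphometry(m)
    stages <- c("PD1", "PD2", "PD3")
    for (st in stages) {
      cur <- morphometry(degenerate(m, st))
      expect_lt(cur$total_dendritic_length, prev$total_dendritic_length)
      expect_lte(cur$n_branch_points, prev$n_branch_points)
      expect_lte(cur$n_primary_dendrites, prev$n_primary_dendrites)
      # the axon is untouched by dendritic degeneration
      expect_equal(cur$total_axonal_length, prev$total_axonal_length)
      prev <- cur
    }
  }
})

test_that("degeneration preserves surviving node identities", {
  m <- generate_morphology(morphgen_spec("dSPN", seed = 5,
                                         axon_total_length = 0))
  d <- degenerate(m, "PD2")
  expect_true(all(d$id %in% m$id))
  # un-truncated interior nodes keep their coordinates
  common <- intersect(d$id, m$id)
  arc_m <- stats::setNames(striatnet:::arc_to_soma(m), m$id)
  arc_d <- stats::setNames(striatnet:::arc_to_soma(d), d$id)
  expect_true(all(arc_d[as.character(common)] <=
                    arc_m[as.character(common)] + 1e-9))
})
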