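test_that("terminal-count calibration follows the stage-loss arithmetic", {
  expect_equal(calibrate_terminal_count(3997.9, 2890.8, 10, 3), 37L)
  expect_equal(calibrate_terminal_count(3116.7, 2362.5, 10, 3), 25L)
  expect_equal(calibrate_terminal_count(100 + 10 * 3, 100, 10, 3), 1L)
  expect_error(calibrate_terminal_count(100, 100), "positive")
})

test_that("generated morphologies are valid, deterministic and on target", {
  sp <- morphgen_spec("dSPN", seed = 31)
  m1 <- generate_morphology(sp)
  m2 <- generate_morphology(sp)
  expect_identical(m1, m2)
  expect_silent(validate_morphology(m1))
  mm <- morphometry(m1)
  expect_equal(mm$total_dendritic_length, 3997.9, tolerance = 1e-6)
  expect_equal(mm$n_primary_dendrites, 8L)
  # terminal count equals the calibrated target
  nchild <- striatnet:::child_counts(m1)
  dend_terms <- sum(striatnet:::is_dendrite_type(m1$type) & nchild == 0)
  expect_equal(dend_terms, 37L)
})

test_that("a terminal count equal to the primary count gives an unbranched star", {
  m <- generate_morphology(morphgen_spec("dSPN", n_primary = 6L,
                                         target_terminal_count = 6L,
                                         target_total_length = 600,
                                         axon_total_length = 0, seed = 3))
  mm <- morphometry(m)
  expect_equal(mm$n_branch_points, 0L)
  expect_equal(mm$n_primary_dendrites, 6L)
  nchild <- striatnet:::child_counts(m)
  expect_equal(sum(striatnet:::is_dendrite_type(m$type) & nchild == 0), 6L)
})

test_that("infeasible generator specs are rejected", {
  expect_error(morphgen_spec("dSPN", target_terminal_count = 4L),
               "infeasible")
  expect_error(morphgen_spec("dSPN", target_total_length = -1), "> 0")
})

test_that("population means converge to the targets across types", {
  for (ct in c("dSPN", "iSPN")) {
    target <- morphgen_spec(ct)$target_total_length
    lens <- vapply(1:20, function(i) {
      m <- generate_morphology(morphgen_spec(ct, seed = 100 + i,
                                             axon_total_length = 0))
      morphometry(m)$total_dendritic_length
    }, numeric(1))
    expect_lt(abs(mean(lens) - target) / target, 0.05)
  }
})

test_that("the library manifest mirrors the generated morphometry", {
  out <- withr::local_tempdir()
  morphs <- generate_morphology_library(c("dSPN", "FS"), n_each = 2,
                                        seed = 5, out_dir = out)
  man <- attr(morphs, "manifest")
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(out, man$file))))
  reread <- read_swc(file.path(out, man$file[1]))
  expect_equal(morphometry(reread)$total_dendritic_length,
               man$total_dendritic_length[1], tolerance = 1e-4)
})
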