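test_that("a minimal SWC file round-trips through read and write", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 6 -1",
               "2 3 10 0 0 0.6 1",
               "3 3 20 0 0 0.6 2"), path)
  m <- read_swc(path)
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m), 3)
  expect_equal(sum(m$parent == -1), 1)
  expect_equal(morphometry(m)$total_dendritic_length, 20)

  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, out)
  m2 <- read_swc(out)
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("write_swc re-emits ids in topological order and keeps morphometry", {
  m <- generate_morphology(morphgen_spec("dSPN", seed = 4,
                                         axon_total_length = 0))
  d2 <- degenerate(m, "PD2")
  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(d2, out)
  r <- read_swc(out)
  expect_equal(r$id, seq_len(nrow(r)))
  expect_equal(morphometry(r)$total_dendritic_length,
               morphometry(d2)$total_dendritic_length, tolerance = 1e-6)
  expect_equal(morphometry(r)$n_branch_points,
               morphometry(d2)$n_branch_points)
})

test_that("malformed SWC inputs fail with the offending line identified", {
  bad_forward <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 6 -1",
               "2 3 10 0 0 0.6 3",
               "3 3 20 0 0 0.6 1"), bad_forward)
  expect_error(read_swc(bad_forward), "line 2")

  bad_fields <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 6 -1", "2 3 10 0 0.6 1"), bad_fields)
  expect_error(read_swc(bad_fields), "line 2")

  two_roots <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 6 -1", "2 1 50 0 0 6 -1"), two_roots)
  expect_error(read_swc(two_roots), "multiple roots")

  expect_error(read_swc(file.path(tempdir(), "nope.swc")), "no such file")
})

test_that("soma-only morphologies are valid and write as one record", {
  m <- morphology(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                             radius = 6, parent = -1))
  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, out)
  expect_equal(nrow(read_swc(out)), 1)
  mm <- morphometry(m)
  expect_equal(mm$total_dendritic_length, 0)
  expect_equal(mm$n_primary_dendrites, 0L)
})
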