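test_that("generated trees satisfy the topology invariants", {
  for (n in c(1L, 4L, 10L)) {
    tr <- generate_pa_tree(n, mpa_radius = 1.3, radius_dispersion = 0.3,
                           seed = 11)
    seg <- tr$segments
    expect_equal(sum(is.na(seg$parent)), 1L)
    expect_length(outlet_ids(tr, "RPA"), n)
    expect_length(outlet_ids(tr, "LPA"), n)
    expect_true(all(seg$radius > 0) && all(seg$length > 0))
    expect_true(all(seg$radius[seg$id %in% c(principal_id(tr, "RPA"),
                                             principal_id(tr, "LPA"))] <=
                      mpa_radius(tr)))
    expect_equal(seg$area, pi * seg$radius^2, tolerance = 1e-13)
  }
  # n = 1: minimal 3-segment tree, principals are the outlets
  tr1 <- generate_pa_tree(1L, mpa_radius = 1.0)
  expect_equal(nrow(tr1$segments), 3L)
  expect_setequal(outlet_ids(tr1), c(2L, 3L))
  r_pr <- 1.0 * 2^(-1 / 2.3)
  expect_equal(outlet_areas(tr1), rep(pi * r_pr^2, 2), tolerance = 1e-12)
})

test_that("tree generation is deterministic and dispersion-controlled", {
  a <- generate_pa_tree(10, 1.3, 0.3, seed = 7)
  b <- generate_pa_tree(10, 1.3, 0.3, seed = 7)
  expect_identical(a, b)
  # and byte-identical after serialization
  pa <- withr::local_tempfile(fileext = ".json")
  pb <- withr::local_tempfile(fileext = ".json")
  write_tree_json(a, pa); write_tree_json(b, pb)
  expect_identical(readLines(pa), readLines(pb))

  c <- generate_pa_tree(10, 1.3, 0.3, seed = 8)
  expect_false(identical(a$segments$radius, c$segments$radius))

  # zero dispersion: all outlet radii identical within a side
  d <- generate_pa_tree(10, 1.3, 0, seed = 0)
  rr <- d$segments$radius[match(outlet_ids(d, "RPA"), d$segments$id)]
  expect_equal(max(rr) - min(rr), 0)

  expect_error(generate_pa_tree(10, mpa_radius = -1), "positive")
  expect_error(generate_pa_tree(0), "n_outlets_per_side")
})

test_that("summed outlet area exceeds the MPA area (peripheral widening)", {
  tr <- generate_pa_tree(10, 1.3, 0.3, seed = 2)
  expect_gt(sum(outlet_areas(tr)), pi * mpa_radius(tr)^2)
})

test_that("tree JSON serialization round-trips exactly", {
  tr <- generate_pa_tree(5, 1.1, 0.25, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, path)
  back <- read_tree_json(path)
  expect_equal(back$segments$radius, tr$segments$radius)
  expect_equal(back$segments$parent, tr$segments$parent)
  writeLines(sub("pahemo-pa-tree/1", "other/9", readLines(path)), path)
  expect_error(read_tree_json(path), "schema")
})

test_that("measurement sites sit one MPA radius past the bifurcation", {
  # inside the principal segment
  tr <- generate_pa_tree(10, mpa_radius = 1.2, radius_dispersion = 0,
                         seed = 0)
  s <- measurement_site(tr, "RPA")
  expect_equal(s$segment_id, principal_id(tr, "RPA"))
  expect_equal(s$arclength, 1.2)

  # arclength bookkeeping across a segment boundary
  seg <- data.frame(
    id = 1:4, parent = c(NA, 1L, 1L, 2L),
    label = c("MPA", "RPA", "LPA", "RPA_d"),
    side = c("MPA", "RPA", "LPA", "RPA"),
    radius = c(1.2, 1.0, 1.0, 0.8), length = c(3, 1.0, 3, 1.0))
  tr2 <- pa_tree(seg)
  s2 <- measurement_site(tr2, "RPA")
  expect_equal(s2$segment_id, 4L)
  expect_equal(s2$arclength, 0.2, tolerance = 1e-12)

  # branch too short: error names the branch
  seg3 <- seg; seg3$length[c(2, 4)] <- c(0.5, 0.5)
  expect_error(measurement_site(pa_tree(seg3), "RPA"), "RPA")

  # MPA site: mid-length section
  sm <- measurement_site(tr, "MPA")
  expect_equal(sm$arclength,
               tr$segments$length[is.na(tr$segments$parent)] / 2)

  # degenerate geometry is rejected at construction
  bad <- tr$segments; bad$radius[1] <- 0
  expect_error(pa_tree(bad[, names(bad) != "area"]), "positive")
})
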