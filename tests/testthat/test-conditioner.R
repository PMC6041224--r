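# property normalization and condition-vector assembly

test_that("fitted statistics capture min/max/mean and one-hot block sizes", {
  props <- data.frame(mw = c(100, 200, 300), logp = c(-1, 0, 4),
                      hbd = c(0L, 1L, 3L), hba = c(0L, 2L, 2L),
                      tpsa = c(0, 50, 100))
  st <- fit_normalization(props)
  expect_equal(st$tpsa, list(min = 0, max = 100, mean = 50))
  expect_identical(st$hbd$max, 3L)
  # block lengths: 3 continuous + (3+1) + (2+1)
  expect_identical(condition_dim(st), 10L)

  expect_error(fit_normalization(props[0, ]), "empty")
  expect_error(fit_normalization(props[1, ]), "degenerate")
  bad <- props; bad$hbd <- c(0.5, 1, 2)
  expect_error(fit_normalization(bad), "integer")
})

test_that("normalization maps endpoints, midpoint and extrapolates linearly", {
  expect_equal(normalize_property(10, 10, 30), -1)
  expect_equal(normalize_property(30, 10, 30), 1)
  expect_equal(normalize_property(20, 10, 30), 0)
  # 10% beyond the maximum lands at 1.2 (out-of-range generation protocol)
  expect_equal(normalize_property(30 + 0.1 * 20, 10, 30), 1.2)
  expect_error(normalize_property(1, 5, 5), "max > min")
  # strictly monotone
  xs <- sort(runif(50, -5, 5))
  ys <- normalize_property(xs, 0, 1)
  expect_true(all(diff(ys) > 0))
})

test_that("condition vectors follow the [MW, LogP, HBD, HBA, TPSA] layout", {
  props <- data.frame(mw = c(100, 300), logp = c(-1, 4), hbd = c(0L, 3L),
                      hba = c(0L, 2L), tpsa = c(10, 100))
  st <- fit_normalization(props)
  at_min <- build_condition(list(mw = 100, logp = -1, hbd = 0, hba = 0,
                                 tpsa = 10), st)
  expect_equal(unname(at_min[1:2]), c(-1, -1))
  expect_equal(unname(at_min[length(at_min)]), -1)
  expect_equal(unname(at_min[3:6]), c(1, 0, 0, 0))  # hbd one-hot
  expect_equal(unname(at_min[7:9]), c(1, 0, 0))     # hba one-hot

  # one-hot blocks always sum to exactly 1
  cond <- build_condition(list(mw = 150, logp = 2, hbd = 2, hba = 1,
                               tpsa = 55), st)
  expect_identical(sum(cond[3:6]), 1)
  expect_identical(sum(cond[7:9]), 1)
  expect_identical(length(cond), condition_dim(st))

  expect_warning(build_condition(list(mw = 150, logp = 2, hbd = 9, hba = 1,
                                      tpsa = 55), st), "clamping")
})

test_that("continuous entries invert to the raw values", {
  corp <- small_corpus()
  st <- fit_normalization(corp$properties)
  row <- corp$properties[11, ]
  cond <- build_condition(row, st)
  back <- invert_condition(cond, st)
  expect_equal(back$mw, row$mw, tolerance = 1e-9)
  expect_equal(back$logp, row$logp, tolerance = 1e-9)
  expect_equal(back$tpsa, row$tpsa, tolerance = 1e-9)
  expect_identical(back$hbd, row$hbd)
  expect_identical(back$hba, row$hba)
})

test_that("molecules inside the fitted corpus stay within [-1, 1]", {
  corp <- small_corpus()
  st <- fit_normalization(corp$properties)
  for (i in c(1, 25, 60)) {
    cond <- build_condition(corp$properties[i, ], st)
    expect_true(all(cond[c(1, 2, length(cond))] >= -1 - 1e-12))
    expect_true(all(cond[c(1, 2, length(cond))] <= 1 + 1e-12))
  }
})

test_that("random conditions have valid structure", {
  st <- fit_normalization(small_corpus()$properties)
  set.seed(31)
  for (i in 1:5) {
    rc <- random_condition(st)
    expect_identical(length(rc), condition_dim(st))
    expect_true(all(rc[c(1, 2, length(rc))] >= -1 & rc[c(1, 2, length(rc))] <= 1))
    nb_d <- st$hbd$max + 1L
    expect_equal(sum(rc[2 + seq_len(nb_d)]), 1)
  }
})

test_that("statistics serialize and reload identically", {
  st <- fit_normalization(small_corpus()$properties)
  path <- withr::local_tempfile(fileext = ".json")
  save_stats(st, path)
  expect_equal(load_stats(path), st)
})
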