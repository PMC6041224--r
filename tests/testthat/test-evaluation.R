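# success rule, accounting tables, distribution shift, latent PCA

test_that("the success rule applies 10%-of-corpus-mean tolerances per property", {
  st <- stats_with_means(mw_mean = 300, logp_mean = 2, hbd_mean = 1,
                         hba_mean = 3, tpsa_mean = 80)
  target <- list(mw = 180.04, logp = 1.31, hbd = 1, hba = 3, tpsa = 63.6)
  rule <- success_rule(target, st)
  expect_equal(unname(rule$tolerances["tpsa"]), 8)
  expect_equal(unname(rule$tolerances["mw"]), 30)

  exact <- as.data.frame(target)
  expect_true(is_success(exact, rule))

  # TPSA tolerance arithmetic: |70 - 63.6| = 6.4 <= 8 ok, |72 - 63.6| = 8.4 not
  near <- exact; near$tpsa <- 70
  expect_true(is_success(near, rule))
  far <- exact; far$tpsa <- 72
  expect_false(is_success(far, rule))

  # integer property with mean 1: tolerance 0.1 forces an exact count match
  off <- exact; off$hbd <- 2
  expect_false(is_success(off, rule))

  # relaxing a property via active_properties
  rule_sweep <- success_rule(target, st,
                             active = c("mw", "hbd", "hba", "tpsa"))
  wild_logp <- exact; wild_logp$logp <- 9
  expect_true(is_success(wild_logp, rule_sweep))
})

test_that("success counts are monotone in the tolerance", {
  st <- stats_with_means()
  target <- list(mw = 250, logp = 2.5, hbd = 1, hba = 3, tpsa = 70)
  set.seed(14)
  cands <- data.frame(mw = rnorm(200, 250, 40), logp = rnorm(200, 2.5, 1),
                      hbd = sample(0:3, 200, TRUE),
                      hba = sample(0:6, 200, TRUE),
                      tpsa = rnorm(200, 70, 15))
  fracs <- c(0.01, 0.05, 0.1, 0.5, 2)
  counts <- vapply(fracs, function(f) {
    sum(is_success(cands, success_rule(target, st, tolerance_fraction = f)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # enormous tolerance accepts everything; vanishing accepts only exact matches
  expect_identical(counts[length(counts)] == 200, TRUE)
  tiny <- success_rule(target, st, tolerance_fraction = 1e-9)
  expect_identical(sum(is_success(cands, tiny)), 0L)
  expect_true(is_success(as.data.frame(target), tiny))
})

test_that("table accounting reproduces the printed success-rate identity", {
  expect_equal(round(success_rate_percent(100, 28840), 3), 0.347)
  expect_equal(round(success_rate_percent(100, 15960), 3), 0.627)
  expect_error(success_rate_percent(1, 0), "positive")
})

test_that("distribution shift reports means, shared bins and tail fraction", {
  set.seed(33)
  ref <- runif(1000, 0, 100)
  same <- distribution_shift(ref, ref)
  expect_equal(same$mean_shift, 0)
  expect_equal(same$fraction_beyond_max, 0)
  expect_identical(same$counts_generated, same$counts_reference)

  shifted <- distribution_shift(ref + 10, ref)
  expect_equal(shifted$mean_shift, 10)

  gen <- runif(1000, 50, 150)
  ds <- distribution_shift(gen, ref)
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(ds$fraction_beyond_max - 0.5), 3 * se + 0.01)

  expect_error(distribution_shift(numeric(), ref), "non-empty")
})

test_that("latent PCA handles degenerate and generic cases", {
  m <- tiny_model()
  # identical molecules -> identical latents -> zero variance on both axes
  res0 <- latent_pca(m, rep(m$corpus$train[1], 4))
  expect_equal(res0$explained_variance_ratio, c(0, 0))
  expect_true(all(res0$coordinates == 0))

  expect_error(latent_pca(m, m$corpus$train[1:2]), "at least 3")

  res <- latent_pca(m, m$corpus$train[1:12])
  expect_identical(dim(res$coordinates), c(12L, 2L))
  expect_true(all(res$explained_variance_ratio >= 0 &
                  res$explained_variance_ratio <= 1))
  # full-component reconstruction identity
  pr <- res$pca
  rebuilt <- pr$x %*% t(pr$rotation)
  rebuilt <- sweep(rebuilt, 2L, pr$center, "+")
  expect_equal(rebuilt, res$latent, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("collinear latent vectors put all variance on the first axis", {
  # the PCA contract on a crafted collinear cloud, via the same machinery
  Z <- outer(seq_len(10), c(1, -2, 0.5))
  pr <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  expect_equal(evr[1], 1)
})

test_that("single-property sweeps relax only the swept property", {
  corp <- small_corpus()
  st <- fit_normalization(corp$properties)
  sw <- sweep_conditions(corp$smiles[1], "logp", values = seq(0, 3, 1), st)
  expect_identical(nrow(sw$conditions), 4L)
  expect_identical(ncol(sw$conditions), condition_dim(st))
  expect_false("logp" %in% sw$rule_template$active)
  # the logp entry varies across the sweep, the others stay fixed
  expect_true(all(diff(sw$conditions[, 2]) > 0))
  expect_identical(length(unique(sw$conditions[, 1])), 1L)
  expect_identical(length(unique(sw$conditions[, ncol(sw$conditions)])), 1L)
})
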