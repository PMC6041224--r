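# latent sampling, stochastic write-out batches, and the attempts accounting

test_that("latent samplers honour their strategy contracts", {
  m <- tiny_model()
  anchor <- m$corpus$train[1]

  expect_error(sampler_spec("around_target"), "anchor")

  # zero-noise limit: exactly the anchor's posterior mean
  sp0 <- sampler_spec("around_target", anchor_smiles = anchor, noise_scale = 0)
  z0 <- sample_latent(sp0, m, n = 2, seed = 1)
  mu <- encode_posterior(m, anchor)$mu
  expect_equal(z0$z[1, ], mu)
  expect_equal(z0$z[2, ], mu)

  # random strategy: seeded and reproducible
  spr <- sampler_spec("random")
  expect_identical(sample_latent(spr, m, n = 3, seed = 5),
                   sample_latent(spr, m, n = 3, seed = 5))

  # around a fixed known molecule: empirical mean approaches the anchor mean
  spk <- sampler_spec("around_known", anchor_smiles = anchor,
                      noise_scale = 0.3)
  zz <- sample_latent(spk, m, n = 4000, seed = 6)$z
  se <- 0.3 / sqrt(4000)
  expect_true(all(abs(colMeans(zz) - mu) < 3 * se))

  # without an anchor, around_known draws anchors from the training set
  zk <- sample_latent(sampler_spec("around_known"), m, n = 5, seed = 7)
  expect_true(all(zk$anchors %in% m$corpus$train))
})

test_that("generate_batch yields one record per write-out, reproducibly", {
  m <- tiny_model()
  cond <- condition_from_smiles(m$corpus$train[2], m$stats)
  z <- rnorm(m$config$latent_dim)
  rec <- generate_batch(m, z, cond, n_writeouts = 40, seed = 12)
  expect_identical(nrow(rec), 40L)
  expect_identical(rec, generate_batch(m, z, cond, n_writeouts = 40, seed = 12))
  # invalid write-outs carry no downstream fields
  expect_true(all(is.na(rec$canonical_smiles[!rec$valid])))
  expect_true(all(is.na(rec$mw[!rec$valid])))
  # valid ones parse and re-canonicalize to themselves
  v <- rec$canonical_smiles[rec$valid & !rec$duplicate]
  if (length(v) > 0) expect_identical(canonicalize(v), v)
})

test_that("a degenerate distribution gives all-valid, all-duplicate records", {
  v <- build_vocabulary(c("CCO"))
  probs <- one_hot_probs(c("C", "C", "O"), v, max_len = 10)
  raw <- molcvae:::.writeout_batch(list_probs <- lapply(seq_len(10), function(t) {
    matrix(probs[t, ], 1)
  }), v, 100)[1, ]
  expect_identical(unique(raw), "CCO")
  rec <- molcvae:::.records_from_raw(raw)
  expect_identical(sum(rec$valid), 100L)
  expect_identical(sum(!rec$duplicate), 1L)  # one unique molecule
})

test_that("generate_until keeps consistent accounting", {
  m <- tiny_model()
  cond <- condition_from_smiles(m$corpus$train[3], m$stats)
  sp <- sampler_spec("random")

  res <- generate_until(m, cond, sp, rule = NULL, n_required = 3,
                        max_attempts = 6, n_writeouts = 20, chunk = 2,
                        seed = 42)
  expect_lte(res$attempts, 6)
  expect_identical(nrow(res$records), res$attempts * 20L)
  expect_gte(nrow(res$records), res$n_valid)
  expect_gte(res$n_valid, res$n_unique)
  expect_gte(res$n_unique, res$n_success)
  expect_equal(res$success_rate,
               success_rate_percent(res$n_success, res$attempts))
  # reproducible end to end
  res2 <- generate_until(m, cond, sp, rule = NULL, n_required = 3,
                         max_attempts = 6, n_writeouts = 20, chunk = 2,
                         seed = 42)
  expect_identical(res$records, res2$records)
  # the unique set has no repeated canonical SMILES
  uni <- res$records$canonical_smiles[res$records$valid & !res$records$duplicate]
  expect_identical(anyDuplicated(uni), 0L)

  # exhausted attempt budget is flagged, not an error
  res0 <- generate_until(m, cond, sp, rule = NULL, n_required = 1,
                         max_attempts = 0, n_writeouts = 5, seed = 1)
  expect_false(res0$complete)
  expect_identical(res0$attempts, 0L)
  expect_identical(res0$n_success, 0L)
})
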