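# the CVAE itself: posterior, reparameterization, decoder distributions,
# objective terms, and the hand-derived gradients

test_that("KL term matches its closed form and a Monte-Carlo oracle", {
  expect_identical(kl_term(list(mu = rep(0, 8), sigma = rep(1, 8))), 0)
  expect_equal(kl_term(list(mu = 1, sigma = 1)), 0.5)
  expect_error(kl_term(list(mu = 0, sigma = 0)), "positive")

  # Monte-Carlo oracle: E_q[log q(z) - log p(z)] over 1e6 draws
  set.seed(8)
  mu <- c(0.7, -1.2, 0.3); sigma <- c(0.5, 1.4, 0.9)
  n <- 1e6
  z <- matrix(rnorm(3 * n, mean = mu, sd = sigma), nrow = 3)
  logq <- colSums(dnorm(z, mean = mu, sd = sigma, log = TRUE))
  logp <- colSums(dnorm(z, log = TRUE))
  mc <- mean(logq - logp)
  expect_equal(kl_term(list(mu = mu, sigma = sigma)), mc, tolerance = 0.01)
})

test_that("reconstruction loss matches closed forms and a brute-force loop", {
  v <- build_vocabulary(c("CCO", "CCN"))
  V <- length(v$tokens)
  enc <- encode_smiles("CCO", v, max_len = 10)

  # distributions equal to the target one-hots -> zero loss
  expect_equal(reconstruction_loss(enc$onehot, enc), 0)

  # uniform distributions: L * ln(V) with L the number of scored positions
  unif <- matrix(1 / V, 10, V)
  expect_equal(reconstruction_loss(unif, enc), 10 * log(V))
  expect_equal(reconstruction_loss(unif, enc, mask_after_end = TRUE),
               4 * log(V))  # 'CCO' + terminal E

  # brute-force per-position -sum(y * log p) oracle on random distributions
  set.seed(4)
  probs <- matrix(rexp(10 * V), 10); probs <- probs / rowSums(probs)
  brute <- 0
  for (t in 1:10) brute <- brute - sum(enc$onehot[t, ] * log(probs[t, ]))
  expect_equal(reconstruction_loss(probs, enc), brute)

  expect_error(reconstruction_loss(unif[1:3, ], enc), "mismatch")
})

test_that("reparameterization is seeded and statistically centred on mu", {
  post <- list(mu = c(2, -1), sigma = c(0, 0))
  expect_identical(reparameterize(post), c(2, -1))  # zero-sigma limit
  post2 <- list(mu = c(0.5, 1.5), sigma = c(1, 2))
  expect_identical(reparameterize(post2, seed = 11),
                   reparameterize(post2, seed = 11))
  set.seed(21)
  draws <- replicate(10000, reparameterize(post2))
  se <- post2$sigma / sqrt(10000)
  expect_true(all(abs(rowMeans(draws) - post2$mu) < 3 * se))
})

test_that("encoder posterior has the right shape, is deterministic, and sees the condition", {
  m <- tiny_model()
  s <- m$corpus$train[1]
  p1 <- encode_posterior(m, s)
  p2 <- encode_posterior(m, s)
  expect_identical(p1, p2)
  expect_length(p1$mu, m$config$latent_dim)
  expect_length(p1$sigma, m$config$latent_dim)
  expect_true(all(p1$sigma > 0))

  # different conditions on the same molecule give different posteriors
  c_alt <- condition_from_smiles(m$corpus$train[2], m$stats)
  p3 <- encode_posterior(m, s, condition = c_alt)
  expect_false(isTRUE(all.equal(p1$mu, p3$mu)))

  expect_error(encode_posterior(m, s, condition = c(0, 1)), "condition")
})

test_that("decoder emits max_len softmax rows and responds to z and c", {
  m <- tiny_model()
  cond <- condition_from_smiles(m$corpus$train[1], m$stats)
  z <- rep(0.3, m$config$latent_dim)
  d1 <- decode_step_distributions(m, z, cond)
  expect_identical(nrow(d1), m$config$max_len)
  expect_identical(ncol(d1), m$config$vocab_size)
  expect_true(all(abs(rowSums(d1) - 1) < 1e-6))
  expect_true(all(d1 >= 0))
  expect_identical(d1, decode_step_distributions(m, z, cond))

  # conditioning reaches the decoder
  d2 <- decode_step_distributions(m, z, cond * 0)
  expect_false(isTRUE(all.equal(d1, d2)))
  # and so does the latent vector
  d3 <- decode_step_distributions(m, z + 1, cond)
  expect_false(isTRUE(all.equal(d1, d3)))

  expect_error(decode_step_distributions(m, z[-1], cond), "latent")
})

test_that("the objective decomposes additively", {
  m <- tiny_model()
  s <- m$corpus$train[3]
  l0 <- cvae_loss(m, s, seed = 2, kl_weight = 0)
  expect_identical(l0$total, l0$recon)
  l1 <- cvae_loss(m, s, seed = 2, kl_weight = 1)
  expect_equal(l1$total, l1$recon + l1$kl)
  l2 <- cvae_loss(m, s, seed = 2, kl_weight = 0.3)
  expect_equal(l2$total, l2$recon + 0.3 * l2$kl)
  # same reparameterization seed -> same reconstruction term
  expect_equal(l0$recon, l1$recon)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- cvae_config(vocab_size = 5, condition_dim = 4, embedding_dim = 3,
                     rnn_layers = 2, hidden_units = 4, latent_dim = 3,
                     max_len = 6)
  params <- cvae_init(cfg, seed = 42)
  set.seed(7)
  N <- 3
  idx <- matrix(sample.int(4, N * cfg$max_len, replace = TRUE), N)
  idx[, 5] <- 5L; idx[, 6] <- 5L
  cond <- matrix(rnorm(N * 4), N)
  eps <- matrix(rnorm(N * cfg$latent_dim), N)
  res <- molcvae:::.cvae_grad(idx, cond, params, cfg, eps, kl_weight = 0.7)
  loss_at <- function(p) molcvae:::.cvae_grad(idx, cond, p, cfg, eps, 0.7)$total

  h <- 1e-5
  for (path in molcvae:::.tree_leaves(unclass(params))) {
    w <- molcvae:::.tree_get(params, path)
    gw <- molcvae:::.tree_get(res$grads, path)
    for (i in sample.int(length(w), min(3, length(w)))) {
      p_up <- molcvae:::.tree_set(params, path, replace(w, i, w[i] + h))
      p_dn <- molcvae:::.tree_set(params, path, replace(w, i, w[i] - h))
      num <- (loss_at(p_up) - loss_at(p_dn)) / (2 * h)
      expect_equal(gw[i], num, tolerance = 1e-4,
                   label = paste("grad", paste(path, collapse = "/")))
    }
  }
})

test_that("a few optimizer steps fit a 5-molecule toy corpus", {
  corp <- c("CCO", "CCN", "CCC", "CC=O", "COC")
  vocab <- build_vocabulary(corp)
  cfg <- cvae_config(vocab_size = length(vocab$tokens), condition_dim = 3,
                     embedding_dim = 6, rnn_layers = 1, hidden_units = 24,
                     latent_dim = 4, max_len = 8)
  params <- cvae_init(cfg, seed = 2)
  idx <- molcvae:::.encode_batch(corp, vocab, cfg$max_len)
  set.seed(2)
  cond <- matrix(rnorm(length(corp) * 3), length(corp))
  state <- molcvae:::.adam_init(params)
  losses <- numeric(200)
  for (step in 1:200) {
    eps <- matrix(rnorm(length(corp) * cfg$latent_dim), length(corp))
    res <- molcvae:::.cvae_grad(idx, cond, params, cfg, eps, kl_weight = 1)
    losses[step] <- res$total
    upd <- molcvae:::.adam_step(params, res$grads, state, lr = 5e-3)
    params <- upd$params; state <- upd$state
  }
  expect_lt(losses[200], 0.5 * losses[1])
})
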