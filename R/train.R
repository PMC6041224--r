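#' Training configuration
#'
#' Optimization schedule for the CVAE. Defaults follow the full-scale recipe:
#' initial learning rate 1e-4 decayed exponentially by 0.97 per epoch, an
#' 80/20 train/test split, and early stopping once the held-out loss stops
#' improving. Desk-scale runs on the small fixture corpus use a larger Adam
#' step (see the vignette): at ~600 optimizer steps a 1e-4 step cannot move
#' the parameters appreciably, whereas the full-scale schedule takes millions
#' of steps.
#'
#' @param learning_rate initial learning rate.
#' @param decay_rate per-epoch exponential decay factor in (0, 1].
#' @param split_fraction fraction of the corpus used for training.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param patience epochs without held-out improvement before stopping
#'   (0 disables early stopping only after the first epoch).
#' @param seed RNG seed covering the split, initialization, shuffling and
#'   reparameterization noise.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param kl_warmup_epochs epochs trained with KL weight 0 before the ramp
#'   begins (lets the reconstruction path learn to use the latent code
#'   first; mitigates posterior collapse on small corpora).
#' @param kl_anneal_epochs length of the linear ramp from 0 up to the
#'   configured `kl_weight` after the warm-up; 0 switches to the full weight
#'   immediately after warm-up.
#' @param grad_clip global gradient-norm ceiling (Inf disables clipping).
#' @return object of class `cvae_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, decay_rate = 0.97,
                         split_fraction = 0.8, batch_size = 128L,
                         max_epochs = 30L, patience = 5L, seed = 1L,
                         optimizer = c("adam", "sgd"),
                         kl_warmup_epochs = 0L, kl_anneal_epochs = 0L,
                         grad_clip = 5) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (decay_rate <= 0 || decay_rate > 1) stop("decay_rate must be in (0, 1]")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be strictly between 0 and 1")
  }
  structure(list(learning_rate = learning_rate, decay_rate = decay_rate,
                 split_fraction = split_fraction,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 optimizer = optimizer,
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 kl_anneal_epochs = as.integer(kl_anneal_epochs),
                 grad_clip = grad_clip),
            class = "cvae_train_config")
}

#' Split a corpus into train and test sets
#'
#' Seeded shuffled partition: the two sides are disjoint and their union is
#' the input (as a multiset). The training side has `round(n * fraction)`
#' molecules.
#'
#' @param corpus character vector of SMILES.
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with `train` and `test` character vectors.
#' @export
split_corpus <- function(corpus, fraction = 0.8, seed = 1L) {
  n <- length(corpus)
  if (n == 0L) stop("cannot split an empty corpus")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(n * fraction)
  list(train = corpus[perm[seq_len(n_train)]],
       test = corpus[perm[setdiff(seq_len(n), seq_len(n_train))]])
}

#' Learning-rate schedule
#'
#' Exponential decay: `lr(epoch) = learning_rate * decay_rate^epoch` with
#' `epoch` counted from 0.
#'
#' @param epoch epoch index (0-based).
#' @param config a `cvae_train_config`.
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$learning_rate * config$decay_rate^epoch
}

# Truncated unroll length for a set of token rows: long enough to cover
# every molecule plus a few scored E-padding steps (which teach the decoder
# to keep emitting E), far shorter than max_len for typical batches.
.unroll_len <- function(tok_len, config, extra = 3L) {
  min(config$max_len, max(tok_len) + extra)
}

# mean loss over a set of molecules without gradients (used for the held-out
# monitor); eps noise drawn from the current RNG stream.
.eval_loss <- function(idx, cond, params, config, kl_weight) {
  N <- nrow(idx)
  enc <- .encoder_forward(idx, cond, params, config)
  sigma <- exp(0.5 * enc$logvar)
  eps <- matrix(stats::rnorm(N * config$latent_dim), N)
  z <- enc$mu + sigma * eps
  dec <- .decoder_forward(z, cond, params, config)
  kl_each <- 0.5 * rowSums(enc$mu^2 + exp(enc$logvar) - enc$logvar - 1)
  recon_each <- numeric(N)
  T <- config$max_len
  mask <- if (config$mask_after_end) {
    m <- matrix(0, N, T)
    for (n in seq_len(N)) m[n, seq_len(match(config$vocab_size, idx[n, ]))] <- 1
    m
  } else matrix(1, N, T)
  for (t in seq_len(T)) {
    p <- dec$probs[[t]][cbind(seq_len(N), idx[, t])]
    recon_each <- recon_each - mask[, t] * log(pmax(p, 1e-12))
  }
  mean(recon_each) + kl_weight * mean(kl_each)
}

#' Train the conditional VAE
#'
#' End-to-end corpus preparation and optimization: canonicalizes the corpus,
#' computes the five descriptors, splits train/test, fits the normalization
#' statistics and vocabulary, then minimizes the CVAE objective
#' (reconstruction cross-entropy + KL) with minibatch Adam under the
#' exponential learning-rate schedule. Training stops at `max_epochs` or when
#' the held-out loss has not improved for `patience` epochs.
#'
#' @param smiles character vector of SMILES strings (need not be canonical).
#' @param model_config a `cvae_config`, or `NULL` to build one from
#'   `model_args` plus the corpus-derived vocabulary/condition sizes.
#' @param config a `cvae_train_config`.
#' @param model_args named list passed to [cvae_config()] when
#'   `model_config` is `NULL` (e.g. `list(hidden_units = 96)`).
#' @param verbose print per-epoch progress.
#' @return object of class `cvae_model`: list with `params`, `config`,
#'   `vocab`, `stats` (fitted on the training split), `corpus` (the split),
#'   `properties` (descriptor table of the whole corpus), `history`
#'   (per-epoch loss log) and `train_config`.
#' @export
cvae_train <- function(smiles, model_config = NULL,
                       config = train_config(), model_args = list(),
                       verbose = interactive()) {
  stopifnot(inherits(config, "cvae_train_config"))
  corpus <- unique(canonicalize(smiles))
  props <- compute_properties(corpus)
  split <- split_corpus(corpus, config$split_fraction, config$seed)
  stats <- fit_normalization(props[match(split$train, props$smiles), ])
  vocab <- build_vocabulary(corpus)

  if (is.null(model_config)) {
    model_config <- do.call(cvae_config, c(
      list(vocab_size = length(vocab$tokens),
           condition_dim = condition_dim(stats)),
      model_args))
  }
  stopifnot(inherits(model_config, "cvae_config"))
  if (model_config$vocab_size != length(vocab$tokens)) {
    stop("model_config$vocab_size does not match the corpus vocabulary")
  }
  if (model_config$condition_dim != condition_dim(stats)) {
    stop("model_config$condition_dim does not match the fitted statistics")
  }

  cond_of <- function(smls) {
    t(vapply(smls, function(s) {
      build_condition(props[match(s, props$smiles), ], stats)
    }, numeric(model_config$condition_dim)))
  }
  idx_train <- .encode_batch(split$train, vocab, model_config$max_len)
  idx_test <- .encode_batch(split$test, vocab, model_config$max_len)
  cond_train <- cond_of(split$train)
  cond_test <- cond_of(split$test)

  params <- cvae_init(model_config, seed = config$seed)
  opt_state <- .adam_init(params)
  set.seed(config$seed + 1L)

  n_train <- nrow(idx_train)
  D <- model_config$latent_dim
  history <- data.frame()
  best <- Inf; best_params <- params; stale <- 0L

  # length-bucketed batches: grouping molecules of similar length lets each
  # batch unroll only as far as its longest member, instead of max_len
  tok_train <- nchar(split$train) + 1L
  len_order <- order(tok_train)
  buckets <- split(len_order, ceiling(seq_along(len_order) / config$batch_size))
  tok_test <- nchar(split$test) + 1L
  t_test <- .unroll_len(tok_test, model_config)

  for (epoch in seq_len(config$max_epochs) - 1L) {
    lr <- lr_schedule(epoch, config)
    klw <- if (config$kl_warmup_epochs > 0L || config$kl_anneal_epochs > 0L) {
      past_warm <- epoch - config$kl_warmup_epochs
      ramp <- if (config$kl_anneal_epochs > 0L) {
        min(1, max(0, past_warm + 1) / config$kl_anneal_epochs)
      } else {
        as.numeric(past_warm >= 0)
      }
      model_config$kl_weight * ramp
    } else {
      model_config$kl_weight
    }
    batches <- buckets[sample.int(length(buckets))]
    tr_tot <- tr_rec <- tr_kl <- 0
    for (b in batches) {
      t_b <- .unroll_len(tok_train[b], model_config)
      cfg_b <- model_config; cfg_b$max_len <- t_b
      eps <- matrix(stats::rnorm(length(b) * D), length(b))
      res <- .cvae_grad(idx_train[b, seq_len(t_b), drop = FALSE],
                        cond_train[b, , drop = FALSE],
                        params, cfg_b, eps, kl_weight = klw)
      grads <- .clip_grads(res$grads, opt_state$leaves, config$grad_clip)
      upd <- if (config$optimizer == "adam") {
        .adam_step(params, grads, opt_state, lr)
      } else {
        .sgd_step(params, grads, opt_state, lr)
      }
      params <- upd$params; opt_state <- upd$state
      w <- length(b) / n_train
      tr_tot <- tr_tot + res$total * w
      tr_rec <- tr_rec + res$recon * w
      tr_kl <- tr_kl + res$kl * w
    }
    # held-out monitor at the *full* KL weight so epochs stay comparable
    # while the training weight is still ramping
    cfg_t <- model_config; cfg_t$max_len <- t_test
    test_tot <- .eval_loss(idx_test[, seq_len(t_test), drop = FALSE],
                           cond_test, params, cfg_t, model_config$kl_weight)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, kl_weight = klw, train_total = tr_tot,
      train_recon = tr_rec, train_kl = tr_kl,
      # the full-weight objective: comparable across epochs even while the
      # annealing schedule is still ramping the training weight
      train_objective = tr_rec + model_config$kl_weight * tr_kl,
      test_total = test_tot))
    if (verbose) {
      message(sprintf(
        "epoch %3d  lr %.2e  train %.3f (recon %.3f, kl %.3f)  test %.3f",
        epoch, lr, tr_tot, tr_rec, tr_kl, test_tot))
    }
    if (test_tot < best) {
      best <- test_tot; best_params <- params; stale <- 0L
    } else {
      stale <- stale + 1L
      if (config$patience > 0L && stale >= config$patience) break
    }
  }

  model <- list(params = best_params, config = model_config, vocab = vocab,
                stats = stats, corpus = split, properties = props,
                history = history, train_config = config)
  class(model) <- "cvae_model"
  model
}

#' @export
print.cvae_model <- function(x, ...) {
  cat("Conditional VAE molecular generator\n")
  print(x$config)
  cat(sprintf("  trained on %d molecules (%d held out), %d epochs\n",
              length(x$corpus$train), length(x$corpus$test), nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.3f, held-out loss %.3f\n",
                last$train_total, last$test_total))
  }
  invisible(x)
}
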