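#' Model architecture configuration
#'
#' Hyperparameters of the conditional VAE. The defaults are the full-scale
#' architecture: a 300-dimensional character embedding, 3 recurrent (LSTM)
#' layers of 500 hidden units each for both encoder and decoder, a
#' 200-dimensional latent space and 120 unroll steps. Desk-scale runs on the
#' bundled fixture corpus use much smaller values (see the package vignette).
#'
#' @param vocab_size number of tokens (including the end token `E`).
#' @param condition_dim length of the condition vector ([condition_dim()]).
#' @param embedding_dim character embedding size.
#' @param rnn_layers number of stacked LSTM layers in encoder and decoder.
#' @param hidden_units LSTM hidden state width per layer.
#' @param latent_dim dimension of the latent code z.
#' @param max_len unroll length (maximum SMILES length + 1 for `E`).
#' @param kl_weight weight on the KL term of the objective (1 = the plain
#'   CVAE objective).
#' @param mask_after_end if `TRUE`, reconstruction cross-entropy ignores
#'   positions after the first `E`; the default scores every unroll position
#'   (plain per-position cross-entropy, padding rows repeat `E`).
#' @return object of class `cvae_config`.
#' @export
cvae_config <- function(vocab_size, condition_dim,
                        embedding_dim = 300L, rnn_layers = 3L,
                        hidden_units = 500L, latent_dim = 200L,
                        max_len = 120L, kl_weight = 1,
                        mask_after_end = FALSE) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              condition_dim = as.integer(condition_dim),
              embedding_dim = as.integer(embedding_dim),
              rnn_layers = as.integer(rnn_layers),
              hidden_units = as.integer(hidden_units),
              latent_dim = as.integer(latent_dim),
              max_len = as.integer(max_len),
              kl_weight = kl_weight,
              mask_after_end = isTRUE(mask_after_end))
  ints <- c("vocab_size", "condition_dim", "embedding_dim", "rnn_layers",
            "hidden_units", "latent_dim", "max_len")
  for (f in ints) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sQuote(f), " must be a positive integer")
    }
  }
  if (kl_weight < 0) stop("kl_weight must be >= 0")
  class(cfg) <- "cvae_config"
  cfg
}

#' @export
print.cvae_config <- function(x, ...) {
  cat(sprintf(paste0(
    "CVAE configuration: vocab %d, condition %d, embedding %d,\n",
    "  %d x LSTM(%d), latent %d, max_len %d, kl_weight %g%s\n"),
    x$vocab_size, x$condition_dim, x$embedding_dim, x$rnn_layers,
    x$hidden_units, x$latent_dim, x$max_len, x$kl_weight,
    if (x$mask_after_end) ", loss masked after 'E'" else ""))
  invisible(x)
}

# Xavier-uniform weight matrix
.winit <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# One LSTM stack: per layer a fused gate matrix W ((input + hidden) x 4*hidden)
# and bias b (forget-gate block initialized to 1). Gate order: i, f, g, o.
.lstm_stack_init <- function(in_dim, hidden, layers) {
  lapply(seq_len(layers), function(l) {
    nin <- if (l == 1L) in_dim else hidden
    b <- numeric(4L * hidden)
    b[(hidden + 1L):(2L * hidden)] <- 1
    list(W = .winit(nin + hidden, 4L * hidden), b = b)
  })
}

#' Initialize CVAE parameters
#'
#' @param config a `cvae_config`.
#' @param seed integer RNG seed; the same seed always yields the same
#'   initialization.
#' @return a named list of parameter matrices/vectors (class `cvae_params`).
#' @export
cvae_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cvae_config"))
  set.seed(seed)
  H <- config$hidden_units; D <- config$latent_dim
  params <- list(
    Emb = .winit(config$vocab_size, config$embedding_dim),
    enc = .lstm_stack_init(config$embedding_dim + config$condition_dim,
                           H, config$rnn_layers),
    # log-variance head starts strongly negative so early latent draws stay
    # close to mu; otherwise unit-variance noise swamps the (initially weak)
    # posterior mean and the decoder learns to ignore z before the encoder
    # can make it informative
    Wmu = .winit(H, D), bmu = numeric(D),
    Wlv = .winit(H, D), blv = rep(-4, D),
    dec = .lstm_stack_init(D + config$condition_dim, H, config$rnn_layers),
    Wy = .winit(H, config$vocab_size), by = numeric(config$vocab_size)
  )
  class(params) <- "cvae_params"
  params
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

# Forward pass through one LSTM layer for one step.
# zin: cbind(input, h_prev); returns gates and new (h, c).
.lstm_step <- function(zin, W, b, c_prev, H) {
  a <- zin %*% W
  a <- sweep(a, 2L, b, "+")
  i <- .sigmoid(a[, 1:H, drop = FALSE])
  f <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
  cs <- f * c_prev + i * g
  tc <- tanh(cs)
  list(i = i, f = f, g = g, o = o, c = cs, tc = tc, h = o * tc)
}

# Encoder forward over a batch.
# idx: N x T integer token matrix; cond: N x condition_dim.
# Returns mu, logvar (N x D) and, if keep, the per-step caches for BPTT.
.encoder_forward <- function(idx, cond, params, config, keep = FALSE) {
  N <- nrow(idx); T <- config$max_len; H <- config$hidden_units
  L <- config$rnn_layers
  h <- lapply(seq_len(L), function(l) matrix(0, N, H))
  cs <- lapply(seq_len(L), function(l) matrix(0, N, H))
  cache <- if (keep) {
    lapply(seq_len(L), function(l) vector("list", T))
  }
  for (t in seq_len(T)) {
    inp <- cbind(params$Emb[idx[, t], , drop = FALSE], cond)
    for (l in seq_len(L)) {
      zin <- cbind(inp, h[[l]])
      st <- .lstm_step(zin, params$enc[[l]]$W, params$enc[[l]]$b, cs[[l]], H)
      if (keep) {
        cache[[l]][[t]] <- c(st, list(zin = zin, c_prev = cs[[l]]))
      }
      h[[l]] <- st$h
      cs[[l]] <- st$c
      inp <- st$h
    }
  }
  hT <- h[[L]]
  mu <- sweep(hT %*% params$Wmu, 2L, params$bmu, "+")
  logvar <- sweep(hT %*% params$Wlv, 2L, params$blv, "+")
  list(mu = mu, logvar = logvar, hT = hT, cache = cache)
}

# Decoder forward. The input at *every* unroll step is [z || c]; no token
# feedback, so the step distributions depend only on (z, c, params) and the
# constant-input projection can be computed once per layer-1 pass.
# z: N x D; cond: N x condition_dim.
# Returns probs: list over t of N x V matrices (+ caches when keep).
.decoder_forward <- function(z, cond, params, config, keep = FALSE) {
  N <- nrow(z); T <- config$max_len; H <- config$hidden_units
  L <- config$rnn_layers; V <- config$vocab_size
  u <- cbind(z, cond)
  in1 <- ncol(u)
  W1 <- params$dec[[1L]]$W
  # split layer-1 weights into the constant-input part and the recurrent part
  Wu <- W1[seq_len(in1), , drop = FALSE]
  Wh <- W1[in1 + seq_len(H), , drop = FALSE]
  uproj <- sweep(u %*% Wu, 2L, params$dec[[1L]]$b, "+")
  h <- lapply(seq_len(L), function(l) matrix(0, N, H))
  cs <- lapply(seq_len(L), function(l) matrix(0, N, H))
  cache <- if (keep) lapply(seq_len(L), function(l) vector("list", T))
  probs <- vector("list", T)
  logits_all <- if (keep) vector("list", T)
  for (t in seq_len(T)) {
    # layer 1 (fused constant-input projection)
    a <- uproj + h[[1L]] %*% Wh
    i <- .sigmoid(a[, 1:H, drop = FALSE])
    f <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    cnew <- f * cs[[1L]] + i * g
    tc <- tanh(cnew)
    hnew <- o * tc
    if (keep) {
      cache[[1L]][[t]] <- list(i = i, f = f, g = g, o = o, c = cnew, tc = tc,
                               h_prev = h[[1L]], c_prev = cs[[1L]])
    }
    h[[1L]] <- hnew; cs[[1L]] <- cnew
    inp <- hnew
    if (L > 1L) {
      for (l in 2:L) {
        zin <- cbind(inp, h[[l]])
        st <- .lstm_step(zin, params$dec[[l]]$W, params$dec[[l]]$b, cs[[l]], H)
        if (keep) cache[[l]][[t]] <- c(st, list(zin = zin, c_prev = cs[[l]]))
        h[[l]] <- st$h; cs[[l]] <- st$c
        inp <- st$h
      }
    }
    logits <- sweep(inp %*% params$Wy, 2L, params$by, "+")
    probs[[t]] <- .softmax_rows(logits)
    if (keep) logits_all[[t]] <- inp  # top hidden state feeding the softmax
  }
  list(probs = probs, cache = cache, top_h = logits_all, u = u,
       Wu = Wu, Wh = Wh)
}

#' Encode a molecule to its latent posterior
#'
#' Runs the recurrent encoder on the one-hot SMILES matrix concatenated with
#' the condition vector at every step, and maps the final hidden state to the
#' Gaussian posterior \eqn{Q(z | X, c)}.
#'
#' @param model a trained `cvae_model` (or a list with `params` and `config`).
#' @param x a `tokenized_smiles` from [encode_smiles()], or a SMILES string
#'   (encoded on the fly against the model vocabulary).
#' @param condition numeric condition vector; defaults to the molecule's own
#'   properties under the model's fitted statistics.
#' @return list with `mu` and `sigma` (numeric vectors of length
#'   `latent_dim`), class `latent_posterior`.
#' @export
encode_posterior <- function(model, x, condition = NULL) {
  if (is.character(x)) {
    x <- encode_smiles(canonicalize(x), model$vocab, model$config$max_len)
  }
  stopifnot(inherits(x, "tokenized_smiles"))
  if (is.null(condition)) {
    condition <- condition_from_smiles(x$smiles, model$stats)
  }
  if (length(condition) != model$config$condition_dim) {
    stop("condition vector length ", length(condition),
         " does not match the model's condition_dim ",
         model$config$condition_dim)
  }
  fwd <- .encoder_forward(matrix(x$idx, nrow = 1L),
                          matrix(condition, nrow = 1L),
                          model$params, model$config)
  structure(list(mu = drop(fwd$mu), sigma = exp(0.5 * drop(fwd$logvar))),
            class = "latent_posterior")
}

#' Sample a latent vector from a posterior
#'
#' The reparameterization step: \eqn{z = \mu + \sigma \odot \epsilon} with
#' \eqn{\epsilon \sim N(0, I)}.
#'
#' @param posterior a `latent_posterior` (fields `mu`, `sigma`).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return numeric latent vector.
#' @export
reparameterize <- function(posterior, seed = NULL) {
  if (any(posterior$sigma < 0)) stop("posterior sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  posterior$mu + posterior$sigma * stats::rnorm(length(posterior$mu))
}

#' Decoder step distributions for a (latent, condition) pair
#'
#' Feeds `[z || c]` to the decoder at each of the `max_len` unroll steps and
#' returns the per-step softmax distributions over the vocabulary. All
#' stochastic write-outs for this latent sample from these rows.
#'
#' @param model a `cvae_model` (or list with `params`, `config`).
#' @param z numeric latent vector of length `latent_dim`.
#' @param condition numeric condition vector.
#' @return numeric matrix (`max_len` x `vocab_size`); every row sums to 1.
#' @export
decode_step_distributions <- function(model, z, condition) {
  cfg <- model$config
  if (length(z) != cfg$latent_dim) stop("latent vector has wrong length")
  if (length(condition) != cfg$condition_dim) stop("condition vector has wrong length")
  fwd <- .decoder_forward(matrix(z, nrow = 1L), matrix(condition, nrow = 1L),
                          model$params, cfg)
  out <- do.call(rbind, fwd$probs)
  colnames(out) <- model$vocab$tokens %||% NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#' prior
#'
#' Closed form: \eqn{\frac{1}{2}\sum_d (\mu_d^2 + \sigma_d^2 -
#' \log \sigma_d^2 - 1)}. Non-negative, and zero exactly at the prior
#' (\eqn{\mu = 0, \sigma = 1}).
#'
#' @param posterior a `latent_posterior` or list with `mu` and `sigma`.
#' @return a single non-negative number.
#' @export
kl_term <- function(posterior) {
  mu <- posterior$mu; sigma <- posterior$sigma
  if (any(sigma <= 0)) stop("posterior sigma must be strictly positive")
  0.5 * sum(mu^2 + sigma^2 - 2 * log(sigma) - 1)
}

#' Reconstruction cross-entropy of step distributions against a target
#'
#' Summed per-position categorical cross-entropy
#' \eqn{-\sum_t \sum_v y_{tv} \log p_{tv}} between the decoder's step
#' distributions and the target one-hot rows. By default every unroll
#' position is scored (padding rows repeat `E`); with `mask_after_end` only
#' positions up to and including the first `E` count.
#'
#' @param dists numeric matrix of step distributions (positions x vocab).
#' @param target a `tokenized_smiles` with matching `max_len` and vocabulary
#'   width.
#' @param mask_after_end logical; see Details.
#' @return a single non-negative number.
#' @export
reconstruction_loss <- function(dists, target, mask_after_end = FALSE) {
  stopifnot(inherits(target, "tokenized_smiles"), is.matrix(dists))
  if (nrow(dists) != length(target$idx) || ncol(dists) != ncol(target$onehot)) {
    stop("distribution matrix and target have mismatched dimensions")
  }
  n_pos <- if (mask_after_end) length(target$tokens) else length(target$idx)
  p <- dists[cbind(seq_len(n_pos), target$idx[seq_len(n_pos)])]
  -sum(log(pmax(p, 1e-12)))
}

#' The CVAE objective for one molecule
#'
#' Evaluates the (negated, minimized) conditional VAE objective
#' \eqn{-E[\log P(X|z,c)] + w \cdot D_{KL}[Q(z|X,c) \| P(z|c)]} for a single
#' molecule: encodes it, samples one latent via reparameterization, decodes,
#' and returns the reconstruction cross-entropy, the KL term and their
#' weighted total.
#'
#' @param model a `cvae_model` (or list with `params`, `config`, `vocab`,
#'   `stats`).
#' @param x a `tokenized_smiles` or SMILES string.
#' @param condition condition vector (defaults to the molecule's own).
#' @param seed integer seed for the reparameterization draw.
#' @param kl_weight overrides the config's KL weight if given.
#' @return list with `total`, `recon`, `kl`.
#' @export
cvae_loss <- function(model, x, condition = NULL, seed = NULL,
                      kl_weight = NULL) {
  if (is.character(x)) {
    x <- encode_smiles(canonicalize(x), model$vocab, model$config$max_len)
  }
  if (is.null(condition)) {
    condition <- condition_from_smiles(x$smiles, model$stats)
  }
  klw <- kl_weight %||% model$config$kl_weight
  post <- encode_posterior(model, x, condition)
  z <- reparameterize(post, seed = seed)
  dists <- decode_step_distributions(model, z, condition)
  recon <- reconstruction_loss(dists, x, model$config$mask_after_end)
  kl <- kl_term(post)
  total <- recon + klw * kl
  if (!all(is.finite(c(total, recon, kl)))) {
    stop("non-finite loss: recon = ", recon, ", kl = ", kl)
  }
  list(total = total, recon = recon, kl = kl)
}
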