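# Backpropagation-through-time for the CVAE and the Adam optimizer.
#
# Gradients are derived by hand for the stacked-LSTM encoder, the Gaussian
# posterior head, the reparameterization z = mu + sigma * eps, the
# constant-input decoder and the softmax/cross-entropy output layer, and are
# verified against central finite differences in the test suite.

# backward through one cached LSTM step; returns dzin and dc_prev, and
# accumulates dW/db into the supplied accumulators by reference semantics
# (returns them since R copies).
.lstm_step_backward <- function(dh, dc_in, cache, W) {
  do <- dh * cache$tc
  dc <- dc_in + dh * cache$o * (1 - cache$tc^2)
  di <- dc * cache$g
  df <- dc * cache$c_prev
  dg <- dc * cache$i
  dc_prev <- dc * cache$f
  da <- cbind(di * cache$i * (1 - cache$i),
              df * cache$f * (1 - cache$f),
              dg * (1 - cache$g^2),
              do * cache$o * (1 - cache$o))
  list(da = da, dzin = da %*% t(W), dc_prev = dc_prev)
}

.zeros_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

.grad_skeleton <- function(params) {
  g <- list(
    Emb = .zeros_like(params$Emb),
    enc = lapply(params$enc, function(l) list(W = .zeros_like(l$W),
                                              b = .zeros_like(l$b))),
    Wmu = .zeros_like(params$Wmu), bmu = .zeros_like(params$bmu),
    Wlv = .zeros_like(params$Wlv), blv = .zeros_like(params$blv),
    dec = lapply(params$dec, function(l) list(W = .zeros_like(l$W),
                                              b = .zeros_like(l$b))),
    Wy = .zeros_like(params$Wy), by = .zeros_like(params$by)
  )
  g
}

# Full forward + backward over a minibatch.
# idx: N x T token index matrix; cond: N x condition_dim; eps: N x D noise.
# Returns per-molecule mean losses and the gradient tree.
.cvae_grad <- function(idx, cond, params, config, eps,
                       kl_weight = config$kl_weight) {
  N <- nrow(idx); T <- config$max_len; H <- config$hidden_units
  L <- config$rnn_layers; V <- config$vocab_size
  D <- config$latent_dim; E <- config$embedding_dim

  ## ---- forward ----
  enc <- .encoder_forward(idx, cond, params, config, keep = TRUE)
  sigma <- exp(0.5 * enc$logvar)
  z <- enc$mu + sigma * eps
  kl_each <- 0.5 * rowSums(enc$mu^2 + exp(enc$logvar) - enc$logvar - 1)
  dec <- .decoder_forward(z, cond, params, config, keep = TRUE)

  mask <- if (config$mask_after_end) {
    e_tok <- V  # 'E' is always the last token by construction
    m <- matrix(0, N, T)
    for (n in seq_len(N)) {
      first_e <- match(e_tok, idx[n, ])
      m[n, seq_len(first_e)] <- 1
    }
    m
  } else {
    matrix(1, N, T)
  }

  recon_each <- numeric(N)
  for (t in seq_len(T)) {
    p <- dec$probs[[t]][cbind(seq_len(N), idx[, t])]
    recon_each <- recon_each - mask[, t] * log(pmax(p, 1e-12))
  }
  recon <- mean(recon_each)
  kl <- mean(kl_each)
  total <- recon + kl_weight * kl
  if (!is.finite(total)) {
    stop("non-finite loss in minibatch (recon = ", recon, ", kl = ", kl, ")")
  }

  ## ---- backward ----
  g <- .grad_skeleton(params)

  # decoder: output layer and BPTT (t = T .. 1)
  dh_next <- lapply(seq_len(L), function(l) matrix(0, N, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, N, H))
  du <- matrix(0, N, D + config$condition_dim)
  dWu <- .zeros_like(dec$Wu); dWh <- .zeros_like(dec$Wh)
  db1 <- numeric(4L * H)
  for (t in rev(seq_len(T))) {
    onehot_idx <- cbind(seq_len(N), idx[, t])
    dlogits <- dec$probs[[t]]
    dlogits[onehot_idx] <- dlogits[onehot_idx] - 1
    dlogits <- dlogits * (mask[, t] / N)
    top_h <- dec$top_h[[t]]
    g$Wy <- g$Wy + crossprod(top_h, dlogits)
    g$by <- g$by + colSums(dlogits)
    # gradient flowing into each layer's output h at this step from above
    d_input_above <- dlogits %*% t(params$Wy)
    if (L > 1L) {
      for (l in L:2) {
        dh <- d_input_above + dh_next[[l]]
        cc <- dec$cache[[l]][[t]]
        bk <- .lstm_step_backward(dh, dc_next[[l]], cc, params$dec[[l]]$W)
        g$dec[[l]]$W <- g$dec[[l]]$W + crossprod(cc$zin, bk$da)
        g$dec[[l]]$b <- g$dec[[l]]$b + colSums(bk$da)
        dc_next[[l]] <- bk$dc_prev
        nin <- ncol(cc$zin) - H
        dh_next[[l]] <- bk$dzin[, nin + seq_len(H), drop = FALSE]
        d_input_above <- bk$dzin[, seq_len(nin), drop = FALSE]
      }
    }
    # layer 1 (constant input u, split weights)
    dh <- d_input_above + dh_next[[1L]]
    cc <- dec$cache[[1L]][[t]]
    do <- dh * cc$tc
    dc <- dc_next[[1L]] + dh * cc$o * (1 - cc$tc^2)
    da <- cbind((dc * cc$g) * cc$i * (1 - cc$i),
                (dc * cc$c_prev) * cc$f * (1 - cc$f),
                (dc * cc$i) * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dc_next[[1L]] <- dc * cc$f
    dWu <- dWu + crossprod(dec$u, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db1 <- db1 + colSums(da)
    du <- du + da %*% t(dec$Wu)
    dh_next[[1L]] <- da %*% t(dec$Wh)
  }
  g$dec[[1L]]$W <- rbind(dWu, dWh)
  g$dec[[1L]]$b <- db1

  # reparameterization + KL
  dz <- du[, seq_len(D), drop = FALSE]
  dmu <- dz + kl_weight * enc$mu / N
  dlogvar <- dz * eps * 0.5 * sigma +
    kl_weight * 0.5 * (exp(enc$logvar) - 1) / N

  # posterior head
  g$Wmu <- crossprod(enc$hT, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(enc$hT, dlogvar); g$blv <- colSums(dlogvar)
  dhT <- dmu %*% t(params$Wmu) + dlogvar %*% t(params$Wlv)

  # encoder BPTT
  dh_next <- lapply(seq_len(L), function(l) matrix(0, N, H))
  dc_next <- lapply(seq_len(L), function(l) matrix(0, N, H))
  dh_next[[L]] <- dhT
  for (t in rev(seq_len(T))) {
    d_input_above <- NULL  # gradient flowing into layer l's output from l+1
    for (l in L:1) {
      dh <- dh_next[[l]]
      if (!is.null(d_input_above)) dh <- dh + d_input_above
      cc <- enc$cache[[l]][[t]]
      bk <- .lstm_step_backward(dh, dc_next[[l]], cc, params$enc[[l]]$W)
      g$enc[[l]]$W <- g$enc[[l]]$W + crossprod(cc$zin, bk$da)
      g$enc[[l]]$b <- g$enc[[l]]$b + colSums(bk$da)
      dc_next[[l]] <- bk$dc_prev
      nin <- ncol(cc$zin) - H
      dh_next[[l]] <- bk$dzin[, nin + seq_len(H), drop = FALSE]
      d_input_above <- bk$dzin[, seq_len(nin), drop = FALSE]
    }
    # d_input_above is now the gradient w.r.t. [embedding || condition] at t
    demb <- d_input_above[, seq_len(E), drop = FALSE]
    agg <- rowsum(demb, group = idx[, t])
    rows <- as.integer(rownames(agg))
    g$Emb[rows, ] <- g$Emb[rows, , drop = FALSE] + agg
  }

  list(total = total, recon = recon, kl = kl, grads = g)
}

## ---- parameter-tree utilities ----

.tree_leaves <- function(x, path = character()) {
  if (is.numeric(x)) return(list(path))
  out <- list()
  for (nm in names(x)) {
    if (nm == "") next
    out <- c(out, .tree_leaves(x[[nm]], c(path, nm)))
  }
  if (is.null(names(x)) && is.list(x)) {
    for (i in seq_along(x)) {
      out <- c(out, .tree_leaves(x[[i]], c(path, as.character(i))))
    }
  }
  out
}

.tree_get <- function(x, path) {
  for (p in path) {
    x <- if (grepl("^[0-9]+$", p)) x[[as.integer(p)]] else x[[p]]
  }
  x
}

.tree_set <- function(x, path, value) {
  if (length(path) == 1L) {
    p <- path[[1L]]
    if (grepl("^[0-9]+$", p)) x[[as.integer(p)]] <- value else x[[p]] <- value
    return(x)
  }
  p <- path[[1L]]
  key <- if (grepl("^[0-9]+$", p)) as.integer(p) else p
  x[[key]] <- .tree_set(x[[key]], path[-1L], value)
  x
}

.grad_global_norm <- function(grads, leaves) {
  sqrt(sum(vapply(leaves, function(p) sum(.tree_get(grads, p)^2), numeric(1))))
}

.clip_grads <- function(grads, leaves, max_norm) {
  nrm <- .grad_global_norm(grads, leaves)
  if (is.finite(max_norm) && nrm > max_norm) {
    scale <- max_norm / nrm
    for (p in leaves) {
      grads <- .tree_set(grads, p, .tree_get(grads, p) * scale)
    }
  }
  grads
}

## ---- Adam ----

.adam_init <- function(params) {
  leaves <- .tree_leaves(unclass(params))
  state <- list(t = 0L, leaves = leaves, m = list(), v = list())
  for (i in seq_along(leaves)) {
    zero <- .zeros_like(.tree_get(params, leaves[[i]]))
    state$m[[i]] <- zero
    state$v[[i]] <- zero
  }
  state
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$leaves)) {
    path <- state$leaves[[i]]
    gleaf <- .tree_get(grads, path)
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * gleaf
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * gleaf^2
    step <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    params <- .tree_set(params, path, .tree_get(params, path) - step)
  }
  list(params = params, state = state)
}

.sgd_step <- function(params, grads, state, lr) {
  for (path in state$leaves) {
    params <- .tree_set(params, path,
                        .tree_get(params, path) - lr * .tree_get(grads, path))
  }
  list(params = params, state = state)
}
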