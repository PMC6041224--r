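#' Latent sampler specification
#'
#' The three latent-sampling strategies used for generation:
#' `"random"` draws \eqn{z \sim N(0, I)}; `"around_known"` perturbs the
#' posterior mean of a molecule drawn at random from the training set with
#' isotropic Gaussian noise; `"around_target"` perturbs the posterior mean of
#' a fixed anchor molecule.
#'
#' @param strategy one of `"around_target"`, `"around_known"`, `"random"`.
#' @param anchor_smiles anchor molecule (required for `"around_target"`;
#'   optional for `"around_known"`, which otherwise draws a fresh training
#'   molecule per latent).
#' @param noise_scale standard deviation of the Gaussian perturbation, in
#'   latent units (ignored for `"random"`).
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(strategy = c("around_target", "around_known", "random"),
                         anchor_smiles = NULL, noise_scale = 0.1) {
  strategy <- match.arg(strategy)
  if (strategy == "around_target" && is.null(anchor_smiles)) {
    stop("strategy 'around_target' requires an anchor molecule")
  }
  if (strategy != "random" && noise_scale < 0) {
    stop("noise_scale must be non-negative")
  }
  structure(list(strategy = strategy, anchor_smiles = anchor_smiles,
                 noise_scale = noise_scale),
            class = "sampler_spec")
}

# posterior mean of a molecule under its own condition (memoized per model
# would be overkill; the bridge cache already absorbs the descriptor calls)
.anchor_mean <- function(model, smiles) {
  encode_posterior(model, smiles)$mu
}

#' Draw latent vectors under a sampling strategy
#'
#' @param spec a [sampler_spec()].
#' @param model a trained `cvae_model`.
#' @param n number of latent vectors to draw.
#' @param seed optional integer seed (`NULL` continues the current RNG
#'   stream).
#' @return list with `z` (`n` x `latent_dim` matrix) and `anchors`
#'   (character vector of anchor SMILES, `NA` for the random strategy).
#' @export
sample_latent <- function(spec, model, n = 1L, seed = NULL) {
  stopifnot(inherits(spec, "sampler_spec"))
  if (!is.null(seed)) set.seed(seed)
  D <- model$config$latent_dim
  if (spec$strategy == "random") {
    return(list(z = matrix(stats::rnorm(n * D), n), anchors = rep(NA_character_, n)))
  }
  anchors <- if (spec$strategy == "around_target" || !is.null(spec$anchor_smiles)) {
    rep(spec$anchor_smiles, n)
  } else {
    sample(model$corpus$train, n, replace = TRUE)
  }
  z <- matrix(0, n, D)
  mu_cache <- list()
  for (i in seq_len(n)) {
    a <- anchors[i]
    if (is.null(mu_cache[[a]])) mu_cache[[a]] <- .anchor_mean(model, a)
    z[i, ] <- mu_cache[[a]] + spec$noise_scale * stats::rnorm(D)
  }
  list(z = z, anchors = anchors)
}

# Sample n_writeouts strings from one latent's step distributions.
# probs: list over t of N x V rows (a batch); returns character matrix
# N x n_writeouts of raw write-outs (NA = no 'E' emitted).
.writeout_batch <- function(probs, vocab, n_writeouts) {
  N <- nrow(probs[[1L]])
  T <- length(probs)
  v <- length(vocab$tokens)
  out <- matrix(NA_character_, N, n_writeouts)
  for (nrow_i in seq_len(N)) {
    picks <- matrix(0L, T, n_writeouts)
    for (t in seq_len(T)) {
      picks[t, ] <- sample.int(v, n_writeouts, replace = TRUE,
                               prob = probs[[t]][nrow_i, ])
    }
    for (w in seq_len(n_writeouts)) {
      out[nrow_i, w] <- .indices_to_smiles(picks[, w], vocab)
    }
  }
  out
}

#' Stochastic write-out generation for one latent vector
#'
#' Decodes the step distributions for `(z, condition)` once and performs
#' `n_writeouts` independent stochastic write-outs. Each write-out is checked
#' for validity with the cheminformatics toolkit; valid molecules are
#' canonicalized, deduplicated (within the batch and against `seen`) and
#' their five descriptors computed.
#'
#' @param model a trained `cvae_model`.
#' @param z numeric latent vector.
#' @param condition numeric condition vector.
#' @param n_writeouts number of stochastic write-outs (default 100).
#' @param seed optional integer seed.
#' @param seen optional character vector of canonical SMILES already
#'   generated elsewhere; molecules in it are flagged as duplicates.
#' @return data.frame of generation records with columns `raw_output`,
#'   `valid`, `canonical_smiles`, `duplicate`, `mw`, `logp`, `hbd`, `hba`,
#'   `tpsa` (`NA` where not applicable), one row per write-out.
#' @export
generate_batch <- function(model, z, condition, n_writeouts = 100L,
                           seed = NULL, seen = character()) {
  if (!is.null(seed)) set.seed(seed)
  probs <- .decoder_forward(matrix(z, nrow = 1L),
                            matrix(condition, nrow = 1L),
                            model$params, model$config)$probs
  raw <- .writeout_batch(probs, model$vocab, n_writeouts)[1L, ]
  .records_from_raw(raw, seen)
}

# raw write-outs (character, NA = no 'E') -> record data.frame
.records_from_raw <- function(raw, seen = character()) {
  rec <- data.frame(raw_output = raw, valid = FALSE,
                    canonical_smiles = NA_character_, duplicate = FALSE,
                    mw = NA_real_, logp = NA_real_, hbd = NA_integer_,
                    hba = NA_integer_, tpsa = NA_real_,
                    stringsAsFactors = FALSE)
  have <- !is.na(raw) & nzchar(raw)
  if (any(have)) {
    ana <- smiles_analyze(raw[have])
    rec$valid[have] <- ana$valid
    rec$canonical_smiles[have] <- ifelse(ana$valid, ana$canonical, NA)
    rec$mw[have] <- ana$mw
    rec$logp[have] <- ana$logp
    rec$hbd[have] <- ana$hbd
    rec$hba[have] <- ana$hba
    rec$tpsa[have] <- ana$tpsa
  }
  isv <- which(rec$valid)
  if (length(isv) > 0L) {
    canon <- rec$canonical_smiles[isv]
    dup <- duplicated(canon) | canon %in% seen
    rec$duplicate[isv] <- dup
  }
  rec
}

#' Generate until enough successful molecules are found
#'
#' Repeats latent draws (each followed by `n_writeouts` stochastic
#' write-outs) until `n_required` distinct molecules satisfying the success
#' rule have been produced, or `max_attempts` latent draws are exhausted.
#' One *attempt* is one latent draw together with its write-outs; the
#' reported success rate is `100 * n_success / attempts` in percent.
#'
#' @param model a trained `cvae_model`.
#' @param condition target condition vector (see [build_condition()] /
#'   [condition_from_smiles()] / [random_condition()]).
#' @param sampler a [sampler_spec()].
#' @param rule a [success_rule()], or `NULL` to count every valid
#'   non-duplicate molecule as a success.
#' @param n_required number of successful molecules to reach (default 100).
#' @param max_attempts hard cap on latent draws; if reached first the result
#'   is flagged incomplete (not an error).
#' @param n_writeouts write-outs per latent draw (default 100).
#' @param chunk latent draws processed per toolkit round-trip (efficiency
#'   only; does not affect results beyond RNG consumption order).
#' @param seed integer seed making the whole run reproducible.
#' @return list with `records` (all write-out records, in attempt order,
#'   with an `attempt` column), `attempts`, `n_valid` (valid write-outs,
#'   duplicates included), `n_unique` (distinct valid molecules),
#'   `n_success`, `success_rate` (percent), and `complete`.
#' @export
generate_until <- function(model, condition, sampler, rule = NULL,
                           n_required = 100L, max_attempts = 1000L,
                           n_writeouts = 100L, chunk = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(sampler, "sampler_spec"))
  records <- list()
  seen <- character()
  attempts <- 0L; n_success <- 0L
  done <- FALSE
  while (!done && attempts < max_attempts) {
    k <- min(chunk, max_attempts - attempts)
    lat <- sample_latent(sampler, model, n = k)
    dec <- .decoder_forward(lat$z, matrix(condition, nrow = k, ncol = length(condition), byrow = TRUE),
                            model$params, model$config)
    raw <- .writeout_batch(dec$probs, model$vocab, n_writeouts)
    # warm the toolkit cache with the whole chunk in one round-trip
    flat <- as.vector(raw)
    flat <- flat[!is.na(flat) & nzchar(flat)]
    if (length(flat) > 0L) invisible(smiles_analyze(unique(flat)))
    for (a in seq_len(k)) {
      attempts <- attempts + 1L
      rec <- .records_from_raw(raw[a, ], seen)
      rec$attempt <- attempts
      new_unique <- which(rec$valid & !rec$duplicate)
      seen <- c(seen, rec$canonical_smiles[new_unique])
      success <- logical(nrow(rec))
      if (length(new_unique) > 0L) {
        cand <- rec[new_unique, , drop = FALSE]
        ok <- if (is.null(rule)) rep(TRUE, nrow(cand)) else is_success(cand, rule)
        success[new_unique] <- ok
      }
      rec$success <- success
      n_success <- n_success + sum(success)
      records[[length(records) + 1L]] <- rec
      if (n_success >= n_required) { done <- TRUE; break }
    }
  }
  records <- do.call(rbind, records)
  list(records = records,
       attempts = attempts,
       n_valid = if (is.null(records)) 0L else sum(records$valid),
       n_unique = length(seen),
       n_success = n_success,
       success_rate = if (attempts > 0L) success_rate_percent(n_success, attempts) else NA_real_,
       complete = n_success >= n_required)
}
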