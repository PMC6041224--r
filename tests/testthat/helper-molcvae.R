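# Shared fixtures, memoized so the expensive pieces (bridge round-trips,
# training) run once per test session.

.memo <- new.env(parent = emptyenv())

memoize <- function(key, fn) {
  if (is.null(.memo[[key]])) .memo[[key]] <- fn()
  .memo[[key]]
}

# small corpus for unit tests (bridge-backed, a few seconds once)
small_corpus <- function() {
  memoize("small_corpus", function() generate_corpus(120, seed = 7))
}

# full desk-scale corpus: the study conditions of the end-to-end checks
desk_corpus <- function() {
  memoize("desk_corpus", function() generate_corpus(2000, seed = 1))
}

# untrained tiny model carrying real vocabulary/statistics from the small
# corpus; adequate wherever only shapes and mechanics matter
tiny_model <- function(seed = 5) {
  memoize(paste0("tiny_model_", seed), function() {
    corp <- small_corpus()
    vocab <- build_vocabulary(corp$smiles)
    stats <- fit_normalization(corp$properties)
    cfg <- cvae_config(vocab_size = length(vocab$tokens),
                       condition_dim = condition_dim(stats),
                       embedding_dim = 8, rnn_layers = 1, hidden_units = 16,
                       latent_dim = 4, max_len = 48)
    model <- list(params = cvae_init(cfg, seed = seed), config = cfg,
                  vocab = vocab, stats = stats,
                  corpus = list(train = corp$smiles[1:100],
                                test = corp$smiles[101:120]),
                  properties = corp$properties,
                  history = data.frame())
    class(model) <- "cvae_model"
    model
  })
}

# the desk-scale trained model: 2000-molecule fixture corpus, <= 30 epochs
# (the vignette documents these conditions); trained once per session
desk_model <- function() {
  memoize("desk_model", function() {
    suppressWarnings(cvae_train(
      desk_corpus()$smiles,
      config = train_config(learning_rate = 1e-2, decay_rate = 0.97,
                            batch_size = 20, max_epochs = 30, patience = 30,
                            seed = 1, kl_warmup_epochs = 18,
                            kl_anneal_epochs = 12),
      model_args = list(embedding_dim = 64, rnn_layers = 1,
                        hidden_units = 160, latent_dim = 32, max_len = 60),
      verbose = FALSE))
  })
}

# hand-built statistics with round numbers, for tolerance arithmetic tests
stats_with_means <- function(mw_mean = 300, logp_mean = 2, hbd_mean = 1,
                             hba_mean = 3, tpsa_mean = 80) {
  props <- data.frame(
    mw = c(2 * mw_mean - 100, 100),
    logp = c(2 * logp_mean - 1, 1),
    hbd = c(2 * hbd_mean, 0),
    hba = c(2 * hba_mean, 0),
    tpsa = c(2 * tpsa_mean - 10, 10)
  )
  fit_normalization(props)
}

# degenerate step-distribution matrix spelling out a fixed token sequence
one_hot_probs <- function(tokens, vocab, max_len) {
  idx <- vocab$index[c(tokens, rep("E", max_len - length(tokens)))]
  m <- matrix(0, max_len, length(vocab$tokens))
  m[cbind(seq_len(max_len), idx)] <- 1
  m
}
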