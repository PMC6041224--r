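#' Read a SMILES file
#'
#' Plain-text SMILES input: one molecule per line, UTF-8, lines starting with
#' `#` and blank lines ignored.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Build a character vocabulary from a SMILES corpus
#'
#' Tokenization is strictly character-level: two-letter element symbols such
#' as `Cl` contribute the characters `C` and `l` as separate tokens, and the
#' downstream validity check catches chemically meaningless assemblies. The
#' reserved end-of-sequence token `E` is appended last; all other tokens are
#' sorted lexicographically so the same corpus always yields the same
#' vocabulary.
#'
#' @param corpus character vector of (canonical) SMILES strings.
#' @return An object of class `cvae_vocabulary`: a list with `tokens`
#'   (ordered character vector, `E` last) and `index` (named integer lookup).
#' @export
build_vocabulary <- function(corpus) {
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  chars <- unique(unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE))
  if ("E" %in% chars) {
    stop("corpus contains the reserved end token character 'E'")
  }
  tokens <- c(sort(chars, method = "radix"), "E")
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens))
  class(vocab) <- "cvae_vocabulary"
  vocab
}

#' @export
print.cvae_vocabulary <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens (incl. end token 'E')\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore a vocabulary
#'
#' The vocabulary is stored as a JSON array of tokens; reloading reproduces
#' the object exactly (ordering is part of the contract, since token indices
#' define the one-hot layout).
#'
#' @param vocab a `cvae_vocabulary`.
#' @param path file path for the JSON token list.
#' @return `save_vocabulary` returns `path` invisibly; `load_vocabulary`
#'   returns the restored `cvae_vocabulary`.
#' @export
save_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "cvae_vocabulary"))
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  tokens <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (anyDuplicated(tokens) || tokens[length(tokens)] != "E") {
    stop("corrupt vocabulary file: ", path)
  }
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens))
  class(vocab) <- "cvae_vocabulary"
  vocab
}

# token index sequence of length max_len: the SMILES characters, one 'E',
# then 'E' repeated as padding (the decoder is trained to keep emitting 'E').
.token_indices <- function(smiles, vocab, max_len) {
  if (!nzchar(smiles)) stop("empty SMILES is not a molecule")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, vocab$tokens)
  if (length(unknown) > 0L) {
    stop("character(s) not in vocabulary: ",
         paste(sQuote(unknown), collapse = ", "), " in ", sQuote(smiles))
  }
  if (length(chars) + 1L > max_len) {
    stop("SMILES longer than max_len - 1 (", max_len - 1L, "): ", sQuote(smiles))
  }
  e <- vocab$index[["E"]]
  idx <- rep.int(e, max_len)
  idx[seq_along(chars)] <- vocab$index[chars]
  idx
}

#' One-hot encode a SMILES string
#'
#' Encodes a SMILES as a `max_len` x `|vocabulary|` one-hot matrix: row `t` is
#' the one-hot of character `t`, the row after the last character is the end
#' token `E`, and all remaining rows repeat `E` (padding convention).
#'
#' @param smiles a single SMILES string whose characters are all in `vocab`.
#' @param vocab a `cvae_vocabulary`.
#' @param max_len maximum unrolled sequence length (default 120); the SMILES
#'   must have at most `max_len - 1` characters to leave room for `E`.
#' @return An object of class `tokenized_smiles`: list with `smiles`,
#'   `tokens` (characters plus the single terminal `E`, padding excluded),
#'   `idx` (integer vector of length `max_len`) and `onehot`
#'   (`max_len` x vocabulary-size matrix).
#' @export
encode_smiles <- function(smiles, vocab, max_len = 120L) {
  stopifnot(inherits(vocab, "cvae_vocabulary"), length(smiles) == 1L)
  idx <- .token_indices(smiles, vocab, max_len)
  v <- length(vocab$tokens)
  onehot <- matrix(0, nrow = max_len, ncol = v,
                   dimnames = list(NULL, vocab$tokens))
  onehot[cbind(seq_len(max_len), idx)] <- 1
  out <- list(smiles = smiles,
              tokens = c(strsplit(smiles, "", fixed = TRUE)[[1]], "E"),
              idx = idx,
              onehot = onehot)
  class(out) <- "tokenized_smiles"
  out
}

# batch variant used by training/generation: n x max_len integer matrix
.encode_batch <- function(smiles, vocab, max_len) {
  t(vapply(smiles, .token_indices, integer(max_len),
           vocab = vocab, max_len = max_len))
}

#' Decode a sequence of token distributions to a SMILES string
#'
#' Implements the write-out step: each row of `probs` is a probability
#' distribution over the vocabulary for one unroll position. In `"argmax"`
#' mode the most probable token is taken at every position; in `"stochastic"`
#' mode each position is sampled independently from its distribution
#' (stochastic write-out). The returned string is everything strictly before
#' the first `E`; if no `E` occurs within the unroll window the write-out is
#' invalid and `NA` is returned.
#'
#' @param probs numeric matrix (positions x vocabulary size); rows must be
#'   non-negative and sum to 1 within `1e-6`.
#' @param vocab a `cvae_vocabulary` whose size matches `ncol(probs)`.
#' @param mode `"argmax"` or `"stochastic"`.
#' @param seed optional integer seed for stochastic mode; with a fixed seed
#'   the sampled string is reproducible. `NULL` uses the current RNG stream.
#' @return A single string, or `NA_character_` for an invalid write-out
#'   (no `E` emitted).
#' @export
decode_tokens <- function(probs, vocab, mode = c("argmax", "stochastic"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(probs), inherits(vocab, "cvae_vocabulary"))
  v <- length(vocab$tokens)
  if (ncol(probs) != v) stop("probability rows have wrong width for this vocabulary")
  if (any(probs < -1e-12)) stop("malformed probability vector: negative entry")
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) stop("malformed probability vector: rows must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  picks <- if (mode == "argmax") {
    max.col(probs, ties.method = "first")
  } else {
    apply(probs, 1L, function(p) sample.int(v, 1L, prob = p))
  }
  .indices_to_smiles(picks, vocab)
}

# turn a vector of token indices into the string before the first 'E'
.indices_to_smiles <- function(picks, vocab) {
  e <- vocab$index[["E"]]
  first_e <- match(e, picks)
  if (is.na(first_e)) return(NA_character_)
  if (first_e == 1L) return("")
  paste(vocab$tokens[picks[seq_len(first_e - 1L)]], collapse = "")
}
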