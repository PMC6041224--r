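.CONTINUOUS <- c("mw", "logp", "tpsa")
.INTEGER <- c("hbd", "hba")
.PROPERTIES <- c("mw", "logp", "hbd", "hba", "tpsa")

#' Fit corpus normalization statistics
#'
#' Computes, per continuous property (MW, LogP, TPSA), the corpus minimum,
#' maximum and mean, and per integer property (HBD, HBA) the maximum count
#' and mean. The min/max define the affine map onto \eqn{[-1, 1]} used in the
#' condition vector; the means feed the 10%-of-mean success tolerances; the
#' integer maxima fix the one-hot block sizes.
#'
#' @param props data.frame with columns `mw`, `logp`, `hbd`, `hba`, `tpsa`
#'   (as returned by [compute_properties()]).
#' @return An object of class `cvae_stats`.
#' @export
fit_normalization <- function(props) {
  if (!is.data.frame(props) || nrow(props) == 0L) {
    stop("cannot fit normalization statistics on an empty corpus")
  }
  missing <- setdiff(.PROPERTIES, names(props))
  if (length(missing) > 0L) {
    stop("missing property column(s): ", paste(missing, collapse = ", "))
  }
  stats <- list()
  for (p in .CONTINUOUS) {
    v <- props[[p]]
    if (min(v) == max(v)) {
      stop("degenerate scaling: property ", sQuote(p),
           " is constant over the corpus (min == max)")
    }
    stats[[p]] <- list(min = min(v), max = max(v), mean = mean(v))
  }
  for (p in .INTEGER) {
    v <- props[[p]]
    if (any(v < 0) || any(v != round(v))) {
      stop("property ", sQuote(p), " must contain non-negative integers")
    }
    stats[[p]] <- list(max = as.integer(max(v)), mean = mean(v))
  }
  structure(stats, class = "cvae_stats")
}

#' @export
print.cvae_stats <- function(x, ...) {
  cat("Corpus property statistics:\n")
  for (p in .CONTINUOUS) {
    cat(sprintf("  %-5s min %.3f  max %.3f  mean %.3f\n",
                p, x[[p]]$min, x[[p]]$max, x[[p]]$mean))
  }
  for (p in .INTEGER) {
    cat(sprintf("  %-5s max %d  mean %.3f\n", p, x[[p]]$max, x[[p]]$mean))
  }
  invisible(x)
}

#' Serialize / restore normalization statistics
#'
#' @param stats a `cvae_stats` object.
#' @param path JSON file path.
#' @return `save_stats` returns `path` invisibly; `load_stats` the restored
#'   object.
#' @export
save_stats <- function(stats, path) {
  stopifnot(inherits(stats, "cvae_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_stats
#' @export
load_stats <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$hbd$max <- as.integer(raw$hbd$max)
  raw$hba$max <- as.integer(raw$hba$max)
  structure(raw, class = "cvae_stats")
}

#' Normalize a property value onto \eqn{[-1, 1]}
#'
#' Affine map with `normalize_property(min) == -1` and
#' `normalize_property(max) == +1`. Values outside the corpus range map
#' linearly beyond \eqn{[-1, 1]}; this deliberate extrapolation is what the
#' out-of-range generation protocol relies on (e.g. a target set 10% above
#' the corpus maximum maps to 1.2).
#'
#' @param value numeric vector of raw property values.
#' @param min,max corpus minimum and maximum for the property (`max > min`).
#' @return numeric vector of normalized values.
#' @export
normalize_property <- function(value, min, max) {
  if (max <= min) stop("normalization requires max > min")
  2 * (value - min) / (max - min) - 1
}

#' @rdname normalize_property
#' @param normalized numeric vector of normalized values to map back.
#' @export
denormalize_property <- function(normalized, min, max) {
  if (max <= min) stop("normalization requires max > min")
  (normalized + 1) / 2 * (max - min) + min
}

#' Length of the condition vector implied by fitted statistics
#'
#' @param stats a `cvae_stats` object.
#' @return integer: `3 + (hbd_max + 1) + (hba_max + 1)`.
#' @export
condition_dim <- function(stats) {
  stopifnot(inherits(stats, "cvae_stats"))
  3L + (stats$hbd$max + 1L) + (stats$hba$max + 1L)
}

.one_hot <- function(value, max) {
  v <- numeric(max + 1L)
  v[value + 1L] <- 1
  v
}

#' Assemble a condition vector
#'
#' Lays out the conditioning encoding fed to both encoder and decoder:
#' normalized MW first, normalized LogP second, then the HBD one-hot block,
#' the HBA one-hot block, and normalized TPSA last. Integer counts above the
#' corpus maximum clamp (with a warning) to the top bin.
#'
#' @param props named list or one-row data.frame with entries `mw`, `logp`,
#'   `hbd`, `hba`, `tpsa` (raw, unnormalized values).
#' @param stats a `cvae_stats` object.
#' @return named numeric vector of length [condition_dim()].
#' @export
build_condition <- function(props, stats) {
  stopifnot(inherits(stats, "cvae_stats"))
  props <- as.list(props)
  for (p in .INTEGER) {
    val <- props[[p]]
    if (val < 0 || val != round(val)) stop(sQuote(p), " must be a non-negative integer")
    if (val > stats[[p]]$max) {
      warning(sQuote(p), " = ", val, " exceeds the corpus maximum ",
              stats[[p]]$max, "; clamping to the top one-hot bin")
      props[[p]] <- stats[[p]]$max
    }
  }
  entries <- c(
    mw = normalize_property(props$mw, stats$mw$min, stats$mw$max),
    logp = normalize_property(props$logp, stats$logp$min, stats$logp$max),
    stats::setNames(.one_hot(props$hbd, stats$hbd$max),
                    paste0("hbd", 0:stats$hbd$max)),
    stats::setNames(.one_hot(props$hba, stats$hba$max),
                    paste0("hba", 0:stats$hba$max)),
    tpsa = normalize_property(props$tpsa, stats$tpsa$min, stats$tpsa$max)
  )
  entries
}

#' Read back the continuous entries of a condition vector
#'
#' Inverts the affine normalization of the MW, LogP and TPSA entries (the
#' one-hot blocks are read off as the arg-max bin).
#'
#' @param condition numeric vector produced by [build_condition()].
#' @param stats the `cvae_stats` used to build it.
#' @return named list with `mw`, `logp`, `hbd`, `hba`, `tpsa`.
#' @export
invert_condition <- function(condition, stats) {
  stopifnot(inherits(stats, "cvae_stats"))
  nb_d <- stats$hbd$max + 1L
  nb_a <- stats$hba$max + 1L
  if (length(condition) != 3L + nb_d + nb_a) {
    stop("condition vector has the wrong length for these statistics")
  }
  hbd_block <- condition[2L + seq_len(nb_d)]
  hba_block <- condition[2L + nb_d + seq_len(nb_a)]
  list(
    mw = denormalize_property(condition[[1L]], stats$mw$min, stats$mw$max),
    logp = denormalize_property(condition[[2L]], stats$logp$min, stats$logp$max),
    hbd = as.integer(which.max(hbd_block)) - 1L,
    hba = as.integer(which.max(hba_block)) - 1L,
    tpsa = denormalize_property(condition[[length(condition)]],
                                stats$tpsa$min, stats$tpsa$max)
  )
}

#' Draw a random condition vector
#'
#' Emulates the "random condition" control: continuous entries uniform on
#' \eqn{[-1, 1]}, HBD/HBA bins uniform over the observed range.
#'
#' @param stats a `cvae_stats` object.
#' @return named numeric vector, same layout as [build_condition()].
#' @export
random_condition <- function(stats) {
  stopifnot(inherits(stats, "cvae_stats"))
  props <- list(
    mw = denormalize_property(stats::runif(1, -1, 1), stats$mw$min, stats$mw$max),
    logp = denormalize_property(stats::runif(1, -1, 1), stats$logp$min, stats$logp$max),
    hbd = sample.int(stats$hbd$max + 1L, 1L) - 1L,
    hba = sample.int(stats$hba$max + 1L, 1L) - 1L,
    tpsa = denormalize_property(stats::runif(1, -1, 1), stats$tpsa$min, stats$tpsa$max)
  )
  build_condition(props, stats)
}

#' Condition vector for a named molecule
#'
#' Convenience wrapper: computes the five descriptors of `smiles` and
#' assembles its condition vector under the fitted corpus statistics.
#'
#' @param smiles a single valid SMILES string.
#' @inheritParams build_condition
#' @return named numeric vector as in [build_condition()].
#' @export
condition_from_smiles <- function(smiles, stats) {
  props <- compute_properties(smiles)
  build_condition(props[1L, ], stats)
}
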