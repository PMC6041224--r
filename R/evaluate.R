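#' Success rule for generated molecules
#'
#' A generated molecule is successful when every active property lies within
#' its tolerance of the target value. Each tolerance is 10% of the corpus
#' mean of that property (in absolute value), so heavier corpora tolerate
#' larger absolute MW deviations, and integer properties with small means
#' effectively demand an exact count match (tolerance < 1).
#'
#' @param target named list / one-row data.frame with the target `mw`,
#'   `logp`, `hbd`, `hba`, `tpsa` values, or a SMILES string whose
#'   descriptors define the target.
#' @param stats a `cvae_stats` object (its property means set the
#'   tolerances).
#' @param active character vector of properties that must match (default all
#'   five; single-property sweeps relax the rest).
#' @param tolerance_fraction fraction of the corpus mean used as tolerance
#'   (default 0.1).
#' @return object of class `success_rule` with fields `target`,
#'   `tolerances`, `active`.
#' @export
success_rule <- function(target, stats, active = .PROPERTIES,
                         tolerance_fraction = 0.1) {
  stopifnot(inherits(stats, "cvae_stats"))
  active <- match.arg(active, .PROPERTIES, several.ok = TRUE)
  if (length(active) == 0L) stop("at least one property must be active")
  if (is.character(target)) {
    target <- as.list(compute_properties(target)[1L, .PROPERTIES])
  } else {
    target <- as.list(target)[.PROPERTIES]
  }
  tol <- vapply(.PROPERTIES, function(p) {
    tolerance_fraction * abs(stats[[p]]$mean)
  }, numeric(1))
  if (any(tol[active] <= 0)) {
    stop("zero tolerance for active property (corpus mean is 0): ",
         paste(active[tol[active] <= 0], collapse = ", "))
  }
  structure(list(target = target, tolerances = tol, active = active),
            class = "success_rule")
}

#' Success rate in percent
#'
#' The accounting used throughout the success tables:
#' `100 * n_success / attempts`, where one attempt is one latent draw with
#' its block of stochastic write-outs.
#'
#' @param n_success number of successful molecules.
#' @param attempts number of latent-draw attempts.
#' @return success rate in percent.
#' @export
success_rate_percent <- function(n_success, attempts) {
  if (any(attempts <= 0)) stop("attempts must be positive")
  100 * n_success / attempts
}

#' Test candidates against a success rule
#'
#' @param candidates data.frame with columns `mw`, `logp`, `hbd`, `hba`,
#'   `tpsa` (e.g. generation records or [compute_properties()] output).
#' @param rule a [success_rule()].
#' @return logical vector: does each candidate match every active property
#'   within tolerance?
#' @export
is_success <- function(candidates, rule) {
  stopifnot(inherits(rule, "success_rule"))
  ok <- rep(TRUE, nrow(candidates))
  for (p in rule$active) {
    ok <- ok & (abs(candidates[[p]] - rule$target[[p]]) <= rule$tolerances[[p]])
  }
  ok & !is.na(ok)
}

#' Matched condition-vs-random success table
#'
#' For each target molecule, runs the generation loop twice with identical
#' samplers and seeds: once with the condition vector set to the target's
#' five properties, and once with a randomly drawn condition vector. This is
#' the control experiment showing that successes come from the conditioning,
#' not from volume of random trials.
#'
#' @param model a trained `cvae_model`.
#' @param targets character vector of target SMILES.
#' @param sampler a [sampler_spec()]; for the `around_target` strategy the
#'   anchor is set to each target in turn.
#' @param n_required,max_attempts,n_writeouts,chunk passed to
#'   [generate_until()].
#' @param seed base seed; target `i` uses `seed + i` for both of its runs.
#' @return data.frame of class `success_table` with one row per (target,
#'   condition type): columns `label`, `condition`, `attempts`, `n_valid`,
#'   `n_success`, `success_rate`.
#' @export
condition_vs_random_table <- function(model, targets, sampler = sampler_spec("around_known"),
                                      n_required = 100L, max_attempts = 1000L,
                                      n_writeouts = 100L, chunk = 20L,
                                      seed = 1L) {
  rows <- list()
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    samp <- if (sampler$strategy == "around_target") {
      sampler_spec("around_target", anchor_smiles = tgt,
                   noise_scale = sampler$noise_scale)
    } else {
      sampler
    }
    rule <- success_rule(tgt, model$stats)
    cond_target <- condition_from_smiles(tgt, model$stats)
    set.seed(seed + i)
    cond_random <- random_condition(model$stats)
    for (kind in c("condition", "random")) {
      cond <- if (kind == "condition") cond_target else cond_random
      res <- generate_until(model, cond, samp, rule,
                            n_required = n_required,
                            max_attempts = max_attempts,
                            n_writeouts = n_writeouts, chunk = chunk,
                            seed = seed + i)
      rows[[length(rows) + 1L]] <- data.frame(
        label = tgt, condition = kind, attempts = res$attempts,
        n_valid = res$n_valid, n_success = res$n_success,
        success_rate = res$success_rate, complete = res$complete,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("success_table", class(out))
  out
}

#' Property distribution shift between generated and reference molecules
#'
#' Compares a property's distribution in a generated set against a reference
#' set on a shared histogram binning, and reports the fraction of generated
#' molecules whose value exceeds the reference maximum (the out-of-range
#' generation diagnostic).
#'
#' @param generated,reference numeric vectors of property values, or
#'   data.frames containing the property column.
#' @param property property name when data.frames are given.
#' @param bins number of shared histogram bins.
#' @return list with `mean_generated`, `mean_reference`, `mean_shift`,
#'   `breaks`, `counts_generated`, `counts_reference`,
#'   `fraction_beyond_max`.
#' @export
distribution_shift <- function(generated, reference, property = NULL,
                               bins = 30L) {
  if (is.data.frame(generated)) generated <- generated[[property]]
  if (is.data.frame(reference)) reference <- reference[[property]]
  generated <- generated[!is.na(generated)]
  reference <- reference[!is.na(reference)]
  if (length(generated) == 0L || length(reference) == 0L) {
    stop("distribution_shift needs non-empty generated and reference sets")
  }
  rng <- range(c(generated, reference))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  hg <- graphics::hist(generated, breaks = breaks, plot = FALSE)
  hr <- graphics::hist(reference, breaks = breaks, plot = FALSE)
  list(mean_generated = mean(generated),
       mean_reference = mean(reference),
       mean_shift = mean(generated) - mean(reference),
       breaks = breaks,
       counts_generated = hg$counts,
       counts_reference = hr$counts,
       fraction_beyond_max = mean(generated > max(reference)))
}

#' PCA of the latent space
#'
#' Encodes a set of molecules to their posterior means and extracts the two
#' leading principal axes, the standard diagnostic of how the latent space
#' organizes molecular structure once the condition vector has absorbed the
#' target properties.
#'
#' @param model a trained `cvae_model`.
#' @param smiles character vector of at least 3 molecules encodable under
#'   the model vocabulary.
#' @return list with `coordinates` (n x 2 matrix of scores),
#'   `explained_variance_ratio` (length 2; zero when the latents carry no
#'   variance), `latent` (the n x latent_dim posterior means) and `pca`
#'   (the full `prcomp` object, or `NULL` for zero-variance input).
#' @export
latent_pca <- function(model, smiles) {
  if (length(smiles) < 3L) stop("latent_pca needs at least 3 molecules")
  Z <- t(vapply(smiles, function(s) encode_posterior(model, s)$mu,
                numeric(model$config$latent_dim)))
  total_var <- sum(apply(Z, 2L, stats::var))
  if (total_var == 0) {
    return(list(coordinates = matrix(0, nrow(Z), 2L),
                explained_variance_ratio = c(0, 0),
                latent = Z, pca = NULL))
  }
  pr <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  k <- min(2L, ncol(pr$x))
  coords <- matrix(0, nrow(Z), 2L)
  coords[, seq_len(k)] <- pr$x[, seq_len(k)]
  list(coordinates = coords,
       explained_variance_ratio = c(evr, 0, 0)[1:2],
       latent = Z, pca = pr)
}

#' Single-property sweep conditions
#'
#' Builds a sequence of condition vectors holding four properties at the
#' anchor molecule's values while scanning one property over a grid — the
#' protocol for changing a single property (e.g. LogP from 0 to 3) without
#' touching the others.
#'
#' @param anchor_smiles molecule providing the four fixed properties.
#' @param property property to sweep.
#' @param values numeric grid of raw (unnormalized) values for the swept
#'   property; integer properties are rounded.
#' @param stats a `cvae_stats`.
#' @return list with `conditions` (one condition vector per grid value,
#'   as rows of a matrix), `values`, and `rule_template` (a
#'   [success_rule()] whose active set excludes the swept property).
#' @export
sweep_conditions <- function(anchor_smiles, property, values, stats) {
  property <- match.arg(property, .PROPERTIES)
  base <- as.list(compute_properties(anchor_smiles)[1L, .PROPERTIES])
  conds <- t(vapply(values, function(v) {
    p <- base
    p[[property]] <- if (property %in% .INTEGER) round(v) else v
    build_condition(p, stats)
  }, numeric(condition_dim(stats))))
  list(conditions = conds, values = values,
       rule_template = success_rule(base, stats,
                                    active = setdiff(.PROPERTIES, property)))
}
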