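
# Session cache: canonical SMILES + descriptors keyed by the input string.
# Generation loops hit the bridge in batches of thousands; interactive and
# test code tends to re-ask about the same few molecules, which this absorbs.
.chem_cache <- new.env(parent = emptyenv())

.bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "molcvae")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is not yet installed
    path <- file.path("inst", "python", "chem_bridge.py")
  }
  if (!file.exists(path)) stop("chem_bridge.py not found; broken installation")
  path
}

.python_bin <- function() {
  bin <- getOption("molcvae.python", Sys.which("python"))
  if (!nzchar(bin)) stop("no `python` interpreter on PATH; the RDKit bridge needs one")
  bin
}

#' Analyze SMILES strings with RDKit
#'
#' Runs a batch of SMILES strings through the RDKit bridge and returns, for
#' each input, its validity, canonical form and the five target descriptors
#' (exact molecular weight, Crippen LogP, Lipinski hydrogen-bond donor and
#' acceptor counts, Ertl TPSA).
#'
#' @param smiles character vector of SMILES strings (possibly invalid).
#' @return A data.frame with one row per input and columns
#'   `smiles`, `valid`, `canonical`, `mw`, `logp`, `hbd`, `hba`, `tpsa`.
#'   Descriptor columns are `NA` where `valid` is `FALSE`.
#' @examples
#' \dontrun{
#' smiles_analyze(c("CCO", "C1CC"))
#' }
#' @export
smiles_analyze <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- data.frame(
    smiles = smiles, valid = NA, canonical = NA_character_,
    mw = NA_real_, logp = NA_real_, hbd = NA_integer_, hba = NA_integer_,
    tpsa = NA_real_, stringsAsFactors = FALSE
  )
  if (length(smiles) == 0L) return(out)
  if (any(grepl("[\t\n]", smiles))) stop("SMILES strings must not contain tabs or newlines")

  key <- paste0(".", smiles)  # avoid the empty string as an env key
  cached <- vapply(key, function(k) !is.null(.chem_cache[[k]]), logical(1))
  todo <- unique(key[!cached])

  if (length(todo) > 0L) {
    fin <- tempfile("smi"); fout <- tempfile("smi")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(substring(todo, 2L), fin)
    status <- system2(.python_bin(), shQuote(.bridge_script()),
                      stdin = fin, stdout = fout, stderr = FALSE)
    if (status != 0L) stop("RDKit bridge failed with exit status ", status)
    res <- utils::read.table(fout, sep = "\t", quote = "", comment.char = "",
                             na.strings = "NA", stringsAsFactors = FALSE,
                             col.names = c("valid", "canonical", "mw", "logp",
                                           "hbd", "hba", "tpsa"))
    if (nrow(res) != length(todo)) stop("RDKit bridge returned a short batch")
    for (i in seq_along(todo)) {
      .chem_cache[[todo[i]]] <- res[i, , drop = FALSE]
    }
  }

  rows <- do.call(rbind, lapply(key, function(k) .chem_cache[[k]]))
  out$valid <- rows$valid == 1L
  out$canonical <- rows$canonical
  out$mw <- rows$mw
  out$logp <- rows$logp
  out$hbd <- as.integer(rows$hbd)
  out$hba <- as.integer(rows$hba)
  out$tpsa <- rows$tpsa
  rownames(out) <- NULL
  out
}

#' Canonicalize SMILES strings
#'
#' Maps each SMILES to the toolkit's unique canonical form, so that two
#' encodings of the same molecule compare equal. Idempotent.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical SMILES, same length.
#' @export
canonicalize <- function(smiles) {
  res <- smiles_analyze(smiles)
  bad <- !res$valid
  if (any(bad)) {
    stop("invalid SMILES: ", paste(sQuote(smiles[bad]), collapse = ", "))
  }
  res$canonical
}

#' Check SMILES validity
#'
#' @param smiles character vector.
#' @return logical vector: does each string parse as a valid molecule?
#' @export
is_valid_smiles <- function(smiles) {
  smiles_analyze(smiles)$valid
}

#' Compute the five target molecular descriptors
#'
#' Returns the property vector used throughout the model: exact (monoisotopic)
#' molecular weight in Da, Wildman-Crippen LogP, Lipinski hydrogen-bond donor
#' and acceptor counts, and Ertl topological polar surface area in Angstrom^2.
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame with columns `smiles`, `mw`, `logp`, `hbd`, `hba`,
#'   `tpsa`, one row per input.
#' @examples
#' \dontrun{
#' compute_properties("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
#' }
#' @export
compute_properties <- function(smiles) {
  res <- smiles_analyze(smiles)
  bad <- !res$valid
  if (any(bad)) {
    stop("invalid SMILES: ", paste(sQuote(smiles[bad]), collapse = ", "))
  }
  res[, c("smiles", "mw", "logp", "hbd", "hba", "tpsa")]
}
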