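# Synthetic fixture corpus: small, valid, drug-like organic molecules
# assembled from scaffold families and substituent pools. Stands in for a
# ZINC extract so that every module is exercisable without a download. The
# molecules are deliberately simpler than ZINC drug-like compounds; see the
# vignette for what that implies about desk-scale results.

.ALKYLS <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "C(C)C",
             "CC(C)CC", "CCC(C)C", "CC(C)(C)C", "CCCCCC", "C(C)(C)C",
             "CCOC", "CCN(C)C")

.AR_SUBS <- c("C", "CC", "CCC", "O", "OC", "OCC", "N", "NC", "Cl",
              "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)C", "CO", "CCO", "C#N")

# templates with one or two substituent slots ({A}, {B})
.AROMATIC_TEMPLATES <- c(
  "{A}c1ccccc1", "{A}c1ccc({B})cc1", "{A}c1cccc({B})c1", "{A}c1ccc({B})cc1O",
  "{A}c1ccncc1", "{A}c1ccc({B})nc1", "{A}c1ccc({B})s1", "{A}c1ccc({B})o1",
  "{A}c1cccs1", "{A}c1ccco1"
)

.NESTED_TEMPLATES <- c(
  "O=C(N{A})C1CCN(c2ccc(N3CCOCC3)cc2)C1",
  "{A}N1CCN(c2ccc({B})cc2)CC1",
  "O=C({A})N1CCC(c2ccc({B})cc2)CC1",
  "O=C(O)C1CCN(C(=O)c2ccc(Cl)s2)CC1",
  "{A}OC(=O)c1ccc(N2CCOCC2)cc1",
  "O=C(N{A})c1ccc(N2CCCC2{B})cc1"
)

# always included: pins down the rarer vocabulary characters (aromatic s/o/n,
# 'Cl', '#', a third ring-closure digit) so the reference drugs stay
# encodable under the fixture vocabulary
.COVERAGE_SET <- c(
  "Clc1ccc(C(=O)O)s1",
  "O=C(NC)C1CCN(c2ccc(N3CCOCC3)cc2)C1",
  "CCOC(=O)c1ccncc1",
  "N#Cc1ccc(O)cc1",
  "CC(C)c1ccco1",
  "COC(=O)C1CCN(C(=O)c2ccc(N3CCOCC3)cc2)CC1",
  "COc1cc(OC)nc(N2CCOCC2)n1",
  "COc1ccc(C(=O)N2CCN(C)CC2)cn1"
)

.fill_template <- function(template, a, b) {
  out <- sub("{A}", a, template, fixed = TRUE)
  sub("{B}", b, out, fixed = TRUE)
}

.FAMILIES <- c("alkane", "alcohol", "ether", "amine", "acid", "ester",
               "amide", "ketone", "aromatic", "nested")

# one raw SMILES from a scaffold family (consumes the current RNG stream)
.raw_molecule <- function(family) {
  a <- sample(.ALKYLS, 1L)
  b <- sample(.ALKYLS, 1L)
  switch(family,
    alkane = a,
    alcohol = paste0("OC", a),
    ether = paste0(a, "OC", b),
    amine = paste0("NC", a),
    acid = paste0(a, "C(=O)O"),
    ester = paste0(a, "C(=O)O", b),
    amide = paste0(a, "C(=O)N", b),
    ketone = paste0(a, "C(=O)", b),
    aromatic = .fill_template(sample(.AROMATIC_TEMPLATES, 1L),
                              sample(.AR_SUBS, 1L), sample(.AR_SUBS, 1L)),
    nested = .fill_template(sample(.NESTED_TEMPLATES, 1L), a,
                            sample(.AR_SUBS, 1L)),
    stop("unknown scaffold family: ", family)
  )
}

# sampling weights lean toward polar, ring-bearing families so the corpus
# property distribution is drug-like rather than alkane-dominated
.FAMILY_WEIGHTS <- c(alkane = 0.04, alcohol = 0.08, ether = 0.06,
                     amine = 0.08, acid = 0.08, ester = 0.10, amide = 0.10,
                     ketone = 0.06, aromatic = 0.25, nested = 0.15)

#' Generate a synthetic SMILES fixture corpus
#'
#' Deterministically assembles `n` unique, valid, canonical SMILES from
#' scaffold families (alkanes, alcohols, ethers, amines, carboxylic acids,
#' esters, amides, ketones, substituted aromatics and small polycyclics).
#' The emitted corpus spans non-degenerate ranges of all five target
#' descriptors, so normalization is always well posed, and its character set
#' covers the five reference drugs of [known_drugs()].
#'
#' @param n number of unique molecules (default 2000).
#' @param seed RNG seed; the corpus is a pure function of `(n, seed,
#'   max_chars, families)`.
#' @param max_chars maximum SMILES length (leaves room for the end token at
#'   the model's unroll length).
#' @param families subset of scaffold families to use.
#' @return list with `smiles` (character vector of `n` canonical SMILES) and
#'   `properties` (data.frame from [compute_properties()]).
#' @export
generate_corpus <- function(n = 2000L, seed = 1L, max_chars = 44L,
                            families = .FAMILIES) {
  families <- match.arg(families, .FAMILIES, several.ok = TRUE)
  set.seed(seed)
  weights <- .FAMILY_WEIGHTS[families] / sum(.FAMILY_WEIGHTS[families])
  pool <- character()
  keep_cov <- all(c("aromatic", "nested") %in% families)
  if (keep_cov) pool <- canonicalize(.COVERAGE_SET)
  pool <- unique(pool[nchar(pool) <= max_chars])
  rounds <- 0L
  while (length(pool) < n && rounds < 60L) {
    rounds <- rounds + 1L
    fams <- sample(families, size = max(2L * (n - length(pool)), 200L),
                   replace = TRUE, prob = weights)
    raw <- vapply(fams, .raw_molecule, character(1))
    ana <- smiles_analyze(unique(raw))
    ok <- ana$valid & nchar(ana$canonical) <= max_chars
    pool <- unique(c(pool, ana$canonical[ok]))
  }
  if (length(pool) < n) {
    stop("could only assemble ", length(pool), " unique molecules (asked for ",
         n, "); widen the family set or relax max_chars")
  }
  smiles <- pool[seq_len(n)]
  list(smiles = smiles, properties = compute_properties(smiles))
}

#' Write a fixture corpus to disk
#'
#' Emits the plain-text SMILES format consumed by training (one molecule per
#' line) and the property table as CSV.
#'
#' @param corpus a list as returned by [generate_corpus()].
#' @param smiles_path path for the SMILES text file.
#' @param properties_path optional path for the property CSV.
#' @return `smiles_path`, invisibly.
#' @export
write_corpus <- function(corpus, smiles_path, properties_path = NULL) {
  writeLines(corpus$smiles, smiles_path)
  if (!is.null(properties_path)) {
    utils::write.csv(corpus$properties, properties_path, row.names = FALSE)
  }
  invisible(smiles_path)
}

#' Reference drug molecules
#'
#' The five top-selling small-molecule drugs used as conditioning anchors
#' and descriptor test cases: aspirin, oseltamivir (Tamiflu), lenalidomide,
#' rivaroxaban and pregabalin.
#'
#' @return named character vector of SMILES.
#' @export
known_drugs <- function() {
  c(aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    oseltamivir = "CCC(CC)OC1C=C(C(=O)OCC)CC(N)C1NC(C)=O",
    lenalidomide = "O=C1CCC(N2C(=O)c3cccc(N)c3C2=O)C(=O)N1",
    rivaroxaban = "O=C(NCC1CN(c2ccc(N3CCOCC3=O)cc2)C(=O)O1)c1ccc(Cl)s1",
    pregabalin = "CC(C)CC(CN)CC(=O)O")
}
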