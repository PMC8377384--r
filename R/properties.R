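#' Amino-acid physicochemical property tables
#'
#' The package ships eight classical per-residue property scales as plain CSV
#' files under `inst/extdata/properties/`. Each scale assigns one real value to
#' each of the 20 standard amino acids. Encoders never consume the raw values
#' directly: every scale is standardized to zero mean and unit variance across
#' the 20 amino acids (population convention, divisor 20) so that descriptors
#' computed from different scales are commensurable, and so that the wildcard
#' residue `X` can be given the neutral value 0.
#'
#' @param name Property name; one of `"hydrophobicity"`, `"hydrophilicity"`,
#'   `"side_chain_mass"`, `"side_chain_volume"`, `"polarity"`,
#'   `"polarizability"`, `"sasa"`, `"net_charge_index"`.
#' @return For `aa_property()`: a tibble with columns `amino_acid`, `value`
#'   (raw) and `normalized`. For `aa_property_vector()`: a named numeric
#'   vector of normalized values keyed by one-letter amino-acid code, with an
#'   `"X"` entry equal to 0.
#' @examples
#' aa_property("hydrophobicity")
#' aa_property_vector("polarity")[c("A", "W")]
#' @export
aa_property <- function(name) {
  name <- match.arg(name, aa_property_names())
  path <- system.file("extdata", "properties", paste0(name, ".csv"),
                      package = "ppiboost", mustWork = TRUE)
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!setequal(raw$amino_acid, AA20) || anyDuplicated(raw$amino_acid)) {
    abort(paste0("property table '", name, "' must key each amino acid exactly once"))
  }
  v <- setNames(raw$value, raw$amino_acid)[AA20]
  tibble(
    amino_acid = AA20,
    value = unname(v),
    normalized = unname(normalize_property(v))
  )
}

#' @rdname aa_property
#' @export
aa_property_names <- function() {
  c("hydrophobicity", "hydrophilicity", "side_chain_mass", "side_chain_volume",
    "polarity", "polarizability", "sasa", "net_charge_index")
}

#' @rdname aa_property
#' @export
aa_property_vector <- function(name) {
  key <- paste0("prop_", name)
  cached <- .ppiboost_cache[[key]]
  if (!is.null(cached)) return(cached)
  tab <- aa_property(name)
  out <- c(setNames(tab$normalized, tab$amino_acid), X = 0)
  assign(key, out, envir = .ppiboost_cache)
  out
}

.ppiboost_cache <- new.env(parent = emptyenv())

# Zero-mean / unit-variance standardization across the 20 amino acids,
# population convention (divisor 20).
normalize_property <- function(v) {
  stopifnot(length(v) == 20)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  (v - m) / s
}

# The three classical scales of type-1 pseudo amino acid composition.
pseaac_property_names <- function() {
  c("hydrophobicity", "hydrophilicity", "side_chain_mass")
}

# The seven scales used by the autocorrelation descriptors; the reduced
# sequence and index-vector encoder uses the first six (all but the net
# charge index).
ad_property_names <- function() {
  c("hydrophobicity", "hydrophilicity", "side_chain_volume", "polarity",
    "polarizability", "sasa", "net_charge_index")
}

rsiv_property_names <- function() {
  ad_property_names()[1:6]
}

# 20x20 BLOSUM62 block in PSI-BLAST column order; backs the pseudo-PSSM
# fallback when no alignment-derived profile is supplied.
blosum62_block <- function() {
  cached <- .ppiboost_cache[["blosum62"]]
  if (!is.null(cached)) return(cached)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b <- env$BLOSUM62[PSSM_AA, PSSM_AA]
  assign("blosum62", b, envir = .ppiboost_cache)
  b
}
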