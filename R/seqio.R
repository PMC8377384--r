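#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a protein table. Record ids are taken as the first
#' whitespace-delimited token of each header; multi-line sequences are joined
#' and upper-cased. Residues outside the 20-letter amino-acid alphabet are
#' handled according to `lenient`: by default the non-standard codes
#' `B, Z, U, O, J, *` (and any other letter) are mapped to the wildcard `X`
#' with a warning, while strict mode raises an error naming the first
#' offending record and position.
#'
#' @param path Path to a FASTA file.
#' @param lenient Map non-standard residues to `X` (default) instead of
#'   raising an error.
#' @return A tibble with columns `id`, `sequence` and `length`, one row per
#'   record, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, lenient = TRUE) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (!any(startsWith(readLines(path, warn = FALSE), ">"))) {
    abort(paste0("no records in FASTA file: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1)
  if (any(!nzchar(ids))) abort("empty FASTA header id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- clean_sequences(seqs, ids, lenient = lenient)
  tibble(id = unname(ids), sequence = unname(seqs), length = nchar(unname(seqs)))
}

# Enforce the A..Y (+X) alphabet; lenient mode rewrites anything else to X.
clean_sequences <- function(seqs, ids, lenient = TRUE) {
  ok <- paste0(c(AA20, "X"), collapse = "")
  bad <- regexpr(paste0("[^", ok, "]"), seqs)
  if (any(bad > 0)) {
    first <- which(bad > 0)[1]
    if (!lenient) {
      abort(sprintf(
        "non-standard residue '%s' at position %d of record '%s' (strict mode)",
        substr(seqs[first], bad[first], bad[first]), bad[first], ids[first]
      ))
    }
    warn(sprintf(
      "%d record(s) contain non-standard residues; mapped to X (first: '%s' position %d)",
      sum(bad > 0), ids[first], bad[first]
    ))
    seqs <- gsub(paste0("[^", ok, "]"), "X", seqs)
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for record '", ids[which(nchar(seqs) == 0)[1]], "'"))
  }
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read and write labeled protein-pair tables
#'
#' A pair table is a delimited text file with three columns: `id_a`, `id_b`
#' and a binary interaction `label`. A single header row is auto-detected
#' (third field non-numeric). Labels `"1"`/`"0"` and `"+1"`/`"-1"` are
#' accepted; `-1` is mapped to 0. Any other label value is an error naming
#' the offending row.
#'
#' @param path Path to the pair table.
#' @param delimiter Field delimiter (default tab).
#' @return A tibble with character columns `id_a`, `id_b` and integer `label`
#'   in `{0, 1}`, in file order.
#' @export
read_pair_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort(paste0("pair table not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("no rows in pair table: ", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  start <- 1L
  if (length(fields[[1]]) == 3 &&
      is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L # header row
    if (length(fields) < 2) abort(paste0("no data rows in pair table: ", path))
  }
  rows <- fields[start:length(fields)]
  out <- purrr::imap(rows, function(f, i) {
    row <- i + start - 1L
    if (length(f) != 3) {
      abort(sprintf("pair table row %d: expected 3 columns, found %d", row, length(f)))
    }
    lab <- switch(trimws(f[3]), "1" = 1L, "+1" = 1L, "0" = 0L, "-1" = 0L, NA_integer_)
    if (is.na(lab)) {
      abort(sprintf("pair table row %d: label '%s' is not in {0, 1, +1, -1}", row, f[3]))
    }
    tibble(id_a = trimws(f[1]), id_b = trimws(f[2]), label = lab)
  })
  bind_rows(out)
}

#' @rdname read_pair_table
#' @param pairs A tibble with columns `id_a`, `id_b`, `label`.
#' @export
write_pair_table <- function(pairs, path, delimiter = "\t") {
  stopifnot(all(c("id_a", "id_b", "label") %in% names(pairs)))
  header <- paste(c("id_a", "id_b", "label"), collapse = delimiter)
  body <- paste(pairs$id_a, pairs$id_b, pairs$label, sep = delimiter)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the text matrix written by PSI-BLAST's `-out_ascii_pssm` option:
#' banner lines, a header row of 40 amino-acid letters, then one row per
#' sequence position holding the position index, the query residue, 20
#' log-odds integers (kept) and 20 weighted-percentage columns (ignored),
#' followed by trailing statistics lines (ignored). The parser is insensitive
#' to run-length whitespace and to the presence or absence of the trailing
#' block.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_id Optional id to attach; defaults to the file's base name.
#' @return An object of class `pssm`: a list with `protein_id`, `residues`
#'   (character vector of query residues) and `scores` (L x 20 numeric matrix,
#'   columns in PSI-BLAST order `A R N D C Q E G H I L K M F P S T W Y V`).
#' @seealso [write_pssm()], [pseudo_pssm()]
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) abort(paste0("PSSM file not found: ", path))
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  is_data <- vapply(toks, function(f) {
    length(f) >= 2 && grepl("^[0-9]+$", f[1]) && grepl("^[A-Z]$", f[2])
  }, logical(1))
  if (!any(is_data)) abort(paste0("no PSSM data rows in: ", path))
  rows <- which(is_data)
  residues <- character(length(rows))
  scores <- matrix(NA_real_, nrow = length(rows), ncol = 20,
                   dimnames = list(NULL, PSSM_AA))
  for (i in seq_along(rows)) {
    f <- toks[[rows[i]]]
    vals <- suppressWarnings(as.numeric(f[-(1:2)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 20) {
      abort(sprintf("PSSM row %d (line %d): fewer than 20 score columns",
                    i, rows[i]))
    }
    residues[i] <- f[2]
    scores[i, ] <- vals[1:20]
  }
  structure(list(protein_id = protein_id, residues = residues, scores = scores),
            class = "pssm")
}

#' Write a position-specific scoring matrix in PSI-BLAST ASCII layout
#'
#' Emits the same layout `read_pssm()` consumes, including the 40-letter
#' header, a mirrored percentage block (zeros) and per-row information
#' columns, so synthetic profiles exercise the full parser.
#'
#' @param pssm A `pssm` object (see [read_pssm()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  s <- pssm$scores
  header <- paste0(
    "           ",
    paste(sprintf("%3s", c(PSSM_AA, PSSM_AA)), collapse = "")
  )
  rows <- vapply(seq_len(nrow(s)), function(i) {
    paste0(
      sprintf("%5d %s ", i, pssm$residues[i]),
      paste(sprintf(" %3d", as.integer(round(s[i, ]))), collapse = ""),
      paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
      "  0.00 0.00"
    )
  }, character(1))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    header,
    rows,
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3176"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @method print pssm
#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s: %d positions x 20 scores\n",
              x$protein_id, nrow(x$scores)))
  invisible(x)
}

# Query sequence reconstructed from the PSSM residue column.
#' @rdname read_pssm
#' @param pssm A `pssm` object.
#' @export
pssm_sequence <- function(pssm) paste(pssm$residues, collapse = "")

#' Read and write feature-matrix CSV files
#'
#' Feature matrices travel as CSV with a header row of feature names and one
#' or more leading id columns (`protein_id` for per-protein matrices; `id_a`,
#' `id_b`, `label` for pair matrices).
#'
#' @param path CSV path.
#' @return A tibble; id columns are character, feature columns numeric.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("feature matrix not found: ", path))
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' @rdname read_feature_matrix
#' @param features A tibble as produced by [encode_proteins()] or
#'   [encode_pairs()].
#' @export
write_feature_matrix <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Save and load fitted pipeline objects
#'
#' Single-file serialization for fitted objects (feature selection models,
#' gradient-boosting models, pipeline reports) with an embedded schema-version
#' string that is checked on load.
#'
#' @param object Object to serialize.
#' @param path File path.
#' @return `load_model()` returns the deserialized object.
#' @export
save_model <- function(object, path) {
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    package_version = as.character(packageVersion("ppiboost")),
    object = object
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$schema_version)) {
    abort("not a ppiboost model file (missing schema version)")
  }
  if (payload$schema_version != MODEL_SCHEMA_VERSION) {
    abort(paste0("unsupported model schema version: ", payload$schema_version))
  }
  payload$object
}

MODEL_SCHEMA_VERSION <- "ppiboost-model-1"
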