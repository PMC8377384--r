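#' Encoder configuration
#'
#' Bundles the tunable parameters of the four sequence encoders. `lambda` is
#' the pseudo amino acid composition rank (number of sequence-order
#' correlation terms), `xi` the pseudo-PSSM lag, `lag` the maximum
#' autocorrelation lag and `w` the weight balancing composition against
#' sequence-order terms in the pseudo amino acid composition. Defaults
#' (`lambda = 11`, `xi = 9`, `lag = 11`, `w = 0.05`) give the 31/200/197/231
#' per-encoder dimensions and the fused 659-dimensional per-protein vector.
#' Every encoded sequence must be longer than each of `lambda`, `xi`, `lag`.
#'
#' @param lambda Integer >= 0; pseudo amino acid composition rank.
#' @param xi Integer >= 0; pseudo-PSSM lag.
#' @param lag Integer >= 1; maximum autocorrelation lag.
#' @param w Real in (0, 1]; pseudo amino acid composition weight factor.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(lambda = 11L, xi = 9L, lag = 11L, w = 0.05) {
  lambda <- as.integer(lambda); xi <- as.integer(xi); lag <- as.integer(lag)
  if (lambda < 0) abort("lambda must be >= 0")
  if (xi < 0) abort("xi must be >= 0")
  if (lag < 1) abort("lag must be >= 1")
  if (!(w > 0 && w <= 1)) abort("w must be in (0, 1]")
  structure(list(lambda = lambda, xi = xi, lag = lag, w = w),
            class = "encoder_config")
}

seq_to_chars <- function(sequence) {
  strsplit(toupper(sequence), "")[[1]]
}

# Normalized property values along the sequence; X contributes 0 (the mean).
property_signal <- function(chars, prop_name) {
  unname(aa_property_vector(prop_name)[chars])
}

#' Pseudo amino acid composition encoder
#'
#' Type-1 pseudo amino acid composition over the three classical property
#' scales (hydrophobicity, hydrophilicity, side-chain mass). The first 20
#' components carry amino-acid composition, the remaining `lambda` components
#' carry rank-k sequence-order correlation factors
#' \eqn{\theta_k = \frac{1}{L-k}\sum_{i=1}^{L-k} \Theta(R_i, R_{i+k})}, where
#' \eqn{\Theta(a,b)} is the mean squared difference of the three normalized
#' property values between residues a and b. Components are jointly
#' normalized: \eqn{x_u = f_u / (\sum_v f_v + w \sum_k \theta_k)} for the 20
#' composition slots (f = residue counts, wildcard X excluded) and
#' \eqn{x_{20+k} = w\theta_k} over the same denominator, so the vector is
#' non-negative and sums to 1.
#'
#' @param sequence Amino-acid sequence (string over the 20-letter alphabet,
#'   optionally with `X`).
#' @param lambda Sequence-order rank; must be < sequence length.
#' @param w Weight factor in (0, 1].
#' @return Named numeric vector of length `20 + lambda` with names
#'   `pseaac_comp_*` and `pseaac_theta_*`.
#' @examples
#' length(encode_pseaac(strrep("ACDEFGHIKLMN", 5))) # 31
#' @export
encode_pseaac <- function(sequence, lambda = 11L, w = 0.05) {
  chars <- seq_to_chars(sequence)
  L <- length(chars)
  if (L <= lambda) {
    abort(sprintf("sequence too short for lambda: L = %d <= lambda = %d", L, lambda))
  }
  counts <- vapply(AA20, function(a) sum(chars == a), numeric(1))
  props <- vapply(pseaac_property_names(), function(p) property_signal(chars, p),
                  numeric(L))
  theta <- numeric(lambda)
  if (lambda > 0) {
    for (k in seq_len(lambda)) {
      d <- props[1:(L - k), , drop = FALSE] - props[(1 + k):L, , drop = FALSE]
      theta[k] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(counts) + w * sum(theta)
  out <- c(counts, w * theta) / denom
  names(out) <- c(paste0("pseaac_comp_", AA20),
                  if (lambda > 0) paste0("pseaac_theta_", seq_len(lambda)))
  out
}

#' Pseudo-PSSM encoder
#'
#' Summarizes an L x 20 position-specific scoring matrix into `20 + 20 * xi`
#' features. Each row of the matrix is first standardized across its 20
#' scores (row mean subtracted, divided by the population row standard
#' deviation; zero-variance rows become all-zero). The first 20 features are
#' the column means of the standardized matrix; the remaining blocks, one per
#' lag `g = 1..xi`, hold for each column j the mean squared lag-g difference
#' \eqn{\frac{1}{L-g}\sum_i (p'_{i,j} - p'_{i+g,j})^2}.
#'
#' @param pssm A `pssm` object or an L x 20 numeric matrix in PSI-BLAST
#'   column order.
#' @param xi Maximum profile lag; must be < number of rows.
#' @param sequence Optional sequence to cross-check the row count against.
#' @return Named numeric vector of length `20 + 20 * xi` with names
#'   `psepssm_mean_*` and `psepssm_lag{g}_*`.
#' @export
encode_psepssm <- function(pssm, xi = 9L, sequence = NULL) {
  scores <- if (inherits(pssm, "pssm")) pssm$scores else as.matrix(pssm)
  if (ncol(scores) != 20) abort("PSSM must have exactly 20 score columns")
  L <- nrow(scores)
  if (!is.null(sequence) && nchar(sequence) != L) {
    abort(sprintf("PSSM has %d rows but sequence has %d residues", L, nchar(sequence)))
  }
  if (L <= xi) abort(sprintf("sequence too short for xi: L = %d <= xi = %d", L, xi))
  m <- rowMeans(scores)
  s <- sqrt(rowMeans((scores - m)^2))
  p <- (scores - m) / ifelse(s > 0, s, 1)
  p[s == 0, ] <- 0
  out <- colMeans(p)
  if (xi > 0) {
    lags <- lapply(seq_len(xi), function(g) {
      d <- p[1:(L - g), , drop = FALSE] - p[(1 + g):L, , drop = FALSE]
      colMeans(d^2)
    })
    out <- c(out, unlist(lags))
  }
  names(out) <- c(paste0("psepssm_mean_", PSSM_AA),
                  if (xi > 0) unlist(lapply(seq_len(xi), function(g)
                    paste0("psepssm_lag", g, "_", PSSM_AA))))
  out
}

#' Reduced sequence and index-vector encoder
#'
#' A 197-dimensional descriptor in two blocks. The index-vector block (120 =
#' 6 properties x 20 amino acids) holds, for each of six physicochemical
#' scales, the normalized property value of each amino acid multiplied by its
#' relative frequency in the sequence. The reduced-sequence block (77 = 7 +
#' 49 + 21) maps the sequence onto the seven conjoint amino-acid classes
#' (\{A,G,V\}, \{I,L,F,P\}, \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\},
#' \{C\}) and collects the 7 class frequencies, the 49 ordered adjacent
#' class-dipeptide frequencies (counts / (L-1)) and the 21 unordered
#' distinct-class adjacent transition frequencies (counts / (L-1)).
#'
#' @inheritParams encode_pseaac
#' @return Named numeric vector of length 197 with names `rsiv_iv_*`,
#'   `rsiv_class_*`, `rsiv_di_*` and `rsiv_tr_*`.
#' @export
encode_rsiv <- function(sequence) {
  chars <- seq_to_chars(sequence)
  L <- length(chars)
  if (L < 2) abort("sequence too short for the reduced-sequence block (L < 2)")
  n_std <- sum(chars != "X")
  if (n_std == 0) abort("sequence contains no standard residues")
  freq <- vapply(AA20, function(a) sum(chars == a), numeric(1)) / n_std

  iv <- unlist(lapply(rsiv_property_names(), function(p) {
    pv <- aa_property_vector(p)[AA20]
    setNames(unname(pv) * freq, paste0("rsiv_iv_", p, "_", AA20))
  }))

  class_of <- rep(NA_integer_, length(chars))
  for (k in seq_along(AA_CLASSES)) {
    class_of[chars %in% AA_CLASSES[[k]]] <- k
  }
  cls_freq <- vapply(1:7, function(k) sum(class_of == k, na.rm = TRUE), numeric(1)) / n_std

  a <- class_of[-L]
  b <- class_of[-1]
  keep <- !is.na(a) & !is.na(b)
  di <- matrix(0, 7, 7)
  for (i in which(keep)) di[a[i], b[i]] <- di[a[i], b[i]] + 1
  di <- di / (L - 1)
  tr <- numeric(21)
  tr_names <- character(21)
  idx <- 1L
  for (c1 in 1:6) for (c2 in (c1 + 1):7) {
    tr[idx] <- di[c1, c2] + di[c2, c1]
    tr_names[idx] <- paste0("rsiv_tr_", c1, "_", c2)
    idx <- idx + 1L
  }
  di_vec <- as.vector(t(di)) # ordered (from-class major)
  di_names <- as.vector(t(outer(1:7, 1:7, function(i, j) paste0("rsiv_di_", i, "_", j))))

  c(iv,
    setNames(cls_freq, paste0("rsiv_class_", 1:7)),
    setNames(di_vec, di_names),
    setNames(tr, tr_names))
}

#' Autocorrelation descriptor encoder
#'
#' Moreau-Broto, Moran and Geary autocorrelations of seven physicochemical
#' property signals along the sequence, at lags `1..lag` (3 x 7 x lag
#' features). With \eqn{P'_i} the normalized property value at position i and
#' \eqn{\bar P} its sequence mean:
#' \itemize{
#'   \item Moreau-Broto: \eqn{\frac{1}{L-d} \sum_i P'_i P'_{i+d}}
#'   \item Moran: \eqn{\frac{\frac{1}{L-d}\sum_i (P'_i-\bar P)(P'_{i+d}-\bar P)}
#'     {\frac{1}{L}\sum_i (P'_i-\bar P)^2}}
#'   \item Geary: \eqn{\frac{\frac{1}{2(L-d)}\sum_i (P'_i-P'_{i+d})^2}
#'     {\frac{1}{L-1}\sum_i (P'_i-\bar P)^2}}
#' }
#' A property signal with zero sequence variance yields 0 for its Moran and
#' Geary features by convention.
#'
#' @inheritParams encode_pseaac
#' @param lag Maximum lag; must be < sequence length.
#' @return Named numeric vector of length `3 * 7 * lag`, ordered descriptor-
#'   major then property then lag, names `ad_{mba,ma,ga}_{property}_{d}`.
#' @export
encode_ad <- function(sequence, lag = 11L) {
  chars <- seq_to_chars(sequence)
  L <- length(chars)
  if (L <= lag) abort(sprintf("sequence too short for lag: L = %d <= lag = %d", L, lag))
  props <- ad_property_names()
  mba <- ma <- ga <- matrix(0, nrow = length(props), ncol = lag,
                            dimnames = list(props, NULL))
  for (p in props) {
    x <- property_signal(chars, p)
    xb <- mean(x)
    xc <- x - xb
    ss <- sum(xc^2)
    for (d in seq_len(lag)) {
      a <- x[1:(L - d)]; b <- x[(1 + d):L]
      mba[p, d] <- mean(a * b)
      if (ss > 0) {
        ma[p, d] <- mean(xc[1:(L - d)] * xc[(1 + d):L]) / (ss / L)
        ga[p, d] <- (sum((a - b)^2) / (2 * (L - d))) / (ss / (L - 1))
      }
    }
  }
  name_block <- function(tag, m) {
    setNames(as.vector(t(m)),
             as.vector(t(outer(props, seq_len(lag), function(p, d)
               paste0("ad_", tag, "_", p, "_", d)))))
  }
  c(name_block("mba", mba), name_block("ma", ma), name_block("ga", ga))
}

#' Fused per-protein feature vector
#'
#' Concatenates the four encoders in fixed order: pseudo amino acid
#' composition, pseudo-PSSM, reduced sequence and index-vectors,
#' autocorrelation descriptors. At default configuration the result has
#' 31 + 200 + 197 + 231 = 659 features.
#'
#' @inheritParams encode_pseaac
#' @param pssm A `pssm` object or L x 20 matrix; if `NULL`, a pseudo-PSSM is
#'   built from BLOSUM62 rows (see [pseudo_pssm()]) with a warning.
#' @param config An [encoder_config()].
#' @return Named numeric vector; length `(20 + lambda) + (20 + 20 xi) + 197 +
#'   21 lag`.
#' @export
encode_protein <- function(sequence, pssm = NULL, config = encoder_config()) {
  if (is.null(pssm)) {
    warn("no PSSM supplied; falling back to a BLOSUM62 pseudo-PSSM",
         class = "ppiboost_pseudo_pssm")
    pssm <- pseudo_pssm(sequence)
  }
  out <- c(
    encode_pseaac(sequence, lambda = config$lambda, w = config$w),
    encode_psepssm(pssm, xi = config$xi, sequence = sequence),
    encode_rsiv(sequence),
    encode_ad(sequence, lag = config$lag)
  )
  if (any(!is.finite(out))) abort("non-finite feature value produced")
  out
}

#' BLOSUM62 pseudo-PSSM
#'
#' Substitute profile for proteins without an alignment-derived PSSM: row i
#' is the BLOSUM62 substitution-score row of residue i (PSI-BLAST column
#' order). `X` rows are all zero.
#'
#' @inheritParams encode_pseaac
#' @param protein_id Id to attach to the profile.
#' @return A `pssm` object.
#' @export
pseudo_pssm <- function(sequence, protein_id = "pseudo") {
  chars <- seq_to_chars(sequence)
  b <- blosum62_block()
  scores <- matrix(0, nrow = length(chars), ncol = 20,
                   dimnames = list(NULL, PSSM_AA))
  std <- chars %in% PSSM_AA
  scores[std, ] <- b[chars[std], , drop = FALSE]
  structure(list(protein_id = protein_id, residues = chars, scores = scores),
            class = "pssm")
}

#' Encode a table of proteins
#'
#' Data-frame-first wrapper around [encode_protein()]: encodes every protein
#' in a table and returns one wide tibble of per-protein features. Proteins
#' with no matching entry in `pssms` fall back to the BLOSUM62 pseudo-PSSM;
#' the fallback is reported once with the ids concerned.
#'
#' @param proteins A tibble with columns `id` and `sequence` (see
#'   [read_fasta()]).
#' @param pssms Optional named list of `pssm` objects (or L x 20 matrices)
#'   keyed by protein id.
#' @param config An [encoder_config()].
#' @return A tibble with a leading `protein_id` column and one numeric column
#'   per feature.
#' @examples
#' prots <- tibble::tibble(id = c("p1", "p2"),
#'                         sequence = c(strrep("ACDEFGHIKL", 6),
#'                                      strrep("MNPQRSTVWY", 6)))
#' dim(encode_proteins(prots)) # 2 x 660
#' @export
encode_proteins <- function(proteins, pssms = NULL, config = encoder_config()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) abort("duplicate protein ids")
  missing_pssm <- if (is.null(pssms)) proteins$id else setdiff(proteins$id, names(pssms))
  if (length(missing_pssm) > 0) {
    warn(sprintf("no PSSM for %d protein(s); using BLOSUM62 pseudo-PSSM (e.g. '%s')",
                 length(missing_pssm), missing_pssm[1]),
         class = "ppiboost_pseudo_pssm")
  }
  vecs <- purrr::map2(proteins$id, proteins$sequence, function(id, sq) {
    pssm <- if (!is.null(pssms) && id %in% names(pssms)) pssms[[id]] else pseudo_pssm(sq, id)
    suppressWarnings(encode_protein(sq, pssm = pssm, config = config))
  })
  nm <- names(vecs[[1]])
  bad <- which(vapply(vecs, function(v) !identical(names(v), nm), logical(1)))
  if (length(bad) > 0) abort("inconsistent feature names across proteins")
  mat <- do.call(rbind, vecs)
  bind_cols(tibble(protein_id = proteins$id), as_tibble(mat))
}

#' Build per-pair feature vectors by concatenation
#'
#' Joins each pair with the per-protein feature table and concatenates the
#' two protein vectors (A-side features first, in pair-table order). With the
#' default 659-dimensional protein vectors this yields 1318 features per
#' pair. Optionally augments the table with the mirrored (B, A) version of
#' each pair.
#'
#' @param pairs A tibble with columns `id_a`, `id_b` and optionally `label`.
#' @param protein_features Output of [encode_proteins()].
#' @param augment_mirrored Also emit the (B, A) mirror of every pair
#'   (training-time augmentation; off by default).
#' @return A tibble with `id_a`, `id_b`, `label` (if present) and feature
#'   columns prefixed `a_` and `b_`.
#' @export
encode_pairs <- function(pairs, protein_features, augment_mirrored = FALSE) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), protein_features$protein_id)
  if (length(missing) > 0) {
    abort(paste0("pair table references unencoded protein(s): ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  if (augment_mirrored) {
    mirror <- pairs
    mirror$id_a <- pairs$id_b
    mirror$id_b <- pairs$id_a
    pairs <- bind_rows(pairs, mirror)
  }
  fm <- as.matrix(protein_features[, -1, drop = FALSE])
  rownames(fm) <- protein_features$protein_id
  a <- fm[pairs$id_a, , drop = FALSE]
  b <- fm[pairs$id_b, , drop = FALSE]
  colnames(a) <- paste0("a_", colnames(fm))
  colnames(b) <- paste0("b_", colnames(fm))
  id_cols <- pairs[, intersect(c("id_a", "id_b", "label"), names(pairs))]
  bind_cols(as_tibble(id_cols), as_tibble(a), as_tibble(b))
}

# Split a feature tibble into its id columns and a numeric matrix.
feature_parts <- function(features) {
  id_cols <- intersect(c("protein_id", "id_a", "id_b", "label"), names(features))
  x <- as.matrix(features[, setdiff(names(features), id_cols), drop = FALSE])
  storage.mode(x) <- "double"
  list(ids = features[, id_cols, drop = FALSE], x = x)
}
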