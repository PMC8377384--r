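#' Synthetic PPI study configuration
#'
#' Defaults define the package's reference study conditions: 120 proteins of
#' length 50-200, 400 labeled pairs balanced 50/50, a composition-similarity
#' signal of effect size 2 against standard logistic noise, and a 5% label
#' flip rate.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer (min, max) sequence lengths.
#' @param n_pairs Number of labeled pairs.
#' @param positive_fraction Fraction of positive labels before flips.
#' @param signal Effect size of the interaction rule (>= 0; 0 = pure null).
#' @param noise_flip Label-flip probability in [0, 0.5).
#' @param seed Integer master seed.
#' @param dirichlet_alpha Concentration of the per-protein composition bias.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 120L, length_range = c(50L, 200L),
                         n_pairs = 400L, positive_fraction = 0.5,
                         signal = 2.0, noise_flip = 0.05, seed = 1L,
                         dirichlet_alpha = 1.0) {
  stopifnot(n_proteins >= 2, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            n_pairs >= 1, positive_fraction > 0, positive_fraction < 1,
            signal >= 0, noise_flip >= 0, noise_flip < 0.5,
            dirichlet_alpha > 0)
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    n_pairs = as.integer(n_pairs),
    positive_fraction = positive_fraction,
    signal = signal,
    noise_flip = noise_flip,
    seed = as.integer(seed),
    dirichlet_alpha = dirichlet_alpha
  ), class = "synth_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic PPI dataset
#'
#' Produces random proteins, pseudo-PSSMs and a labeled pair table, fully
#' reproducible from the configuration seed. Each protein draws a composition
#' bias from a symmetric Dirichlet and its residues i.i.d. from that bias;
#' its PSSM is the BLOSUM62 row of each residue plus integer noise in
#' [-2, 2]. Candidate pairs are sampled without replacement; the latent
#' interaction score is `signal` times the standardized (z-scored across
#' candidates) cosine similarity of the two composition-bias vectors plus
#' standard logistic noise, the provisional label is score > median(score),
#' exact class balance at `positive_fraction` is enforced by stratified
#' subsampling down to `n_pairs`, and finally each kept label flips with
#' probability `noise_flip`. The signal thus lives in amino-acid composition
#' (reachable by the composition-based encoders) rather than in PSSM
#' structure.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_dataset` with `proteins` (tibble `id`,
#'   `sequence`, `length`), `pssms` (named list of `pssm` objects), `pairs`
#'   (tibble `id_a`, `id_b`, `label`), `latent` (per-pair tibble with the
#'   similarity, score, and pre-flip label) and the `config`.
#' @examples
#' ds <- generate_ppi_dataset(synth_config(n_proteins = 12, n_pairs = 20,
#'                                         length_range = c(30, 60)))
#' table(ds$pairs$label)
#' @export
generate_ppi_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("synth%03d", seq_len(n))
  bias <- t(vapply(seq_len(n),
                   function(i) rdirichlet1(rep(config$dirichlet_alpha, 20)),
                   numeric(20)))
  colnames(bias) <- AA20
  lens <- sample(config$length_range[1]:config$length_range[2], n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(AA20, lens[i], replace = TRUE, prob = bias[i, ]), collapse = "")
  }, character(1))
  proteins <- tibble(id = ids, sequence = seqs, length = lens)

  b62 <- blosum62_block()
  pssms <- setNames(lapply(seq_len(n), function(i) {
    chars <- seq_to_chars(seqs[i])
    scores <- b62[chars, , drop = FALSE] +
      matrix(sample(-2:2, lens[i] * 20, replace = TRUE), nrow = lens[i])
    dimnames(scores) <- list(NULL, PSSM_AA)
    structure(list(protein_id = ids[i], residues = chars, scores = scores),
              class = "pssm")
  }), ids)

  n_distinct <- n * (n - 1) / 2
  if (config$n_pairs > n_distinct) {
    abort(sprintf("n_pairs = %d exceeds the %d distinct protein pairs",
                  config$n_pairs, n_distinct))
  }
  n_pos <- round(config$positive_fraction * config$n_pairs)
  n_neg <- config$n_pairs - n_pos
  # oversample candidates so stratified subsampling can hit the class counts
  n_cand <- min(n_distinct, max(3L * config$n_pairs, n_pos + n_neg))
  all_pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  cand_idx <- sample.int(n_distinct, n_cand)
  i_a <- all_pairs[cand_idx, 1]
  i_b <- all_pairs[cand_idx, 2]
  cosim <- vapply(seq_len(n_cand), function(j) {
    u <- bias[i_a[j], ]; v <- bias[i_b[j], ]
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }, numeric(1))
  z <- (cosim - mean(cosim)) / stats::sd(cosim)
  score <- config$signal * z + rlogis(n_cand)
  lab0 <- as.integer(score > median(score))
  pos_pool <- which(lab0 == 1)
  neg_pool <- which(lab0 == 0)
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg) {
    abort("candidate pool cannot satisfy the requested positive fraction")
  }
  keep <- c(sample(pos_pool, n_pos), sample(neg_pool, n_neg))
  keep <- keep[sample.int(length(keep))]
  label <- lab0[keep]
  flip <- runif(length(keep)) < config$noise_flip
  pairs <- tibble(
    id_a = ids[i_a[keep]],
    id_b = ids[i_b[keep]],
    label = as.integer(ifelse(flip, 1L - label, label))
  )
  latent <- tibble(
    id_a = pairs$id_a, id_b = pairs$id_b,
    similarity = cosim[keep], z = z[keep], score = score[keep],
    label_preflip = label, flipped = flip
  )
  structure(list(proteins = proteins, pssms = pssms, pairs = pairs,
                 latent = latent, config = config),
            class = "synth_dataset")
}

#' @method print synth_dataset
#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("<synth_dataset> %d proteins, %d pairs (%d positive), signal = %g, seed = %d\n",
              nrow(x$proteins), nrow(x$pairs), sum(x$pairs$label),
              x$config$signal, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `proteins.fasta`, `pssm/<id>.pssm` (PSI-BLAST ASCII layout),
#' `pairs.tsv` and `manifest.json` (the generating configuration) under
#' `dir`.
#'
#' @param dataset A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ppi_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$proteins, file.path(dir, "proteins.fasta"))
  write_pair_table(dataset$pairs, file.path(dir, "pairs.tsv"))
  for (id in names(dataset$pssms)) {
    write_pssm(dataset$pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
  }
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read the PSSM files of a dataset directory
#'
#' @param dir Directory holding `<id>.pssm` files.
#' @return Named list of `pssm` objects.
#' @export
read_pssm_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.pssm$", full.names = TRUE)
  pssms <- lapply(files, read_pssm)
  setNames(pssms, vapply(pssms, `[[`, character(1), "protein_id"))
}
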