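#' Pipeline configuration
#'
#' Collects every knob of the five-step pipeline (input, feature extraction,
#' dimensionality reduction, boosted prediction, evaluation). Inputs come
#' either from files (`fasta`, `pssm_dir`, `pairs`) or from the built-in
#' generator (`simulate = synth_config(...)`); exactly one source must be
#' given. Every random stage derives its seed deterministically from the
#' master `seed`.
#'
#' @param fasta,pssm_dir,pairs Input paths (FASTA, directory of `.pssm`
#'   files, labeled pair table). `pssm_dir` may be `NULL`, in which case the
#'   BLOSUM62 pseudo-PSSM fallback is used.
#' @param simulate Optional [synth_config()] replacing file inputs.
#' @param workdir Directory for artifacts (created if needed).
#' @param encoder An [encoder_config()].
#' @param C Selection trade-off (default 1).
#' @param M,learning_rate,max_depth Boosting parameters.
#' @param k Cross-validation folds.
#' @param threshold Probability threshold for hard labels.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, pssm_dir = NULL, pairs = NULL,
                            simulate = NULL, workdir = tempfile("ppiboost_run_"),
                            encoder = encoder_config(), C = 1, M = 1000L,
                            learning_rate = 0.1, max_depth = 3L, k = 5L,
                            threshold = 0.5, seed = 1L) {
  if (is.null(simulate) && (is.null(fasta) || is.null(pairs))) {
    abort("either 'simulate' or both 'fasta' and 'pairs' must be given")
  }
  structure(list(
    fasta = fasta, pssm_dir = pssm_dir, pairs = pairs, simulate = simulate,
    workdir = workdir, encoder = encoder, C = C, M = as.integer(M),
    learning_rate = learning_rate, max_depth = as.integer(max_depth),
    k = as.integer(k), threshold = threshold, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full prediction pipeline
#'
#' Executes encode, select, train and evaluate in order and writes the
#' artifacts to the configured working directory: the per-pair feature
#' matrix (`features.csv`), the selection model (`selection.model`) and its
#' support list (`support.txt`), the boosted model (`gtb.model`), in-sample
#' predictions of the final model (`predictions.csv`), the cross-validation
#' report (`report.json`) and a manifest with the configuration and the MD5
#' checksum of every artifact (`manifest.json`). Rerunning an identical
#' configuration reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param write Write artifacts to `config$workdir` (default `TRUE`); the
#'   returned object is the same either way.
#' @return A list of class `ppi_pipeline`: the cross-validation report
#'   (`cv`), the final `selection` and `gtb` models fitted on all pairs,
#'   `predictions`, and the paths of written artifacts.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  # --- input stage -----------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    ds <- generate_ppi_dataset(sim)
    proteins <- ds$proteins; pssms <- ds$pssms; pairs <- ds$pairs
  } else {
    proteins <- read_fasta(config$fasta)
    pairs <- read_pair_table(config$pairs)
    pssms <- if (!is.null(config$pssm_dir)) read_pssm_dir(config$pssm_dir) else NULL
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  # --- feature extraction ----------------------------------------------
  protein_features <- stage("encode",
    encode_proteins(proteins, pssms = pssms, config = config$encoder))
  pair_features <- stage("encode", encode_pairs(pairs, protein_features))
  # --- evaluation (per-fold selection + training; no leakage) -----------
  cv <- stage("evaluate", cross_validate(
    pair_features, k = config$k, C = config$C, M = config$M,
    learning_rate = config$learning_rate, max_depth = config$max_depth,
    threshold = config$threshold, seed = config$seed))
  # --- final model on all pairs ----------------------------------------
  sel <- stage("select", fit_l1rlr(pair_features, C = config$C,
                                   seed = config$seed))
  selected <- stage("select", apply_selection(pair_features, sel))
  gtb <- stage("train", train_gtb(selected, M = config$M,
                                  learning_rate = config$learning_rate,
                                  max_depth = config$max_depth,
                                  seed = config$seed))
  prob <- predict(gtb, selected, type = "prob")
  predictions <- tibble(
    id_a = pairs$id_a, id_b = pairs$id_b,
    probability = prob,
    label = as.integer(prob >= config$threshold)
  )
  report <- list(
    seed = config$seed,
    k = config$k,
    params = cv$params,
    summary = cv$summary,
    per_fold = cv$per_fold,
    support_sizes = cv$support_sizes,
    n_pairs = nrow(pairs),
    n_proteins = nrow(proteins),
    n_features = ncol(pair_features) -
      length(intersect(c("id_a", "id_b", "label"), names(pair_features)))
  )
  out <- structure(list(cv = cv, selection = sel, gtb = gtb,
                        predictions = predictions, report = report,
                        config = config, paths = NULL),
                   class = "ppi_pipeline")
  if (write) out$paths <- write_pipeline_artifacts(out, pair_features)
  out
}

write_pipeline_artifacts <- function(pipeline, pair_features) {
  dir.create(pipeline$config$workdir, recursive = TRUE, showWarnings = FALSE)
  wd <- pipeline$config$workdir
  paths <- list(
    features = file.path(wd, "features.csv"),
    selection = file.path(wd, "selection.model"),
    support = file.path(wd, "support.txt"),
    gtb = file.path(wd, "gtb.model"),
    predictions = file.path(wd, "predictions.csv"),
    report = file.path(wd, "report.json"),
    manifest = file.path(wd, "manifest.json")
  )
  write_feature_matrix(pair_features, paths$features)
  save_model(pipeline$selection, paths$selection)
  writeLines(pipeline$selection$feature_names, paths$support)
  save_model(pipeline$gtb, paths$gtb)
  write.csv(pipeline$predictions, paths$predictions, row.names = FALSE)
  jsonlite::write_json(pipeline$report, paths$report, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  manifest <- list(
    package = "ppiboost",
    version = as.character(packageVersion("ppiboost")),
    seed = pipeline$config$seed,
    config = config_as_list(pipeline$config),
    checksums = as.list(tools::md5sum(unlist(paths[names(paths) != "manifest"])))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$encoder <- unclass(out$encoder)
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}

#' @method print ppi_pipeline
#' @export
print.ppi_pipeline <- function(x, ...) {
  cat("<ppi_pipeline>\n")
  print(x$cv)
  invisible(x)
}
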