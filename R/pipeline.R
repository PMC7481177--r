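#' Write a dataset container
#'
#' Versioned on-disk container for record or window tables: scalar columns
#' go to `manifest.csv`, each numeric list-column to a raw little-endian
#' double file (`<name>.bin`), and schema/shape metadata to `meta.json`.
#' The round trip is lossless (doubles are stored bit-exactly) and writing
#' the same data twice produces byte-identical files.
#'
#' @param data Records or windows tibble (list-columns hold equal-length
#'   numeric traces).
#' @param path Container directory (created if needed).
#' @param append Append to an existing container (schema must match).
#' @param seed Optional seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_container <- function(data, path, append = FALSE, seed = NULL) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  sig_cols <- names(data)[vapply(data, is.list, TRUE)]
  lens <- lapply(sig_cols, function(cl) unique(lengths(data[[cl]])))
  if (any(lengths(lens) != 1)) {
    abort_field("data", "each list-column must hold equal-length traces")
  }
  lens <- as.integer(unlist(lens))
  names(lens) <- sig_cols
  man <- data[setdiff(names(data), sig_cols)]
  man[] <- lapply(man, function(x) if (is.factor(x)) as.character(x) else x)
  if (!append) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    meta <- list(schema_version = 1L, n = nrow(data),
                 signal_columns = as.list(lens),
                 manifest_columns = names(man), seed = seed)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(man, file.path(path, "manifest.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  } else {
    meta <- read_meta(path)
    if (!identical(sort(names(meta$signal_columns)), sort(sig_cols)) ||
        !identical(meta$manifest_columns, names(man))) {
      rlang::abort("container schema mismatch on append")
    }
    meta$n <- meta$n + nrow(data)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(man, file.path(path, "manifest.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE, col.names = FALSE,
                       append = TRUE)
  }
  for (cl in sig_cols) {
    con <- file(file.path(path, paste0(cl, ".bin")),
                if (append) "ab" else "wb")
    writeBin(as.numeric(unlist(data[[cl]], use.names = FALSE)), con,
             size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

read_meta <- function(path) {
  f <- file.path(path, "meta.json")
  if (!file.exists(f)) rlang::abort(paste("not a container:", path))
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), 1L)) {
    rlang::abort(sprintf(
      "container schema version %s not supported (expected 1); migrate the container",
      meta$schema_version))
  }
  meta
}

#' Read a dataset container
#'
#' Inverse of [write_container()].  Label columns (`rhythm`, `qa`,
#' `qa_true`) are restored as factors; a missing `qa` column is tolerated
#' and filled with `NA` (unknown) for externally imported signals.
#'
#' @param path Container directory.
#' @return Tibble with manifest columns and one list-column per stored
#'   signal.
#' @export
read_container <- function(path) {
  meta <- read_meta(path)
  man <- utils::read.csv(file.path(path, "manifest.csv"),
                         stringsAsFactors = FALSE)
  out <- tibble::as_tibble(man)
  if (nrow(out) != meta$n) rlang::abort("container manifest is inconsistent with metadata")
  for (cl in c("rhythm")) if (cl %in% names(out)) out[[cl]] <- rhythm_factor(out[[cl]])
  for (cl in c("qa", "qa_true")) if (cl %in% names(out)) out[[cl]] <- qa_factor(out[[cl]])
  if (!"qa" %in% names(out) && !"qa_true" %in% names(out)) out$qa <- qa_factor(NA)
  for (cl in names(meta$signal_columns)) {
    L <- as.integer(meta$signal_columns[[cl]])
    v <- readBin(file.path(path, paste0(cl, ".bin")), "double",
                 n = meta$n * L, size = 8, endian = "little")
    if (length(v) != meta$n * L) rlang::abort("container signal file is truncated")
    m <- matrix(v, nrow = L)
    out[[cl]] <- lapply(seq_len(meta$n), function(i) m[, i])
  }
  out
}

#' Assign subject-disjoint train/validation/test splits
#'
#' Subjects are shuffled deterministically from the seed and allocated to
#' splits by the requested fractions; all windows of a subject land in the
#' same split, so no individual overlaps between sets.
#'
#' @param data Tibble with a subject column.
#' @param fractions Named non-negative fractions summing to 1 (default
#'   70/10/20 train/val/test).
#' @param subject Subject column name.
#' @param seed Integer seed.
#' @return `data` with a `split` factor column.
#' @export
assign_splits <- function(data, fractions = c(train = 0.7, val = 0.1, test = 0.2),
                          subject = "subject_id", seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    abort_field("fractions", "must be non-negative and sum to 1")
  }
  stopifnot(subject %in% names(data))
  set.seed(derive_seed(seed, "splits"))
  us <- sample(unique(data[[subject]]))
  cuts <- round(cumsum(fractions) * length(us))
  lab <- rep(names(fractions), diff(c(0, cuts)))
  assignment <- stats::setNames(lab, us)
  data$split <- factor(assignment[data[[subject]]], levels = names(fractions))
  data
}

#' Configure the end-to-end pipeline
#'
#' One global seed fans out to per-stage derived seeds, so every stage is
#' independently reproducible.  The default scale is a desk-scale smoke
#' configuration; raise `n_records` and the epoch counts for real use.
#'
#' @param out_dir Output directory for artifacts.
#' @param n_records Simulated records (stratified over rhythm x noise).
#' @param variant Classifier variant (see [model_variants()]).
#' @param cdae_epochs,clf_epochs Training epochs for the two phases.
#' @param splits Train/val/test fractions (subject-disjoint).
#' @param fs,duration Simulator geometry.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("ppgnet_run_"),
                            n_records = 280L, variant = "MT_PRETRAINED",
                            cdae_epochs = 3L, clf_epochs = 3L,
                            splits = c(train = 0.7, val = 0.1, test = 0.2),
                            fs = 128, duration = 25, seed = 1L) {
  if (abs(sum(splits) - 1) > 1e-8) abort_field("splits", "must sum to 1")
  structure(list(out_dir = out_dir, n_records = as.integer(n_records),
                 variant = variant, cdae_epochs = as.integer(cdae_epochs),
                 clf_epochs = as.integer(clf_epochs), splits = splits,
                 fs = fs, duration = duration, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> quality labels -> subject-disjoint split ->
#' autoencoder pretraining (pretrained variants) -> classifier training ->
#' prediction -> evaluation (overall, quality-filtered, per-individual) ->
#' class activation maps and embedding projection.  All artifacts are
#' written under `config$out_dir` together with a provenance record
#' (configuration hash, seed, package version).  A stage failure halts the
#' run with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the fitted models, predictions, metrics
#'   and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  say <- function(...) if (verbose) message("[ppgnet] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  }
  say("simulate: %d records", config$n_records)
  records <- stage("simulate", simulate_ppg_dataset(
    config$n_records, fs = config$fs, duration = config$duration,
    seed = derive_seed(config$seed, "pipeline_sim")))
  stage("simulate", write_container(records, file.path(out, "records"),
                                    seed = config$seed))
  say("preprocess")
  windows <- stage("preprocess", preprocess_records(records))
  windows$qa <- stage("qa", qa_oracle(windows))
  windows <- stage("split", assign_splits(windows, config$splits,
                                          seed = config$seed))
  stage("preprocess", write_container(windows, file.path(out, "windows"),
                                      seed = config$seed))
  tr <- windows[windows$split == "train", ]
  va <- windows[windows$split == "val", ]
  te <- windows[windows$split == "test", ]
  encoder <- NULL
  if (variant_pretrained(config$variant)) {
    say("pretrain autoencoder: %d windows, %d epochs", nrow(tr),
        config$cdae_epochs)
    cdae <- stage("pretrain", {
      m <- build_cdae(cdae_config(
        input_length = length(windows$samples[[1]]),
        epochs = config$cdae_epochs,
        seed = derive_seed(config$seed, "pipeline_cdae")))
      train_cdae(m, tr)
    })
    encoder <- extract_encoder(cdae)
    saveRDS(encoder, file.path(out, "encoder.rds"))
  }
  say("train classifier: variant %s, %d epochs", config$variant,
      config$clf_epochs)
  fit <- stage("train", {
    m <- build_afnet(config$variant,
                     input_length = length(windows$samples[[1]]),
                     seed = derive_seed(config$seed, "pipeline_clf"),
                     encoder = encoder)
    train_afnet(m, tr, epochs = config$clf_epochs,
                seed = derive_seed(config$seed, "pipeline_train"),
                val = va)
  })
  saveRDS(fit, file.path(out, "model.rds"))
  say("predict + evaluate: %d test windows", nrow(te))
  pred <- stage("predict", dplyr::bind_cols(
    te[c("window_id", "subject_id", "rhythm", "qa", "noise_factor")],
    predict(fit, te)[-1]))
  utils::write.csv(pred[setdiff(names(pred), "samples")],
                   file.path(out, "predictions.csv"), row.names = FALSE)
  metrics <- stage("evaluate", {
    overall <- metrics_report(pred$rhythm, pred$af_pred, rhythm_levels(),
                              quiet = TRUE)
    filtered <- qa_filtered_eval(pred, qa = "qa", quiet = TRUE)
    per_ind <- per_individual_aggregate(pred)
    list(overall = overall, qa_filtered = filtered, per_individual = per_ind)
  })
  jsonlite::write_json(list(
    overall = metrics$overall$aggregate,
    overall_per_class = metrics$overall$per_class,
    qa_filtered = metrics$qa_filtered$report$aggregate,
    qa_retained = metrics$qa_filtered$retained,
    per_individual = metrics$per_individual),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  say("explain")
  expl <- stage("explain", {
    sub <- te[seq_len(min(8, nrow(te))), ]
    cam <- class_activation_map(fit, sub)
    emb <- embed_windows(fit, te)
    proj <- embedding_projection(emb,
                                 seed = derive_seed(config$seed, "pipeline_umap"))
    proj$rhythm <- te$rhythm
    list(cam = cam, projection = proj)
  })
  utils::write.csv(cbind(window_id = expl$cam$window_id,
                         as.data.frame(do.call(rbind, expl$cam$cam))),
                   file.path(out, "cam.csv"), row.names = FALSE)
  utils::write.csv(expl$projection, file.path(out, "projection.csv"),
                   row.names = FALSE)
  prov <- list(config_hash = rlang::hash(unclass(config)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("ppgnet")),
               variant = config$variant, n_records = config$n_records)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE)
  say("done: %s", out)
  invisible(list(records = records, windows = windows, fit = fit,
                 predictions = pred, metrics = metrics, explain = expl,
                 out_dir = out, provenance = prov))
}
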