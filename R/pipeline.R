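# End-to-end orchestration of the three phases (preprocess -> supervised
# learning -> cluster prediction), artifact writing, and the
# model-comparison harness.

#' Pipeline configuration
#'
#' Bundles the k-mer, backbone, training and predictor settings of one
#' end-to-end run. Defaults mirror the reference operating point: 2-mers,
#' a 200-unit GRU with the 128/64/32/16 relu stack, and the K-means
#' predictor on the fourth feature layer.
#'
#' @param k k-mer length.
#' @param ordering Vocabulary id ordering (see [build_vocabulary()]).
#' @param unknown_kmer Policy for k-mers unseen at training time when
#'   tokenizing validation/test data: `"mask"` (id 0, default here) or
#'   `"error"`.
#' @param backbone_kind,gru_units,embedding_dim,dense_units,dropout_rate,latent_layer_index
#'   Passed to [backbone_config()].
#' @param input_encoding Passed to [backbone_config()].
#' @param epochs,batch_size,learning_rate,early_stopping_patience,monitor
#'   Passed to [train_config()].
#' @param predictor `"kmeans"` (the semi-supervised default) or one of the
#'   supervised comparators `"rf"`, `"svr"`, `"tree"`.
#' @param kmeans_restarts,kmeans_tol,kmeans_max_iter K-means options.
#' @param standardize_latents Standardize each latent dimension (zero
#'   mean, unit variance, computed on the set being clustered — no labels
#'   involved) before K-means. Relu activations have very unequal
#'   per-dimension scales, and without standardization a few
#'   high-magnitude dimensions dominate the Euclidean metric.
#' @param include_labelled_in_kmeans Fit K-means on the union of labelled
#'   and unlabelled latents instead of the unlabelled latents only.
#' @param learn_test_ratio,train_val_ratio Split ratios (see
#'   [split_dataset()]).
#' @param seed Global seed; every stochastic stage derives its own stream
#'   from it.
#' @return A config list of class `gmean_pipeline_config`.
#' @export
pipeline_config <- function(k = 2L,
                            ordering = "frequency_desc",
                            unknown_kmer = "mask",
                            backbone_kind = "gru",
                            gru_units = 200L,
                            embedding_dim = 32L,
                            dense_units = c(128L, 64L, 32L, 16L),
                            dropout_rate = 0.2,
                            latent_layer_index = 4L,
                            input_encoding = "embedding",
                            epochs = 50L,
                            batch_size = 32L,
                            learning_rate = 1e-3,
                            early_stopping_patience = 5L,
                            monitor = "val_loss",
                            predictor = c("kmeans", "rf", "svr", "tree"),
                            kmeans_restarts = 20L,
                            kmeans_tol = 1e-4,
                            kmeans_max_iter = 300L,
                            standardize_latents = TRUE,
                            include_labelled_in_kmeans = FALSE,
                            learn_test_ratio = c(4, 1),
                            train_val_ratio = c(4, 1),
                            seed = 1L) {
  predictor <- match.arg(predictor)
  cfg <- list(k = as.integer(k), ordering = ordering,
              unknown_kmer = unknown_kmer,
              backbone_kind = backbone_kind,
              gru_units = as.integer(gru_units),
              embedding_dim = as.integer(embedding_dim),
              dense_units = as.integer(dense_units),
              dropout_rate = dropout_rate,
              latent_layer_index = as.integer(latent_layer_index),
              input_encoding = input_encoding,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              early_stopping_patience = as.integer(early_stopping_patience),
              monitor = monitor,
              predictor = predictor,
              kmeans_restarts = as.integer(kmeans_restarts),
              kmeans_tol = kmeans_tol,
              kmeans_max_iter = as.integer(kmeans_max_iter),
              standardize_latents = isTRUE(standardize_latents),
              include_labelled_in_kmeans = include_labelled_in_kmeans,
              learn_test_ratio = learn_test_ratio,
              train_val_ratio = train_val_ratio,
              seed = as.integer(seed))
  structure(cfg, class = "gmean_pipeline_config")
}

resolve_input <- function(input) {
  if (inherits(input, "gmean_synth_config")) {
    generate_synthetic(input)
  } else if (is.character(input) && length(input) == 1L) {
    read_sequence_csv(input, has_labels = TRUE)
  } else if (is.data.frame(input)) {
    sequence_records(input$sequence, label = input$label, id = input$id)
  } else {
    stopf("run_pipeline: input must be a CSV path, a record data frame or a synthetic config")
  }
}

#' Run the full semi-supervised pipeline
#'
#' Executes preprocess -> supervised training -> latent extraction ->
#' K-means (or comparator) prediction -> evaluation on one labelled input,
#' using the two-stage 4:1 split protocol. Test labels are held out-of-band
#' and consulted only in the final evaluation step. The run is
#' reproducible: the same config and seed give identical vocabulary,
#' weights, centroids and predictions.
#'
#' @param input A labelled sequence CSV path, a sequence record data frame,
#'   or a [synthetic_config()] to generate from.
#' @param config A [pipeline_config()].
#' @param out_dir Directory for run artifacts (created if needed); `NULL`
#'   keeps everything in memory.
#' @param verbose Print stage progress and per-epoch training lines?
#' @return An object of class `gmean_run`: list with `report`
#'   (a [class_report()]), `accuracy`, `predictions` (data frame `id,
#'   predicted_label, cluster, distance_to_centroid`), `history`, `vocab`,
#'   `backbone`, `kmeans`, `cluster_map`, `split_sizes`, `config` and
#'   `artifacts` (paths, when `out_dir` is given).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "gmean_pipeline_config"))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    note("stage %s", name)
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  records <- stage("input", resolve_input(input))
  if (all(is.na(records$label))) stopf("run_pipeline: input must be labelled")
  note("loaded %d labelled records", nrow(records))

  split <- stage("split", split_dataset(records,
                                        config$learn_test_ratio,
                                        config$train_val_ratio,
                                        seed = derive_seed(config$seed, 11L)))
  note("split: %d train / %d validation / %d test",
       nrow(split$train), nrow(split$validation),
       nrow(split$test_unlabelled))

  vocab <- stage("vocabulary", {
    kc <- kmer_config(config$k)
    build_vocabulary(split$train, kc, config$ordering)
  })
  note("vocabulary: %d distinct %d-mers", length(vocab$kmers), vocab$k)

  enc <- function(recs) encode_dataset(recs, vocab, config$unknown_kmer)
  train_tok <- stage("tokenize", enc(split$train))
  val_tok <- enc(split$validation)
  test_tok <- enc(split$test_unlabelled)

  bcfg <- backbone_config(vocab_size = length(vocab$kmers),
                          embedding_dim = config$embedding_dim,
                          gru_units = config$gru_units,
                          dense_units = config$dense_units,
                          dropout_rate = config$dropout_rate,
                          latent_layer_index = config$latent_layer_index,
                          backbone_kind = config$backbone_kind,
                          input_encoding = config$input_encoding)
  tcfg <- train_config(epochs = config$epochs,
                       batch_size = config$batch_size,
                       learning_rate = config$learning_rate,
                       early_stopping_patience = config$early_stopping_patience,
                       monitor = config$monitor,
                       seed = derive_seed(config$seed, 31L))
  model <- stage("build", build_backbone(bcfg,
                                         seed = derive_seed(config$seed, 21L)))
  model <- stage("train", train_supervised(model, train_tok, val_tok, tcfg,
                                           verbose = verbose))
  note("trained %d epochs; best val_loss %.4f", nrow(model$history),
       min(model$history$val_loss))

  lat_train <- stage("latent", extract_latent(model, train_tok))
  lat_test <- extract_latent(model, test_tok)

  if (config$predictor == "kmeans") {
    km_X <- if (config$include_labelled_in_kmeans) {
      rbind(lat_test, lat_train)
    } else {
      lat_test
    }
    lat_train_km <- lat_train
    lat_test_km <- lat_test
    if (config$standardize_latents) {
      # per-dimension z-scores, fitted on the clustered set itself (no
      # labels): keeps the Euclidean metric from being dominated by a few
      # high-magnitude relu dimensions
      mu <- colMeans(km_X)
      sdv <- apply(km_X, 2L, stats::sd)
      sdv[sdv < 1e-12] <- 1
      std <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
      km_X <- std(km_X)
      lat_train_km <- std(lat_train)
      lat_test_km <- std(lat_test)
    }
    km <- stage("kmeans", kmeans_fit(km_X, c = 2L,
                                     seed = derive_seed(config$seed, 41L),
                                     tol = config$kmeans_tol,
                                     max_iter = config$kmeans_max_iter,
                                     n_restarts = config$kmeans_restarts))
    cmap <- stage("cluster-map",
                  map_clusters_to_labels(km, lat_train_km, train_tok$labels))
    clusters <- kmeans_assign(km, lat_test_km)
    pred <- cmap$mapping[clusters]
    d2 <- sq_dist_to_centroids(lat_test_km, km$centroids)
    dist <- sqrt(d2[cbind(seq_along(clusters), clusters)])
  } else {
    km <- NULL
    cmap <- NULL
    pred <- stage(config$predictor,
                  comparator_predict(config$predictor, lat_train,
                                     train_tok$labels, lat_test,
                                     seed = derive_seed(config$seed, 41L)))
    clusters <- rep(NA_integer_, length(pred))
    dist <- rep(NA_real_, length(pred))
  }

  predictions <- data.frame(id = split$test_unlabelled$id,
                            predicted_label = as.integer(pred),
                            cluster = clusters,
                            distance_to_centroid = dist,
                            stringsAsFactors = FALSE)
  report <- stage("evaluate", class_report(split$test_labels, pred))
  note("test accuracy %.4f", report$accuracy[1L])

  artifacts <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    artifacts <- list(
      vocabulary = file.path(out_dir, "vocabulary.tsv"),
      checkpoint = file.path(out_dir, "backbone.rds"),
      kmeans = file.path(out_dir, "kmeans.tsv"),
      predictions = file.path(out_dir, "predictions.csv"),
      report_csv = file.path(out_dir, "report.csv"),
      report_txt = file.path(out_dir, "report.txt"),
      history = file.path(out_dir, "history.csv"),
      log = file.path(out_dir, "run.log"))
    write_vocabulary(vocab, artifacts$vocabulary)
    save_backbone(model, artifacts$checkpoint)
    if (!is.null(km)) write_kmeans(km, cmap, artifacts$kmeans)
    utils::write.csv(predictions, artifacts$predictions, row.names = FALSE)
    write_report_csv(report, artifacts$report_csv)
    writeLines(format_report(report), artifacts$report_txt)
    utils::write.csv(model$history, artifacts$history, row.names = FALSE)
    writeLines(log_lines, artifacts$log)
  }

  structure(list(report = report,
                 accuracy = report$accuracy[1L],
                 predictions = predictions,
                 history = model$history,
                 vocab = vocab,
                 backbone = model,
                 kmeans = km,
                 cluster_map = cmap,
                 split_sizes = c(train = nrow(split$train),
                                 validation = nrow(split$validation),
                                 test = nrow(split$test_unlabelled)),
                 test_labels = split$test_labels,
                 config = config,
                 log = log_lines,
                 artifacts = artifacts),
            class = "gmean_run")
}

#' @export
print.gmean_run <- function(x, ...) {
  cat(sprintf("Semi-supervised run: %s backbone, %s predictor, k = %d\n",
              toupper(x$config$backbone_kind), x$config$predictor,
              x$config$k))
  cat(sprintf("  split %d/%d/%d; %d training epochs\n",
              x$split_sizes[1L], x$split_sizes[2L], x$split_sizes[3L],
              nrow(x$history)))
  print(x$report)
  invisible(x)
}

#' Model-comparison harness
#'
#' Runs the full pipeline over a grid of backbones, predictors, k-mer
#' lengths and recurrent unit counts, and collects accuracy plus per-class
#' precision/recall/F1 into one table. A failing cell is recorded as
#' failed rather than aborting the grid. With a singleton grid the row
#' reproduces [run_pipeline()] under the same seed.
#'
#' @param input As in [run_pipeline()].
#' @param backbones,predictors Character vectors of backbone and predictor
#'   kinds.
#' @param k_values,unit_values Integer vectors of k-mer lengths and
#'   recurrent unit counts.
#' @param config Base [pipeline_config()] supplying all other settings.
#' @param verbose Print one line per cell?
#' @return A data frame with one row per combination: `backbone`,
#'   `predictor`, `k`, `units`, `accuracy`, `precision_0`, `recall_0`,
#'   `f1_0`, `precision_1`, `recall_1`, `f1_1`, `failed`, `error`.
#' @export
compare_models <- function(input,
                           backbones = "gru",
                           predictors = "kmeans",
                           k_values = 2L,
                           unit_values = 200L,
                           config = pipeline_config(),
                           verbose = FALSE) {
  grid <- expand.grid(backbone = backbones, predictor = predictors,
                      k = k_values, units = unit_values,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    cfg <- config
    cfg$backbone_kind <- cell$backbone
    cfg$predictor <- cell$predictor
    cfg$k <- as.integer(cell$k)
    cfg$gru_units <- as.integer(cell$units)
    out <- data.frame(cell, accuracy = NA_real_,
                      precision_0 = NA_real_, recall_0 = NA_real_,
                      f1_0 = NA_real_, precision_1 = NA_real_,
                      recall_1 = NA_real_, f1_1 = NA_real_,
                      failed = FALSE, error = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch(run_pipeline(input, cfg), error = identity)
    if (inherits(res, "error")) {
      out$failed <- TRUE
      out$error <- conditionMessage(res)
    } else {
      rep <- res$report
      out$accuracy <- rep$accuracy[1L]
      out$precision_0 <- rep$precision[1L]
      out$recall_0 <- rep$recall[1L]
      out$f1_0 <- rep$f1[1L]
      out$precision_1 <- rep$precision[2L]
      out$recall_1 <- rep$recall[2L]
      out$f1_1 <- rep$f1[2L]
    }
    if (verbose) {
      message(sprintf("%-7s %-7s k=%d units=%-4d -> %s",
                      cell$backbone, cell$predictor, cell$k, cell$units,
                      if (out$failed) "FAILED" else
                        sprintf("accuracy %.4f", out$accuracy)))
    }
    out
  })
  do.call(rbind, rows)
}
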