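#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end workflow with defaults matching the
#' study protocol: 2/3 stratified train/test split, SMOTE balancing, NQE
#' trained with learning rate 0.01 / 1000 iterations / batch 10, 3 feature-map
#' repetitions, two-stage grid search with 5-fold cross-validated F1, and the
#' ten-metric comparative evaluation.
#'
#' @param input either a [labeled_dataset()], a file path readable by
#'   [read_expression_table()], or a named list of arguments for
#'   [generate_two_class()].
#' @param pc_counts integer vector of principal-component counts to sweep
#'   (each becomes the qubit count; must lie in 1..14).
#' @param classifiers subset of `c("svc", "qsvc", "nn", "qnn")`.
#' @param balance apply SMOTE to the training partition (default TRUE).
#' @param balance_order `"oversample_then_cv"` applies SMOTE once to the full
#'   training partition, so grid-search cross-validation runs on the balanced
#'   set (the published protocol order; validation folds then contain
#'   synthetic samples — see the methods vignette); `"none"` skips balancing.
#' @param nqe train a Neural Quantum Embedding before the quantum classifiers
#'   (default TRUE).
#' @param nqe_config an [nqe_train_config()].
#' @param reps feature-map repetitions (default 3).
#' @param folds cross-validation folds (default 5).
#' @param train_fraction train split fraction (default 2/3).
#' @param grid_svc,grid_qsvc hyperparameter grids (defaults from
#'   [default_svc_grid()]).
#' @param refine_grid run the stage-2 grid refinement (default TRUE).
#' @param nn_epochs,qnn_epochs training epochs for the NN / QNN classifiers.
#' @param seed master seed; every random draw in the run derives from it.
#' @param out_dir output directory (created if missing).
#' @param make_plots write PNG heatmaps / bar charts (default FALSE).
#' @return a `run_config` list.
#' @export
run_config <- function(input, pc_counts = 4, classifiers = c("svc", "qsvc"),
                       balance = TRUE, balance_order = c("oversample_then_cv", "none"),
                       nqe = TRUE, nqe_config = nqe_train_config(),
                       reps = 3, folds = 5, train_fraction = 2 / 3,
                       grid_svc = default_svc_grid("rbf"),
                       grid_qsvc = default_svc_grid("quantum"),
                       refine_grid = TRUE,
                       nn_epochs = 300, qnn_epochs = 15,
                       seed = 1, out_dir = tempfile("qembed_run_"),
                       make_plots = FALSE) {
  classifiers <- match.arg(classifiers, c("svc", "qsvc", "nn", "qnn"),
                           several.ok = TRUE)
  if (!length(classifiers)) stop("at least one classifier is required", call. = FALSE)
  if (any(pc_counts < 1 | pc_counts > 14))
    stop("pc_counts must lie in 1..14", call. = FALSE)
  structure(list(input = input, pc_counts = as.integer(pc_counts),
                 classifiers = classifiers, balance = balance,
                 balance_order = match.arg(balance_order),
                 nqe = nqe, nqe_config = nqe_config, reps = reps,
                 folds = folds, train_fraction = train_fraction,
                 grid_svc = grid_svc, grid_qsvc = grid_qsvc,
                 refine_grid = refine_grid,
                 nn_epochs = nn_epochs, qnn_epochs = qnn_epochs,
                 seed = as.integer(seed), out_dir = out_dir,
                 make_plots = make_plots),
            class = "run_config")
}

resolve_input <- function(input, seed) {
  if (inherits(input, "labeled_dataset")) return(input)
  if (is.character(input) && length(input) == 1L) return(read_expression_table(input))
  if (is.list(input)) {
    if (is.null(input$seed)) input$seed <- derive_seed(seed, 11L)
    return(do.call(generate_two_class, input))
  }
  stop("input must be a labeled_dataset, a file path, or a generator argument list",
       call. = FALSE)
}

#' Run the full classification pipeline
#'
#' For each requested principal-component count: stratified train/test split,
#' PCA fitted on the training partition and applied to the test partition,
#' optional SMOTE balancing of the training set, optional NQE training,
#' two-stage grid search per classifier, final fit, test-set evaluation with
#' the ten metrics, and pairwise comparative scores (svc vs qsvc, nn vs qnn).
#' All artifacts (metrics JSON, loss-history and kernel CSVs, markdown
#' comparison tables, a manifest recording configuration, seeds and artifact
#' paths) are written under `config$out_dir`. Identical configuration and
#' seed reproduce identical metric output.
#'
#' @param config a [run_config()].
#' @return (invisibly) the results list; `$manifest_path` points at the run
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "qembed",
                   version = as.character(utils::packageVersion("qembed")),
                   seed = config$seed,
                   pc_counts = config$pc_counts,
                   classifiers = config$classifiers,
                   balance = config$balance, nqe = config$nqe,
                   reps = config$reps, folds = config$folds,
                   train_fraction = config$train_fraction,
                   artifacts = list(), stages = list())
  manifest_path <- file.path(config$out_dir, "manifest.json")
  persist <- function() jsonlite::write_json(manifest, manifest_path,
                                             auto_unbox = TRUE, digits = NA,
                                             pretty = TRUE, force = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      persist()
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  ds <- stage("input", resolve_input(config$input, config$seed))
  results <- list()

  for (pc in config$pc_counts) {
    tag <- sprintf("pc%02d", pc)
    sp <- stage(paste0(tag, "_split"),
                split_dataset(ds, train_fraction = config$train_fraction,
                              seed = derive_seed(config$seed, 20L + pc)))
    pca <- stage(paste0(tag, "_pca"), fit_pca(sp$train, k = pc))
    train_pc <- pca$projected
    test_pc <- predict(pca$model, sp$test)

    if (config$balance && config$balance_order != "none")
      train_pc <- stage(paste0(tag, "_smote"),
                        smote_oversample(train_pc,
                                         seed = derive_seed(config$seed, 40L + pc)))

    embed_cfg <- embedding_config(pc, reps = config$reps)
    nqe_fit <- NULL
    if (config$nqe) {
      ncfg <- config$nqe_config
      ncfg$seed <- ncfg$seed %||% derive_seed(config$seed, 60L + pc)
      nqe_fit <- stage(paste0(tag, "_nqe"),
                       train_nqe(train_pc, config = ncfg, embed_config = embed_cfg))
      lh_path <- file.path(config$out_dir, sprintf("%s_nqe_loss.csv", tag))
      write_loss_history_csv(nqe_fit, lh_path)
      manifest$artifacts[[sprintf("%s_nqe_loss", tag)]] <- lh_path
      train_use <- labeled_dataset(nqe_forward(train_pc$features, nqe_fit),
                                   train_pc$labels, train_pc$sample_ids)
      test_use <- labeled_dataset(nqe_forward(test_pc$features, nqe_fit),
                                  test_pc$labels, test_pc$sample_ids)
    } else {
      train_use <- train_pc
      test_use <- test_pc
    }

    pc_res <- list(pc = pc, reports = list(), best_params = list())
    for (cl in config$classifiers) {
      pred <- stage(paste0(tag, "_", cl),
                    fit_and_predict_classifier(cl, train_use, test_use, embed_cfg,
                                               config, pc))
      pc_res$reports[[cl]] <- compute_metrics(confusion(test_use$labels, pred$labels))
      pc_res$best_params[[cl]] <- pred$params
      if (!is.null(pred$kernel)) {
        kp <- file.path(config$out_dir, sprintf("%s_%s_train_kernel.csv", tag, cl))
        write_kernel_csv(pred$kernel, kp)
        manifest$artifacts[[sprintf("%s_%s_train_kernel", tag, cl)]] <- kp
        if (config$make_plots) {
          pp <- file.path(config$out_dir, sprintf("%s_%s_train_kernel.png", tag, cl))
          grDevices::png(pp, width = 600, height = 600)
          plot(pred$kernel, main = sprintf("%s train kernel, %d PCs", cl, pc))
          grDevices::dev.off()
          manifest$artifacts[[sprintf("%s_%s_kernel_png", tag, cl)]] <- pp
        }
      }
    }

    pc_res$comparisons <- list()
    for (pair in list(c("svc", "qsvc"), c("nn", "qnn"))) {
      if (all(pair %in% names(pc_res$reports))) {
        cs <- comparative_score(pc_res$reports[[pair[1]]], pc_res$reports[[pair[2]]])
        pc_res$comparisons[[paste(pair, collapse = "_vs_")]] <- cs
        tab <- format_comparison_table(pc_res$reports[[pair[1]]],
                                       pc_res$reports[[pair[2]]],
                                       names_ab = toupper(pair))
        tp <- file.path(config$out_dir, sprintf("%s_%s.md", tag,
                                                paste(pair, collapse = "_vs_")))
        writeLines(tab, tp)
        manifest$artifacts[[sprintf("%s_%s_table", tag,
                                    paste(pair, collapse = "_vs_"))]] <- tp
        if (config$make_plots) {
          bp <- file.path(config$out_dir, sprintf("%s_%s.png", tag,
                                                  paste(pair, collapse = "_vs_")))
          grDevices::png(bp, width = 700, height = 450)
          plot_metric_comparison(pc_res$reports[[pair[1]]], pc_res$reports[[pair[2]]],
                                 names_ab = toupper(pair))
          grDevices::dev.off()
          manifest$artifacts[[sprintf("%s_%s_png", tag,
                                      paste(pair, collapse = "_vs_"))]] <- bp
        }
      }
    }

    mj <- file.path(config$out_dir, sprintf("%s_metrics.json", tag))
    jsonlite::write_json(
      list(pc = pc,
           metrics = lapply(pc_res$reports, function(r) r[metric_names()]),
           best_params = pc_res$best_params,
           comparisons = lapply(pc_res$comparisons, function(cs)
             list(wins_a = cs$wins_a, wins_b = cs$wins_b, ties = cs$ties))),
      mj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$artifacts[[sprintf("%s_metrics", tag)]] <- mj
    results[[tag]] <- pc_res
  }

  persist()
  results$manifest_path <- manifest_path
  invisible(results)
}

## dispatch: fit one classifier with its grid search, predict the test set
fit_and_predict_classifier <- function(cl, train, test, embed_cfg, config, pc) {
  seed_gs <- derive_seed(config$seed, 80L + pc)
  if (cl == "svc") {
    gs <- grid_search_two_stage(
      train,
      fit_fun = function(tr, p) {
        K <- rbf_kernel_matrix(tr, gamma = p$gamma)
        list(fit = fit_svc_precomputed(K, tr$labels, C = p$C), gamma = p$gamma)
      },
      predict_fun = function(m, tr, te)
        predict(m$fit, rbf_kernel_matrix(te, tr, gamma = m$gamma)),
      grid = config$grid_svc, folds = config$folds, seed = seed_gs,
      refine = config$refine_grid)
    Ktr <- rbf_kernel_matrix(train, gamma = gs$best$gamma)
    fit <- fit_svc_precomputed(Ktr, train$labels, C = gs$best$C)
    pred <- predict(fit, rbf_kernel_matrix(test, train, gamma = gs$best$gamma))
    list(labels = pred, params = gs$best, kernel = Ktr)
  } else if (cl == "qsvc") {
    Ktr_full <- quantum_kernel_matrix(train, embed_config = embed_cfg)
    gs <- grid_search_two_stage(
      train,
      fit_fun = function(tr, p) {
        idx <- match(tr$sample_ids, train$sample_ids)
        K <- kernel_matrix(Ktr_full$values[idx, idx, drop = FALSE], "train")
        list(fit = fit_svc_precomputed(K, tr$labels, C = p$C), idx = idx)
      },
      predict_fun = function(m, tr, te) {
        idx_te <- match(te$sample_ids, train$sample_ids)
        predict(m$fit, Ktr_full$values[idx_te, m$idx, drop = FALSE])
      },
      grid = config$grid_qsvc, folds = config$folds, seed = seed_gs,
      refine = config$refine_grid)
    fit <- fit_svc_precomputed(Ktr_full, train$labels, C = gs$best$C)
    pred <- predict(fit, quantum_kernel_matrix(test, train, embed_config = embed_cfg))
    list(labels = pred, params = gs$best, kernel = Ktr_full)
  } else if (cl == "nn") {
    fit <- fit_nn(train, epochs = config$nn_epochs,
                  seed = derive_seed(config$seed, 90L + pc))
    list(labels = predict(fit, test), params = list(epochs = config$nn_epochs),
         kernel = NULL)
  } else {
    fit <- fit_qnn(train, embed_config = embed_cfg, epochs = config$qnn_epochs,
                   seed = derive_seed(config$seed, 95L + pc))
    list(labels = predict(fit, test, embed_cfg),
         params = list(epochs = config$qnn_epochs), kernel = NULL)
  }
}
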