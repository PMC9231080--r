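#' Scaled-down end-to-end ablation run
#'
#' The package's standard desk-scale experiment: simulate a measurement
#' campaign on the (optionally separable) 20-class library, extract
#' optical constants for every record, assemble datasets, and train the
#' classifier in the requested input modes - plus the plain-CNN (no
#' attention) variant for the hybrid input - then evaluate on the
#' noisier averaging groups.  One campaign and one extraction are shared
#' by all trained variants.
#'
#' The default conditions are a reduced version of the full tablet
#' protocol: 15 s continuous acquisition per tablet (45 avg-100 records
#' per class; 720 training and 180 validation records), test groups
#' capped at 4 records per tablet (400 records each), 30 + 10 training
#' epochs at learning rates 1e-2 / 1e-3.
#'
#' @param seed Seed controlling simulation, splits, initialization and
#'   shuffling.
#' @param modes Input modes to train (`"hybrid"`, `"absorption"`,
#'   `"refractive"`).
#' @param plain_cnn Also train the no-attention variant on the first
#'   mode.
#' @param separable Use the grid-separable material library.
#' @param duration_s,n_tablets,test_cap Campaign scale.
#' @param avg_counts Averaging levels (first = training group).
#' @param tcfg A [training_config()]; the default is the reduced
#'   schedule above.
#' @param instr A [instrument_spec()].
#' @param keep_models Return the trained models (memory permitting).
#' @param verbose Print per-epoch training progress.
#' @return List with `results` (one entry per trained variant: mode,
#'   use_eca, final validation accuracy, and a `thz_eval` per test
#'   group), `class_names`, and the run conditions.
#' @export
run_ablation <- function(seed = 1,
                         modes = c("hybrid", "absorption", "refractive"),
                         plain_cnn = TRUE, separable = TRUE,
                         duration_s = 15, n_tablets = 5, test_cap = 4,
                         avg_counts = c(100, 20, 10),
                         tcfg = training_config(epochs = 30,
                                                fine_tune_epochs = 10,
                                                lr = 1e-2,
                                                fine_tune_lr = 1e-3),
                         instr = instrument_spec(),
                         keep_models = FALSE, verbose = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  lib <- build_material_library(separable = separable)
  camp <- acquire_dataset(lib, instr, n_tablets = n_tablets,
                          duration_s = duration_s, avg_counts = avg_counts,
                          seed = seed,
                          max_records_per_tablet = c(Inf, rep(test_cap,
                                                    length(avg_counts) - 1)))
  feats <- extract_feature_records(camp)
  test_tags <- paste0("test", avg_counts[-1])
  results <- list()
  for (mode in modes) {
    variants <- if (mode == modes[1] && plain_cnn) c(TRUE, FALSE) else TRUE
    ds <- assemble_datasets(feats, mode, seed = seed)
    for (use_eca in variants) {
      cfg <- network_config(
        input_channels = if (mode == "hybrid") 2 else 1,
        n_classes = length(lib), use_eca = use_eca)
      tr <- nn_train(build_network(cfg, seed = seed), ds$train, ds$val,
                     tcfg, seed = seed, verbose = verbose)
      evals <- lapply(test_tags, function(tag)
        evaluate_model(tr$model, ds[[tag]], class_names = ds$class_names))
      names(evals) <- test_tags
      entry <- list(mode = mode, use_eca = use_eca,
                    val_accuracy = utils::tail(tr$history$val_acc, 1),
                    evals = evals, history = tr$history)
      if (keep_models) entry$model <- tr$model
      results[[paste0(mode, if (!use_eca) "_plain")]] <- entry
    }
  }
  list(results = results, class_names = feats$class_names,
       conditions = list(seed = seed, separable = separable,
                         duration_s = duration_s, n_tablets = n_tablets,
                         test_cap = test_cap, avg_counts = avg_counts,
                         noise_sigma_single = instr$noise_sigma_single,
                         epochs = tcfg$epochs,
                         fine_tune_epochs = tcfg$fine_tune_epochs))
}

#' End-to-end demonstration run
#'
#' Runs the scaled-down pipeline of [run_ablation()] and prints a
#' report: overall accuracy and per-class precision of the
#' ECA/hybrid model on each noisy test group, plus the ablation summary
#' (input modes and plain CNN).  Optionally writes the report (JSON),
#' the confusion matrices and a reproducibility log to a directory.
#'
#' @param seed Run seed.
#' @param outdir Output directory, or `NULL` for a print-only run.
#' @param ... Passed to [run_ablation()].
#' @return Invisibly, the [run_ablation()] result.
#' @export
run_demo <- function(seed = 1, outdir = NULL, ...) {
  ab <- run_ablation(seed = seed, ...)
  main <- ab$results[[1]]
  cat("== ECA network,", main$mode, "input ==\n")
  for (tag in names(main$evals)) {
    ev <- main$evals[[tag]]
    cat(sprintf("%s: accuracy %.4f (%d items)\n", tag, ev$accuracy,
                ev$n_items))
  }
  cat("\nPer-class precision (", names(main$evals)[1], "):\n", sep = "")
  print(round(main$evals[[1]]$per_class, 3))
  cat("\n== Ablation summary ==\n")
  for (nm in names(ab$results)) {
    r <- ab$results[[nm]]
    accs <- vapply(r$evals, `[[`, numeric(1), "accuracy")
    cat(sprintf("%-18s %s\n",
                paste0(r$mode, if (!r$use_eca) " (plain CNN)"),
                paste(sprintf("%s=%.4f", names(accs), accs),
                      collapse = "  ")))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    report <- list(
      package_version = as.character(utils::packageVersion("thzamino")),
      conditions = ab$conditions,
      models = lapply(ab$results, function(r) list(
        mode = r$mode, use_eca = r$use_eca,
        val_accuracy = r$val_accuracy,
        test_accuracy = lapply(r$evals, `[[`, "accuracy"),
        per_class = lapply(r$evals, function(e) as.list(e$per_class)))))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (tag in names(main$evals))
      write_confusion(main$evals[[tag]]$confusion,
                      file.path(outdir, paste0("confusion_", tag, ".tsv")))
    writeLines(c(paste("thzamino", utils::packageVersion("thzamino")),
                 paste("seed", seed),
                 paste(names(ab$conditions),
                       vapply(ab$conditions, paste, character(1),
                              collapse = ","), sep = "=")),
               file.path(outdir, "run.log"))
  }
  invisible(ab)
}
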