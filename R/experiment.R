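#' Default experiment configuration
#'
#' Every pipeline knob in one place; [run_experiment()] merges user
#' values (an R list or a YAML file) over these defaults. `data$source`
#' is `"synthetic"` (seeded generator, `profile` either `"cric"` for the
#' reference class frequencies or a named count vector) or `"marks"`
#' (`marks` CSV path plus `image_dir`).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    data = list(source = "synthetic", profile = "cric",
                image_size = c(255, 344), marks = NULL, image_dir = NULL),
    scheme = "two",
    mode = "general",            # balancing plan: "general" or "paper"
    m = 90,
    input_size = 32,
    backbone = "tiny",
    models = 3,                  # number of ensemble candidates
    epochs = 30, batch_size = 32, lr = 1e-3, patience = 5,
    dropout = 0.2,
    k = 3,                       # ensemble size
    select_on = "validation",    # or "test" to rank members as published
    test_fraction = 0.2, val_fraction = 0.2,
    repetitions = 1,
    seed = 1,
    out_dir = NULL
  )
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return Config list merged over the defaults.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Run the full classification experiment
#'
#' Orchestrates the pipeline, repeated `repetitions` times as a
#' shuffle-split cross-validation: per repetition -- stratified test
#' holdout, balancing plan and expansion, validation re-split, crop/
#' transform/resize preparation, training of the candidate models,
#' per-model test metrics, recall-ranked member selection, majority vote,
#' and ensemble metrics. Metrics are averaged over repetitions. Every
#' stage is seeded from `config$seed` so a run is replayable from its
#' configuration alone.
#'
#' @param config List (merged over [default_config()]) or a YAML path.
#' @param dataset Optional pre-built [cyto_dataset()]; overrides
#'   `config$data`.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `cyto_experiment`: per-repetition results
#'   (`reports`, `ensemble_report`, `ensemble_spec`, `plan`), a `summary`
#'   data.frame with one row per repetition plus mean and sd rows of the
#'   five ensemble macro metrics, and the resolved `config`.
#' @export
run_experiment <- function(config = list(), dataset = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  scheme <- class_scheme(cfg$scheme)

  if (is.null(dataset)) {
    if (identical(cfg$data$source, "synthetic")) {
      profile <- cfg$data$profile
      if (identical(profile, "cric")) profile <- cric_counts()
      say("generating synthetic dataset (%d marks)...", sum(profile))
      dataset <- generate_synthetic(profile, image_size = cfg$data$image_size,
                                    seed = sub_seed(cfg$seed, 999))
    } else {
      dataset <- read_marks(cfg$data$marks, image_dir = cfg$data$image_dir)
    }
  }
  say("dataset: %s", paste(sprintf("%s:%d", names(dataset_counts(dataset)),
                                   dataset_counts(dataset)), collapse = " "))
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  reps <- vector("list", cfg$repetitions)
  for (rep_i in seq_len(cfg$repetitions)) {
    rep_seed <- sub_seed(cfg$seed, rep_i)
    say("repetition %d/%d (seed %d)", rep_i, cfg$repetitions, rep_seed)
    reps[[rep_i]] <- run_repetition(dataset, scheme, cfg, rep_seed, rep_i, say)
  }

  metric_cols <- c("precision", "recall", "f1", "accuracy", "specificity")
  ens <- t(vapply(reps, function(r) r$ensemble_report$macro,
                  numeric(length(metric_cols))))
  summary_df <- data.frame(repetition = as.character(seq_len(cfg$repetitions)),
                           ens, check.names = FALSE)
  summary_df <- rbind(summary_df,
                      data.frame(repetition = "mean", t(colMeans(ens)),
                                 check.names = FALSE),
                      data.frame(repetition = "sd",
                                 t(apply(ens, 2, stats::sd)),
                                 check.names = FALSE))
  rownames(summary_df) <- NULL
  structure(list(config = cfg, scheme = scheme, repetitions = reps,
                 summary = summary_df),
            class = "cyto_experiment")
}

run_repetition <- function(dataset, scheme, cfg, rep_seed, rep_i, say) {
  cnt0 <- dataset_counts(dataset)
  sp <- split_test(dataset, cfg$test_fraction, seed = rep_seed,
                   labels = names(cnt0)[cnt0 > 0])
  say("  test split: pool %d / test %d", nrow(sp$pool$marks),
      nrow(sp$test$marks))
  plan <- plan_balance(dataset_counts(sp$pool), scheme, mode = cfg$mode)
  balanced <- expand_pool(sp$pool, plan, seed = sub_seed(rep_seed, 2))
  say("  balanced pool: %s",
      paste(sprintf("%s:%d", names(planned_sizes(plan)), planned_sizes(plan)),
            collapse = " "))
  tv <- split_validation(balanced, cfg$val_fraction,
                         seed = sub_seed(rep_seed, 3),
                         group_by_source = isTRUE(cfg$group_by_source))
  say("  train %d / validation %d", nrow(tv$train$marks),
      nrow(tv$validation$marks))

  prep <- function(ds) prepare_inputs(ds, m = cfg$m,
                                      input_size = cfg$input_size,
                                      seed = sub_seed(rep_seed, 4),
                                      scheme = scheme)
  tr <- prep(tv$train); va <- prep(tv$validation); te <- prep(sp$test)

  model_names <- character(cfg$models)
  val_pred <- list(); test_pred <- list(); reports <- list()
  val_recall <- numeric(cfg$models)
  for (j in seq_len(cfg$models)) {
    mdl <- build_model(cfg$backbone, classes = scheme$target_order,
                       dropout_rate = cfg$dropout,
                       input_size = cfg$input_size,
                       seed = sub_seed(rep_seed, 50 + j))
    mdl <- train_model(mdl, tr$x, tr$y,
                       validation = list(x = va$x, y = va$y),
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       lr = cfg$lr, patience = cfg$patience,
                       seed = sub_seed(rep_seed, 70 + j))
    model_names[j] <- mdl$name
    val_pred[[mdl$name]] <- predict(mdl, va$x, mark_id = va$mark_id)
    test_pred[[mdl$name]] <- predict(mdl, te$x, mark_id = te$mark_id)
    reports[[mdl$name]] <- classification_report(te$y,
                                                 test_pred[[mdl$name]]$predicted,
                                                 scheme, model_name = mdl$name)
    val_recall[j] <- classification_report(va$y,
                                           val_pred[[mdl$name]]$predicted,
                                           scheme,
                                           model_name = mdl$name)$macro[["recall"]]
    say("  model %s: val recall %.3f, test recall %.3f", mdl$name,
        val_recall[j], reports[[mdl$name]]$macro[["recall"]])
  }
  names(val_recall) <- model_names

  sel_recalls <- if (identical(cfg$select_on, "test"))
    vapply(reports, function(r) r$macro[["recall"]], numeric(1))
  else val_recall
  spec <- select_members(sel_recalls, k = cfg$k,
                         seed = sub_seed(rep_seed, 90))
  ens_pred <- ensemble_vote(spec, test_pred)
  ens_report <- classification_report(te$y, ens_pred$predicted, scheme,
                                      model_name = "ensemble")
  say("  ensemble: test recall %.3f (members %s)",
      ens_report$macro[["recall"]], paste(spec$members, collapse = ", "))

  if (!is.null(cfg$out_dir)) {
    rd <- file.path(cfg$out_dir, sprintf("rep%02d", rep_i))
    dir.create(rd, recursive = TRUE, showWarnings = FALSE)
    assignments <- c(stats::setNames(rep("train", nrow(tv$train$marks)),
                                     tv$train$marks$mark_id),
                     stats::setNames(rep("validation",
                                         nrow(tv$validation$marks)),
                                     tv$validation$marks$mark_id),
                     stats::setNames(rep("test", nrow(sp$test$marks)),
                                     sp$test$marks$mark_id))
    write_manifest(balanced_with_test(balanced, sp$test), assignments,
                   file.path(rd, "manifest.csv"), scheme = scheme)
    write_plan(plan, file.path(rd, "plan.json"))
    for (nm in names(test_pred))
      write_predictions(test_pred[[nm]],
                        file.path(rd, paste0("predictions_", nm, ".csv")))
    write_predictions(ens_pred, file.path(rd, "predictions_ensemble.csv"))
    for (nm in names(reports))
      write_report(reports[[nm]], file.path(rd, paste0("report_", nm, ".json")),
                   extra = list(seed = rep_seed, scheme = scheme$name))
    write_report(ens_report, file.path(rd, "report_ensemble.json"),
                 extra = list(seed = rep_seed, scheme = scheme$name,
                              members = spec$members,
                              tiebreaker = spec$tiebreaker))
  }

  list(seed = rep_seed, plan = plan, reports = reports,
       val_recall = val_recall, ensemble_spec = spec,
       ensemble_pred = ens_pred, ensemble_report = ens_report)
}

# Merge the balanced pool and the untouched test set into one dataset for
# manifest writing.
balanced_with_test <- function(balanced, test) {
  cyto_dataset(rbind(balanced$marks, test$marks), images = balanced$images,
               image_dir = balanced$image_dir,
               image_size = balanced$image_size)
}

#' @export
print.cyto_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("<cyto_experiment> scheme=%s mode=%s models=%d reps=%d\n",
              x$config$scheme, x$config$mode, x$config$models,
              x$config$repetitions))
  df <- x$summary
  df[, -1] <- round(df[, -1], digits)
  cat("ensemble macro metrics per repetition:\n")
  print(df, row.names = FALSE)
  invisible(x)
}
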