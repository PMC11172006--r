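# Threshold-aware accumulative fine-tuning engine: single trials,
# multi-trial experiments with goal assessment and minimum-proportion
# selection, the final-model protocol, and the local-holdout drift check.

#' Predefined performance goals
#'
#' The experiment succeeds when the mean trial-wise performance at some
#' training proportion meets both goals (assessed as >=, stable to exact
#' ties) on the chosen validation set. The defaults are the lower bounds of
#' a source-domain cross-validation interval: sensitivity 0.901 and
#' specificity 0.793, assessed on the variable-sized validation set.
#'
#' @param min_sensitivity,min_specificity goal values in [0,1].
#' @param assessed_on "variable" or "fixed".
#' @export
performance_goals <- function(min_sensitivity = 0.901,
                              min_specificity = 0.793,
                              assessed_on = c("variable", "fixed")) {
  assessed_on <- match.arg(assessed_on)
  stopifnot(min_sensitivity >= 0, min_sensitivity <= 1,
            min_specificity >= 0, min_specificity <= 1)
  structure(list(min_sensitivity = min_sensitivity,
                 min_specificity = min_specificity,
                 assessed_on = assessed_on),
            class = "performance_goals")
}

# Evaluate a model on the main M-mode records of the given clip set.
eval_on_clips <- function(model, contract, main, features, clip_ids, threshold) {
  sel <- main$clip_id %in% clip_ids
  ids <- main$mmode_id[sel]
  scores <- contract$predict_scores(model, features[ids, , drop = FALSE])
  evaluate(scores, main$label[sel], threshold = threshold)
}

# One fine-tuning step shared by run_trial() and finalize_model():
# inner 80/20 patient-wise split, pool upsampling, warm-started fine-tune.
fine_tune_on <- function(train_main, pool, features, base_model, contract,
                         config, target_positive_fraction, seed) {
  if (length(unique(train_main$label)) < 2) {
    stop_taaft("training fold union is missing a class; trial aborted",
               class = "taaft_class_error")
  }
  # the 80/20 split can strand every positive patient in the secondary set;
  # redraw deterministically until the fit set keeps both classes
  fit_main <- NULL
  for (try in 0:49) {
    split <- inner_split(train_main, fraction = 0.8, seed = seed + 100000L * try)
    fit_main <- train_main[train_main$clip_id %in% split$fit, , drop = FALSE]
    if (length(unique(fit_main$label)) == 2) break
  }
  if (length(unique(fit_main$label)) < 2) {
    stop_taaft("no patient-wise 80/20 split keeps both classes in the fit set",
               class = "taaft_class_error")
  }
  cols <- c("mmode_id", "clip_id", "label")
  eligible_pool <- pool[pool$clip_id %in% split$fit, , drop = FALSE]
  aug <- upsample_positives(fit_main[, cols], eligible_pool[, cols],
                            target_positive_fraction, seed = seed + 1L)
  sec_main <- train_main[train_main$clip_id %in% split$secondary, , drop = FALSE]
  val <- if (nrow(sec_main) > 0) {
    list(x = structure(features[sec_main$mmode_id, , drop = FALSE],
                       class = c("mmode_features", "matrix", "array")),
         y = sec_main$label)
  } else {
    NULL
  }
  x <- structure(features[aug$mmode_id, , drop = FALSE],
                 class = c("mmode_features", "matrix", "array"))
  model <- contract$fine_tune(base_model, x, aug$label, val, config)
  list(model = model, fit_clips = split$fit, secondary_clips = split$secondary,
       fit_mmode_ids = aug$mmode_id,
       n_upsampled = nrow(aug) - nrow(fit_main))
}

#' Run a single accumulative fine-tuning trial
#'
#' Builds a patient-wise 2k-fold split and the accumulative schedule, then:
#' iteration 0 evaluates the base model on both validation sets without any
#' training; iterations 1..k fine-tune the base model (always from the base,
#' never from the previous iteration's model) on the accumulated folds —
#' after an inner patient-wise 80/20 split and positive-class upsampling
#' from the sequestered pool — and evaluate on both validation sets.
#'
#' @param data an `mmode_dataset`.
#' @param base_model the pretrained state to fine-tune from.
#' @param k number of increments (2k folds).
#' @param seed trial seed (folds, inner splits and upsampling derive from it).
#' @param config a [classifier_config()].
#' @param target_positive_fraction upsampling target class distribution.
#' @param features optional precomputed [mmode_features()] for all records.
#' @return a `taaft_trial`: list(seed, k, fold_assignment, fold_summary,
#'   iterations); each iteration holds p_train, the model, metrics on both
#'   validation sets and the exact clip/image composition used.
#' @export
run_trial <- function(data, base_model, k = 3, seed = 1,
                      config = classifier_config(),
                      target_positive_fraction = 0.26,
                      features = NULL) {
  stopifnot(inherits(data, "mmode_dataset"))
  contract <- get_classifier(config$classifier)
  main <- data$records[data$records$is_main, , drop = FALSE]
  pool <- data$records[!data$records$is_main, , drop = FALSE]
  if (is.null(features)) {
    features <- mmode_features(data$images, n_bins = config$n_bins)
  }
  fa <- split_patientwise(main, k, seed)
  sched <- make_schedule(fa)
  iterations <- vector("list", k + 1)
  for (entry in sched) {
    i <- entry$iteration
    if (i == 0) {
      model <- base_model
      step <- list(fit_clips = character(0), secondary_clips = character(0),
                   fit_mmode_ids = character(0), n_upsampled = 0L)
    } else {
      train_main <- main[main$clip_id %in% entry$train_clips, , drop = FALSE]
      step <- fine_tune_on(train_main, pool, features, base_model, contract,
                           config, target_positive_fraction,
                           seed = seed + 31L * i)
      model <- step$model
    }
    iterations[[i + 1]] <- list(
      iteration = i, p_train = entry$p_train, model = model,
      metrics_variable = eval_on_clips(model, contract, main, features,
                                       entry$variable_clips, config$threshold),
      metrics_fixed = eval_on_clips(model, contract, main, features,
                                    entry$fixed_clips, config$threshold),
      train_clips = entry$train_clips,
      variable_clips = entry$variable_clips,
      fixed_clips = entry$fixed_clips,
      fit_clips = step$fit_clips,
      secondary_clips = step$secondary_clips,
      fit_mmode_ids = step$fit_mmode_ids,
      n_upsampled = step$n_upsampled
    )
  }
  structure(list(seed = seed, k = k, fold_assignment = fa,
                 fold_summary = summarize_folds(fa, main),
                 iterations = iterations),
            class = "taaft_trial")
}

METRIC_NAMES <- c("sensitivity", "specificity", "auc", "accuracy")

summarize_trials <- function(trials, k) {
  rows <- list()
  for (set in c("variable", "fixed")) {
    field <- paste0("metrics_", set)
    for (i in 0:k) {
      for (metric in METRIC_NAMES) {
        vals <- vapply(trials, function(tr) {
          tr$iterations[[i + 1]][[field]][[metric]]
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          p_train = i / (2 * k), iteration = i, set = set, metric = metric,
          mean = mean(vals), sd = stats::sd(vals), n = length(vals),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Run a multi-trial fine-tuning experiment
#'
#' Runs `n_trials` trials, each with a distinct derived seed (hence
#' different patient-wise folds), aggregates per-proportion trial-wise means
#' and standard deviations (n-1 denominator) of each metric on each
#' validation set, assesses the performance goals, and selects the smallest
#' training proportion whose mean metrics meet them.
#'
#' @inheritParams run_trial
#' @param n_trials number of trials (default 5).
#' @param goals a [performance_goals()].
#' @param seed master seed; trial seeds are `seed + 1000 * trial`.
#' @return a `taaft_experiment`: list(trials, summary, goals, success,
#'   selected_proportion, incomplete, errors, k, n_trials, seed, config).
#' @export
run_experiment <- function(data, base_model, k = 3, n_trials = 5,
                           goals = performance_goals(), seed = 1,
                           config = classifier_config(),
                           target_positive_fraction = 0.26) {
  features <- mmode_features(data$images, n_bins = config$n_bins)
  trials <- list(); errors <- character(0)
  for (t in seq_len(n_trials)) {
    trial_seed <- as.integer(seed + 1000 * t)
    res <- tryCatch(
      run_trial(data, base_model, k = k, seed = trial_seed, config = config,
                target_positive_fraction = target_positive_fraction,
                features = features),
      taaft_class_error = function(e) e
    )
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("trial %d (seed %d): %s", t, trial_seed,
                                  conditionMessage(res)))
    } else {
      trials[[length(trials) + 1]] <- res
    }
  }
  incomplete <- length(errors) > 0
  summary_df <- if (length(trials) > 0) summarize_trials(trials, k) else NULL
  success <- FALSE; selected <- NA_real_
  if (!is.null(summary_df)) {
    sens <- summary_df[summary_df$set == goals$assessed_on &
                         summary_df$metric == "sensitivity", ]
    spec <- summary_df[summary_df$set == goals$assessed_on &
                         summary_df$metric == "specificity", ]
    ok <- sens$p_train > 0 &
      sens$mean >= goals$min_sensitivity &
      spec$mean[match(sens$p_train, spec$p_train)] >= goals$min_specificity
    if (any(ok)) {
      success <- TRUE
      selected <- min(sens$p_train[ok])
    }
  }
  structure(list(trials = trials, summary = summary_df, goals = goals,
                 success = success, selected_proportion = selected,
                 incomplete = incomplete, errors = errors,
                 k = k, n_trials = n_trials, seed = seed, config = config),
            class = "taaft_experiment")
}

#' Fine-tune the final model at the selected proportion
#'
#' Builds a new patient-wise fold assignment with a fresh seed, fine-tunes
#' the base model on the first `2k * proportion` folds (with the same inner
#' split and upsampling protocol as a trial iteration), and evaluates on the
#' remaining folds — that split's variable-sized validation set.
#'
#' @inheritParams run_trial
#' @param proportion training proportion in {1/(2k), ..., 1/2}.
#' @return list(model, metrics, proportion, fold_assignment, train_clips,
#'   validation_clips).
#' @export
finalize_model <- function(data, base_model, proportion, seed, k = 3,
                           config = classifier_config(),
                           target_positive_fraction = 0.26) {
  m <- 2 * k * proportion
  if (abs(m - round(m)) > 1e-9 || round(m) < 1 || round(m) > k) {
    stop_taaft("proportion must be one of i/(2k) for i in 1..k",
               class = "taaft_config_error")
  }
  m <- as.integer(round(m))
  contract <- get_classifier(config$classifier)
  main <- data$records[data$records$is_main, , drop = FALSE]
  pool <- data$records[!data$records$is_main, , drop = FALSE]
  features <- mmode_features(data$images, n_bins = config$n_bins)
  fa <- split_patientwise(main, k, seed)
  train_clips <- unlist(fa$folds[seq_len(m)], use.names = FALSE)
  val_clips <- unlist(fa$folds[(m + 1):(2 * k)], use.names = FALSE)
  train_main <- main[main$clip_id %in% train_clips, , drop = FALSE]
  step <- fine_tune_on(train_main, pool, features, base_model, contract,
                       config, target_positive_fraction, seed = seed + 7L)
  metrics <- eval_on_clips(step$model, contract, main, features, val_clips,
                           config$threshold)
  list(model = step$model, metrics = metrics, proportion = proportion,
       fold_assignment = fa, train_clips = train_clips,
       validation_clips = val_clips)
}

#' Check for source-domain drift after fine-tuning
#'
#' Evaluates the fine-tuned and base models on the original local holdout
#' set and reports both metric sets side by side with deltas
#' (final - base). Fine-tuning on external data should not degrade
#' source-domain performance.
#'
#' @param final_model,base_model fitted states.
#' @param holdout an `mmode_dataset` patient-disjoint from all fine-tuning
#'   data.
#' @param train_patients optional character vector of fine-tuning patient
#'   ids; when given, any overlap with holdout patients is an error.
#' @param config a [classifier_config()] (threshold, classifier name).
#' @return list(table = data.frame of per-model metrics, deltas = named
#'   numeric vector).
#' @export
drift_check <- function(final_model, base_model, holdout,
                        train_patients = NULL,
                        config = classifier_config()) {
  stopifnot(inherits(holdout, "mmode_dataset"))
  main <- holdout$records[holdout$records$is_main, , drop = FALSE]
  if (nrow(main) == 0) {
    stop_taaft("holdout set is empty", class = "taaft_validation_error")
  }
  if (!is.null(train_patients)) {
    overlap <- intersect(train_patients, main$patient_id)
    if (length(overlap) > 0) {
      stop_taaft("holdout overlaps fine-tuning patients: ",
                 paste(utils::head(overlap, 5), collapse = ", "),
                 class = "taaft_validation_error")
    }
  }
  contract <- get_classifier(config$classifier)
  features <- mmode_features(holdout$images[main$mmode_id],
                             n_bins = config$n_bins)
  one <- function(model) {
    eval_on_clips(model, contract, main, features, main$clip_id,
                  config$threshold)
  }
  m_final <- one(final_model); m_base <- one(base_model)
  table <- data.frame(
    model = c("final", "base"),
    sensitivity = c(m_final$sensitivity, m_base$sensitivity),
    specificity = c(m_final$specificity, m_base$specificity),
    auc = c(m_final$auc, m_base$auc),
    accuracy = c(m_final$accuracy, m_base$accuracy),
    stringsAsFactors = FALSE
  )
  deltas <- c(sensitivity = m_final$sensitivity - m_base$sensitivity,
              specificity = m_final$specificity - m_base$specificity,
              auc = m_final$auc - m_base$auc,
              accuracy = m_final$accuracy - m_base$accuracy)
  list(table = table, deltas = deltas)
}

#' @export
print.taaft_experiment <- function(x, ...) {
  cat(sprintf("<taaft_experiment> k=%d, %d/%d trials complete, seed=%d\n",
              x$k, length(x$trials), x$n_trials, x$seed))
  cat(sprintf("  goals: sens >= %.3f, spec >= %.3f on the %s-sized set\n",
              x$goals$min_sensitivity, x$goals$min_specificity,
              x$goals$assessed_on))
  if (x$success) {
    cat(sprintf("  SUCCESS: smallest qualifying proportion p_train = %s\n",
                format(x$selected_proportion)))
  } else {
    cat("  goals not met at any training proportion\n")
  }
  if (!is.null(x$summary)) {
    sub <- x$summary[x$summary$set == x$goals$assessed_on &
                       x$summary$metric %in% c("sensitivity", "specificity"), ]
    print(sub, row.names = FALSE)
  }
  invisible(x)
}
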