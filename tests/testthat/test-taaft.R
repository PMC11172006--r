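# Shared small experiment fixture: one external-style dataset and a base
# model trained on a separate local-style dataset.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      local_ds <- simulate_mmode_dataset(
        lus_config(n_patients = 16, clips_per_patient = c(2, 3),
                   positive_fraction = 0.26, frame_shape = c(48, 48),
                   fps = 10, institutions = default_institutions("local"),
                   seed = 501), target_size = 64)
      lmain <- local_ds$records[local_ds$records$is_main, ]
      m0 <- baseline_fit(local_ds$images[lmain$mmode_id], lmain$label)
      ext <- simulate_mmode_dataset(
        lus_config(n_patients = 24, clips_per_patient = c(2, 3),
                   positive_fraction = 0.35, frame_shape = c(48, 48),
                   fps = 10, seed = 502), target_size = 64)
      cache <<- list(local = local_ds, m0 = m0, ext = ext)
    }
    cache
  }
})

test_that("run_trial produces k+1 iterations with the documented structure", {
  w <- small_world()
  tr <- run_trial(w$ext, w$m0, k = 3, seed = 61)
  expect_s3_class(tr, "taaft_trial")
  expect_length(tr$iterations, 4)
  expect_equal(vapply(tr$iterations, `[[`, numeric(1), "p_train"),
               c(0, 1 / 6, 1 / 3, 1 / 2))
  # iteration 0 evaluates the base model without training
  it0 <- tr$iterations[[1]]
  expect_length(it0$train_clips, 0)
  main <- w$ext$records[w$ext$records$is_main, ]
  direct <- evaluate(predict_scores(w$m0, w$ext$images[main$mmode_id]),
                     main$label)
  expect_equal(it0$metrics_variable$sensitivity, direct$sensitivity)
  expect_equal(it0$metrics_variable$auc, direct$auc)
  # at the final iteration both validation sets coincide
  last <- tr$iterations[[4]]
  expect_setequal(last$variable_clips, last$fixed_clips)
  expect_equal(last$metrics_variable$confusion, last$metrics_fixed$confusion)
  # every iteration model is fine-tuned from the base, never chained
  expect_true(all(vapply(tr$iterations[-1],
                         function(it) isTRUE(it$model$fine_tuned), logical(1))))
})

test_that("trials are leakage-free at every iteration", {
  w <- small_world()
  tr <- run_trial(w$ext, w$m0, k = 3, seed = 62)
  recs <- w$ext$records
  patient_of <- function(clip_ids) {
    unique(recs$patient_id[recs$clip_id %in% clip_ids])
  }
  for (it in tr$iterations[-1]) {
    fit_pat <- unique(recs$patient_id[recs$mmode_id %in% it$fit_mmode_ids])
    expect_length(intersect(fit_pat, patient_of(it$variable_clips)), 0)
    expect_length(intersect(fit_pat, patient_of(it$fixed_clips)), 0)
    expect_length(intersect(fit_pat, patient_of(it$secondary_clips)), 0)
    # upsampled pool images come only from fit-set clips
    pool_ids <- setdiff(it$fit_mmode_ids,
                        recs$mmode_id[recs$is_main])
    expect_true(all(recs$clip_id[match(pool_ids, recs$mmode_id)] %in%
                      it$fit_clips))
  }
})

test_that("run_experiment: model count, derived seeds, aggregation, reproducibility", {
  w <- small_world()
  exp1 <- run_experiment(w$ext, w$m0, k = 3, n_trials = 3, seed = 71)
  expect_length(exp1$trials, 3)
  # 3 trials x 3 proportions = 9 fine-tuned models
  models <- unlist(lapply(exp1$trials, function(tr) {
    lapply(tr$iterations[-1], `[[`, "model")
  }), recursive = FALSE)
  expect_length(models, 9)
  # distinct trial seeds -> distinct folds
  expect_false(identical(exp1$trials[[1]]$fold_assignment$patient_fold,
                         exp1$trials[[2]]$fold_assignment$patient_fold))
  # summary means computed over exactly n_trials values
  expect_true(all(exp1$summary$n == 3))
  # mean/sd recomputed by hand for one cell
  sens_half <- vapply(exp1$trials, function(tr) {
    tr$iterations[[4]]$metrics_variable$sensitivity
  }, numeric(1))
  cell <- exp1$summary[exp1$summary$set == "variable" &
                         exp1$summary$iteration == 3 &
                         exp1$summary$metric == "sensitivity", ]
  expect_equal(cell$mean, mean(sens_half))
  expect_equal(cell$sd, sd(sens_half))
  # bit-reproducibility under the master seed
  exp2 <- run_experiment(w$ext, w$m0, k = 3, n_trials = 3, seed = 71)
  expect_identical(exp1$summary, exp2$summary)
  expect_identical(exp1$selected_proportion, exp2$selected_proportion)
})

test_that("goal assessment selects the smallest qualifying proportion", {
  w <- small_world()
  # vacuous goals: success at the smallest nonzero proportion
  exp_easy <- run_experiment(w$ext, w$m0, k = 2, n_trials = 2, seed = 72,
                             goals = performance_goals(0, 0))
  expect_true(exp_easy$success)
  expect_equal(exp_easy$selected_proportion, 1 / 4)
  # unattainable goals: no success, no selection
  exp_hard <- run_experiment(w$ext, w$m0, k = 2, n_trials = 2, seed = 72,
                             goals = performance_goals(1, 1))
  if (!exp_hard$success) expect_true(is.na(exp_hard$selected_proportion))
  # ties count as meeting the goal (>=, not >)
  sens1 <- exp_easy$summary[exp_easy$summary$set == "variable" &
                              exp_easy$summary$iteration == 1 &
                              exp_easy$summary$metric == "sensitivity", "mean"]
  spec1 <- exp_easy$summary[exp_easy$summary$set == "variable" &
                              exp_easy$summary$iteration == 1 &
                              exp_easy$summary$metric == "specificity", "mean"]
  exp_tie <- run_experiment(w$ext, w$m0, k = 2, n_trials = 2, seed = 72,
                            goals = performance_goals(sens1, spec1))
  expect_true(exp_tie$success)
  expect_equal(exp_tie$selected_proportion, 1 / 4)
})

test_that("a dataset too small for the folds marks the experiment incomplete", {
  w <- small_world()
  tiny <- w$ext
  keep <- tiny$records$patient_id %in% unique(tiny$records$patient_id)[1:4]
  tiny$records <- tiny$records[keep, ]
  tiny$images <- tiny$images[tiny$records$mmode_id]
  expect_error(run_trial(tiny, w$m0, k = 3, seed = 1),
               class = "taaft_validation_error")
})

test_that("finalize_model trains on the selected folds and evaluates on the rest", {
  w <- small_world()
  fin <- finalize_model(w$ext, w$m0, proportion = 1 / 3, seed = 81)
  expect_equal(fin$proportion, 1 / 3)
  # p = 1/3 with k = 3: trained on 2 folds, evaluated on 4
  expect_setequal(fin$train_clips,
                  unlist(fin$fold_assignment$folds[1:2]))
  expect_setequal(fin$validation_clips,
                  unlist(fin$fold_assignment$folds[3:6]))
  expect_length(intersect(fin$train_clips, fin$validation_clips), 0)
  # p = 1/2: the evaluation set is the fixed-size definition (last k folds)
  fin2 <- finalize_model(w$ext, w$m0, proportion = 1 / 2, seed = 82)
  expect_setequal(fin2$validation_clips,
                  unlist(fin2$fold_assignment$folds[4:6]))
  # a fresh seed yields a different membership than a trial with another seed
  tr <- run_trial(w$ext, w$m0, k = 3, seed = 61)
  expect_false(identical(fin$fold_assignment$patient_fold,
                         tr$fold_assignment$patient_fold))
  expect_error(finalize_model(w$ext, w$m0, proportion = 0.4, seed = 1),
               class = "taaft_config_error")
})

test_that("drift_check reports paired metrics with deltas and guards leakage", {
  w <- small_world()
  # identical models -> zero deltas
  dc0 <- drift_check(w$m0, w$m0, w$local)
  expect_true(all(dc0$deltas == 0))
  # fine-tuned model: deltas reported for both headline metrics
  fin <- finalize_model(w$ext, w$m0, proportion = 1 / 3, seed = 81)
  dc <- drift_check(fin$model, w$m0, w$local)
  expect_named(dc$deltas, c("sensitivity", "specificity", "auc", "accuracy"))
  expect_equal(nrow(dc$table), 2)
  # patient overlap with fine-tuning data is an error
  expect_error(
    drift_check(fin$model, w$m0, w$local,
                train_patients = unique(w$local$records$patient_id)[1]),
    class = "taaft_validation_error")
  # empty holdout is an error
  empty <- w$local
  empty$records <- empty$records[0, ]
  expect_error(drift_check(fin$model, w$m0, empty),
               class = "taaft_validation_error")
})
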