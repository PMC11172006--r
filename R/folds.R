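# Patient-wise fold construction, the accumulative fine-tuning schedule,
# inner train/secondary-validation splitting, and pool-based upsampling.

#' Patient-wise split into 2k folds
#'
#' Patients are shuffled by a seeded RNG and assigned greedily to the fold
#' currently holding the fewest clips (ties to the lowest fold index), so
#' folds end up near-balanced by clip count while every patient's clips stay
#' together in one fold.
#'
#' @param records data.frame with columns clip_id and patient_id (e.g. the
#'   main M-mode records or a manifest).
#' @param k number of training-set increments; 2k folds are built.
#' @param seed RNG seed.
#' @return a `fold_assignment`: `list(k, folds, patient_fold, seed)` where
#'   `folds` is a list of 2k clip-id character vectors and `patient_fold`
#'   maps patient -> fold index.
#' @export
split_patientwise <- function(records, k, seed) {
  records <- as.data.frame(records)
  stopifnot(all(c("clip_id", "patient_id") %in% names(records)))
  patients <- unique(records$patient_id)
  n_folds <- 2L * as.integer(k)
  if (length(patients) < n_folds) {
    stop_taaft("need at least ", n_folds, " patients for k = ", k,
               "; got ", length(patients), class = "taaft_validation_error")
  }
  shuffled <- with_seed(seed, sample(patients))
  clip_counts <- table(records$patient_id)
  fold_sizes <- integer(n_folds)
  patient_fold <- stats::setNames(integer(length(shuffled)), shuffled)
  for (p in shuffled) {
    f <- which.min(fold_sizes)  # first minimum -> lowest fold index
    patient_fold[p] <- f
    fold_sizes[f] <- fold_sizes[f] + clip_counts[[p]]
  }
  folds <- lapply(seq_len(n_folds), function(f) {
    records$clip_id[records$patient_id %in% names(patient_fold)[patient_fold == f]]
  })
  structure(list(k = as.integer(k), folds = folds,
                 patient_fold = patient_fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Build the accumulative fine-tuning schedule
#'
#' Iteration 0 has an empty training set; each subsequent iteration moves one
#' fold from the variable-sized validation set into the training set. The
#' fixed-size validation set is the constant union of the last k folds; at
#' iteration k the two validation sets coincide. The training proportion at
#' iteration i is i/(2k).
#'
#' @param fa a [split_patientwise()] result.
#' @return an `accumulative_schedule`: list of k+1 iteration entries
#'   `list(iteration, p_train, train_folds, train_clips, variable_clips,
#'   fixed_clips)`.
#' @export
make_schedule <- function(fa) {
  stopifnot(inherits(fa, "fold_assignment"))
  k <- fa$k; n_folds <- 2L * k
  fixed_clips <- unlist(fa$folds[(k + 1):n_folds], use.names = FALSE)
  iterations <- lapply(0:k, function(i) {
    train_folds <- if (i == 0) integer(0) else seq_len(i)
    list(
      iteration = i,
      p_train = i / n_folds,
      train_folds = train_folds,
      train_clips = unlist(fa$folds[train_folds], use.names = FALSE),
      variable_clips = unlist(fa$folds[(i + 1):n_folds], use.names = FALSE),
      fixed_clips = fixed_clips
    )
  })
  structure(iterations, class = "accumulative_schedule")
}

#' Patient-wise inner train/secondary-validation split
#'
#' Shuffles the patients of a training set and assigns a prefix to the fit
#' set until it holds approximately `fraction` of the clips; the rest form
#' the secondary validation set. Both sides are guaranteed nonempty.
#'
#' @param records data.frame with clip_id and patient_id restricted to the
#'   training set.
#' @param fraction target fit-set clip fraction, in (0, 1); default 0.8.
#' @param seed RNG seed.
#' @return `list(fit = clip ids, secondary = clip ids)`.
#' @export
inner_split <- function(records, fraction = 0.8, seed = 0) {
  records <- as.data.frame(records)
  if (fraction <= 0 || fraction >= 1) {
    stop_taaft("fraction must be strictly inside (0,1)",
               class = "taaft_config_error")
  }
  patients <- unique(records$patient_id)
  if (length(patients) < 2) {
    stop_taaft("inner split needs at least 2 patients",
               class = "taaft_validation_error")
  }
  shuffled <- with_seed(seed, sample(patients))
  counts <- table(records$patient_id)[shuffled]
  cum <- cumsum(counts)
  target <- fraction * nrow(records)
  m <- max(which(cum <= ceiling(target)), 1)
  if (m >= length(patients)) m <- length(patients) - 1
  fit_patients <- shuffled[seq_len(m)]
  list(
    fit = records$clip_id[records$patient_id %in% fit_patients],
    secondary = records$clip_id[!records$patient_id %in% fit_patients]
  )
}

#' Upsample the positive class from the sequestered M-mode pool
#'
#' Adds pooled candidate M-modes of fit-set positive clips — never images
#' from validation patients — until the positive fraction reaches the target
#' class distribution. The number of additions is
#' `ceil(f * N_neg / (1 - f)) - N_pos`. Drawn without replacement until the
#' eligible pool is exhausted, then with replacement.
#'
#' @param fit_records data.frame of training M-mode records (columns
#'   mmode_id, clip_id, label at least).
#' @param pool_records data.frame of sequestered pool records (same columns;
#'   `is_main` FALSE).
#' @param target_positive_fraction target positive fraction in (0,1);
#'   default 0.26, the class distribution of a typical single-center
#'   training set.
#' @param seed RNG seed.
#' @return the augmented record data.frame (fit records plus sampled pool
#'   rows, possibly with repeats).
#' @export
upsample_positives <- function(fit_records, pool_records,
                               target_positive_fraction = 0.26, seed = 0) {
  f <- target_positive_fraction
  if (f <= 0 || f >= 1) {
    stop_taaft("target_positive_fraction must be in (0,1)",
               class = "taaft_config_error")
  }
  n_pos <- sum(fit_records$label == 1)
  n_neg <- sum(fit_records$label == 0)
  n_add <- ceiling(f * n_neg / (1 - f)) - n_pos
  if (n_add <= 0) return(fit_records)
  eligible <- pool_records[pool_records$clip_id %in% fit_records$clip_id, ,
                           drop = FALSE]
  if (nrow(eligible) == 0) {
    warning("eligible upsampling pool is empty; returning fit set unchanged",
            call. = FALSE)
    return(fit_records)
  }
  idx <- with_seed(seed, {
    first <- sample(nrow(eligible), min(n_add, nrow(eligible)))
    if (n_add > nrow(eligible)) {
      c(first, sample(nrow(eligible), n_add - nrow(eligible), replace = TRUE))
    } else {
      first
    }
  })
  rbind(fit_records, eligible[idx, names(fit_records), drop = FALSE])
}

#' Summarize fold characteristics
#'
#' Per-fold patient and clip counts by class with percentages — the shape of
#' a fold-characteristics table for one assignment.
#'
#' @param fa a [split_patientwise()] result.
#' @param records the data.frame the assignment was built from (clip_id,
#'   patient_id, label).
#' @return data.frame with one row per fold.
#' @export
summarize_folds <- function(fa, records) {
  records <- as.data.frame(records)
  do.call(rbind, lapply(seq_along(fa$folds), function(f) {
    sub <- records[records$clip_id %in% fa$folds[[f]], , drop = FALSE]
    n <- nrow(sub)
    pat <- tapply(sub$patient_id, sub$label, function(p) length(unique(p)))
    data.frame(
      fold = f,
      n_patients = length(unique(sub$patient_id)),
      patients_negative = if ("0" %in% names(pat)) pat[["0"]] else 0L,
      patients_positive = if ("1" %in% names(pat)) pat[["1"]] else 0L,
      n_clips = n,
      clips_negative = sum(sub$label == 0),
      clips_positive = sum(sub$label == 1),
      pct_positive = if (n > 0) 100 * mean(sub$label == 1) else 0,
      stringsAsFactors = FALSE
    )
  }))
}
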