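# M-mode preprocessing pipeline: 3-second segmentation, pleural-line ROI,
# column brightness scoring, M-mode reconstruction, main/pool partition,
# resizing to the classifier input size.
#
# Conventions: clips are arrays (rows, cols, frames), row 1 = shallowest
# depth; all indices are 1-based and intervals inclusive.

#' Split a cine clip into fixed-duration segments
#'
#' Consecutive, non-overlapping segments of `floor(fps * segment_seconds)`
#' frames. A trailing remainder shorter than one segment is dropped; a clip
#' shorter than one segment yields an empty list.
#'
#' @param clip array (rows, cols, frames).
#' @param fps frames per second (> 0).
#' @param segment_seconds segment duration, default 3 s.
#' @return list of clip arrays.
#' @export
segment_clip <- function(clip, fps, segment_seconds = 3) {
  stopifnot(fps > 0)
  per <- floor(fps * segment_seconds)
  n <- dim(clip)[3]
  n_seg <- n %/% per
  if (n_seg == 0) return(list())
  lapply(seq_len(n_seg), function(i) {
    clip[, , ((i - 1) * per + 1):(i * per), drop = FALSE]
  })
}

#' Locate the pleural line heuristically
#'
#' Stand-in for a learned pleural-line detector: the row band is centered on
#' the row maximizing the row-wise mean intensity over the lower 80% of the
#' frame (the top 20% of rows — chest wall near field — is excluded),
#' extended by ±2 rows and clipped to the frame; ties break to the lowest
#' qualifying row index. The column range is the full width. Deterministic.
#'
#' @param frame matrix (rows x cols).
#' @return a `pleural_roi`: `list(row_band = c(lo, hi), col_range = c(lo, hi))`,
#'   1-based inclusive.
#' @export
locate_pleura <- function(frame) {
  stopifnot(length(dim(frame)) == 2, nrow(frame) >= 1, ncol(frame) >= 1)
  start_row <- floor(0.2 * nrow(frame)) + 1
  means <- rowMeans(frame)
  cand <- start_row:nrow(frame)
  center <- cand[which.max(means[cand])]  # which.max takes the first maximum
  structure(list(
    row_band = c(max(1, center - 2), min(nrow(frame), center + 2)),
    col_range = c(1, ncol(frame))
  ), class = "pleural_roi")
}

#' Score columns by pleural-band brightness
#'
#' The per-column score is the sum of pixel intensities within the ROI row
#' band of the given (first) frame — a column statistic robust to single
#' speckle maxima.
#'
#' @param frame matrix (rows x cols).
#' @param roi a `pleural_roi` valid for the frame.
#' @return named numeric vector of scores, one per column in `col_range`
#'   (names are column indices).
#' @export
score_columns <- function(frame, roi) {
  stopifnot(roi$row_band[1] >= 1, roi$row_band[2] <= nrow(frame),
            roi$col_range[1] >= 1, roi$col_range[2] <= ncol(frame))
  cols <- roi$col_range[1]:roi$col_range[2]
  sub <- frame[roi$row_band[1]:roi$row_band[2], cols, drop = FALSE]
  stats::setNames(colSums(sub), cols)
}

#' Reconstruct an M-mode image from one column of a cine clip
#'
#' Output pixel (r, t) equals frame t, row r, at the chosen column: depth on
#' the vertical axis, time on the horizontal.
#'
#' @param clip array (rows, cols, frames) with >= 2 frames.
#' @param column 1-based column index.
#' @return matrix (rows x frames).
#' @export
extract_mmode <- function(clip, column) {
  d <- dim(clip)
  if (column < 1 || column > d[2]) {
    stop_taaft("column ", column, " out of range [1, ", d[2], "]",
               class = "taaft_bounds_error")
  }
  stopifnot(d[3] >= 2)
  clip[, column, , drop = TRUE]
}

# Bilinear resize to a square target with intensities clamped to [0,1].
resize_image <- function(img, target_size) {
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img), w = target_size, h = target_size,
    filter = "bilinear"))
  clamp(out)
}

#' Build the candidate M-mode set for one clip segment
#'
#' Candidates are the `n_candidates` distinct columns with the highest
#' pleural-band brightness scores on the first frame (ties break to the
#' lower column index). The highest-scoring candidate becomes the main
#' record; the remaining `n_candidates - 1` are sequestered into the pool
#' used for class upsampling during training. All images are resized to
#' `target_size` x `target_size`.
#'
#' @param clip array (rows, cols, frames).
#' @param roi a `pleural_roi`; default locates the pleura on frame 1.
#' @param n_candidates number of candidate columns (default 10).
#' @param target_size output side length (default 224).
#' @return `list(main =, pool =)` of `mmode_record`s, each
#'   `list(source_column, brightness_score, is_main, image)`.
#' @export
build_mmode_set <- function(clip, roi = NULL, n_candidates = 10,
                            target_size = 224) {
  first <- clip[, , 1]
  if (is.null(roi)) roi <- locate_pleura(first)
  scores <- score_columns(first, roi)
  if (length(scores) < n_candidates) {
    stop_taaft("ROI has ", length(scores), " columns; ", n_candidates,
               " candidates requested", class = "taaft_config_error")
  }
  cols <- as.integer(names(scores))
  ord <- order(-scores, cols)[seq_len(n_candidates)]
  make_record <- function(i, is_main) {
    col <- cols[ord[i]]
    structure(list(
      source_column = col,
      brightness_score = unname(scores[ord[i]]),
      is_main = is_main,
      image = resize_image(extract_mmode(clip, col), target_size)
    ), class = "mmode_record")
  }
  main <- make_record(1, TRUE)
  pool <- if (n_candidates > 1) {
    lapply(2:n_candidates, make_record, is_main = FALSE)
  } else {
    list()
  }
  list(main = main, pool = pool)
}

#' Preprocess one clip into M-mode records
#'
#' Segments the clip, locates (or accepts) the pleural ROI per segment, and
#' builds the candidate set: positive (absent-sliding) clips contribute
#' `n_candidates` M-modes (1 main + sequestered pool); negative clips
#' contribute only their main M-mode unless `pool_negatives`.
#'
#' @param clip array (rows, cols, frames).
#' @param fps frame rate.
#' @param clip_id,label,patient_id record identity.
#' @param roi optional `pleural_roi` overriding the heuristic locator.
#' @param n_candidates,target_size see [build_mmode_set()].
#' @param pool_negatives pool candidates for negative clips too.
#' @param segment_seconds see [segment_clip()].
#' @return `list(records = data.frame, images = named list)`; `records` has
#'   columns mmode_id, clip_id (segment id), source_clip_id, patient_id,
#'   label, segment, source_column, brightness_score, is_main.
#' @export
preprocess_clip <- function(clip, fps, clip_id, label, patient_id = NA_character_,
                            roi = NULL, n_candidates = 10, target_size = 224,
                            pool_negatives = FALSE, segment_seconds = 3) {
  segments <- segment_clip(clip, fps, segment_seconds)
  rows <- list(); images <- list()
  for (s in seq_along(segments)) {
    seg <- segments[[s]]
    seg_id <- if (length(segments) == 1) clip_id else
      sprintf("%s-s%d", clip_id, s)
    nc <- if (label == 1 || pool_negatives) n_candidates else 1
    set <- build_mmode_set(seg, roi = roi, n_candidates = nc,
                           target_size = target_size)
    recs <- c(list(set$main), set$pool)
    for (r in recs) {
      mmode_id <- sprintf("%s_m%03d", seg_id, r$source_column)
      rows[[length(rows) + 1]] <- data.frame(
        mmode_id = mmode_id, clip_id = seg_id, source_clip_id = clip_id,
        patient_id = patient_id, label = label, segment = s,
        source_column = r$source_column,
        brightness_score = r$brightness_score, is_main = r$is_main,
        stringsAsFactors = FALSE
      )
      images[[mmode_id]] <- r$image
    }
  }
  list(records = do.call(rbind, rows) %||% data.frame(), images = images)
}

#' Preprocess every clip of a dataset
#'
#' @param manifest a `lus_manifest`.
#' @param clips named list of clip arrays keyed by clip_id; clips absent from
#'   the list are read from `manifest$path` via [read_clip()].
#' @param roi_table optional data.frame (clip_id, row_lo, row_hi, col_lo,
#'   col_hi) overriding the heuristic pleura locator per clip.
#' @param ... passed to [preprocess_clip()].
#' @return an `mmode_dataset` (see [simulate_mmode_dataset()]).
#' @export
preprocess_dataset <- function(manifest, clips = NULL, roi_table = NULL, ...) {
  stopifnot(inherits(manifest, "lus_manifest"))
  acc_records <- list(); images <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    clip <- clips[[row$clip_id]] %||% read_clip(row$path)
    roi <- NULL
    if (!is.null(roi_table)) {
      j <- match(row$clip_id, roi_table$clip_id)
      if (!is.na(j)) {
        roi <- structure(list(
          row_band = c(roi_table$row_lo[j], roi_table$row_hi[j]),
          col_range = c(roi_table$col_lo[j], roi_table$col_hi[j])
        ), class = "pleural_roi")
      }
    }
    res <- preprocess_clip(clip, fps = row$fps, clip_id = row$clip_id,
                           label = row$label, patient_id = row$patient_id,
                           roi = roi, ...)
    acc_records[[i]] <- res$records
    for (id in names(res$images)) assign(id, res$images[[id]], envir = images)
  }
  records <- do.call(rbind, acc_records)
  structure(list(records = records,
                 images = as.list(images)[records$mmode_id],
                 manifest = manifest,
                 exclusions = data.frame(clip_id = character(0),
                                         rule = character(0))),
            class = "mmode_dataset")
}
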