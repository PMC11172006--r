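make_clip <- function(rows, cols, frames, fill = 0) {
  array(fill, dim = c(rows, cols, frames))
}

test_that("segment_clip arithmetic: full segments kept, remainder dropped", {
  clip <- make_clip(8, 8, 270)
  segs <- segment_clip(clip, fps = 30)  # 9 s at 30 fps
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) dim(s)[3], numeric(1)) == 90))
  # consecutive, non-overlapping
  clip2 <- array(seq_len(8 * 8 * 270), dim = c(8, 8, 270))
  segs2 <- segment_clip(clip2, fps = 30)
  expect_equal(segs2[[2]][, , 1], clip2[, , 91])

  expect_length(segment_clip(make_clip(8, 8, 90), 30), 1)     # exactly 3 s
  expect_equal(segment_clip(make_clip(8, 8, 90), 30)[[1]], make_clip(8, 8, 90))
  expect_length(segment_clip(make_clip(8, 8, 75), 30), 0)     # 2.5 s
})

test_that("locate_pleura finds the bright band within the lower 80%", {
  f <- matrix(0, 100, 30)
  f[60, ] <- 1
  roi <- locate_pleura(f)
  expect_true(roi$row_band[1] <= 60 && 60 <= roi$row_band[2])
  expect_equal(roi$row_band, c(58, 62))
  expect_equal(roi$col_range, c(1, 30))

  # uniform frame: tie broken to the lowest qualifying row
  u <- matrix(0.5, 100, 30)
  roi_u <- locate_pleura(u)
  expect_equal(roi_u$row_band, c(19, 23))  # first candidate row is 21

  # a band in the excluded top 20% is not selected
  g <- matrix(0, 100, 30)
  g[2, ] <- 1    # inside excluded top 20%
  g[70, ] <- 0.6
  roi_g <- locate_pleura(g)
  expect_true(roi_g$row_band[1] <= 70 && 70 <= roi_g$row_band[2])
})

test_that("score_columns equals brute-force ROI sums", {
  set.seed(42)
  for (rep in 1:20) {
    f <- matrix(runif(60 * 40), 60, 40)
    roi <- list(row_band = sort(sample(60, 2)), col_range = sort(sample(40, 2)))
    class(roi) <- "pleural_roi"
    scores <- score_columns(f, roi)
    brute <- vapply(roi$col_range[1]:roi$col_range[2], function(c) {
      s <- 0
      for (r in roi$row_band[1]:roi$row_band[2]) s <- s + f[r, c]
      s
    }, numeric(1))
    expect_equal(unname(scores), brute, tolerance = 1e-12)
  }
  # saturated column wins; all-zero frame scores zero
  f <- matrix(0, 20, 10); f[, 7] <- 1
  roi <- structure(list(row_band = c(5, 9), col_range = c(1, 10)),
                   class = "pleural_roi")
  expect_equal(which.max(score_columns(f, roi)), c("7" = 7))
  expect_true(all(score_columns(matrix(0, 20, 10), roi) == 0))
})

test_that("extract_mmode transposes one column over time exactly", {
  set.seed(1)
  clip <- array(runif(128 * 20 * 90), dim = c(128, 20, 90))
  m <- extract_mmode(clip, 7)
  expect_equal(dim(m), c(128, 90))
  for (probe in 1:25) {
    r <- sample(128, 1); t <- sample(90, 1)
    expect_identical(m[r, t], clip[r, 7, t])
  }
  # static column -> identical M-mode columns
  clip2 <- array(rep(runif(16), 4 * 5), dim = c(16, 1, 20))
  m2 <- extract_mmode(clip2, 1)
  expect_true(all(m2 == m2[, 1]))
  expect_error(extract_mmode(clip, 21), class = "taaft_bounds_error")
})

test_that("build_mmode_set partitions candidates and resizes", {
  clip <- generate_clip(1, tiny_profile(), c(48, 48), n_frames = 30, seed = 9)
  set <- build_mmode_set(clip, n_candidates = 10, target_size = 224)
  expect_true(set$main$is_main)
  expect_length(set$pool, 9)
  expect_true(all(!vapply(set$pool, `[[`, logical(1), "is_main")))
  expect_equal(dim(set$main$image), c(224, 224))
  for (p in set$pool) expect_equal(dim(p$image), c(224, 224))

  # main is the brute-force argmax of the scores, pool scores never exceed it
  roi <- locate_pleura(clip[, , 1])
  scores <- score_columns(clip[, , 1], roi)
  expect_equal(set$main$source_column, as.integer(names(scores)[which.max(scores)]))
  expect_true(all(vapply(set$pool, `[[`, numeric(1), "brightness_score") <=
                    set$main$brightness_score))
  # candidate columns pairwise distinct
  cols <- c(set$main$source_column,
            vapply(set$pool, `[[`, numeric(1), "source_column"))
  expect_equal(anyDuplicated(cols), 0)

  expect_error(build_mmode_set(clip[, 1:5, , drop = FALSE], n_candidates = 10),
               class = "taaft_config_error")
})

test_that("candidate ties break to the lower column index", {
  clip <- make_clip(30, 10, 5)
  clip[10, , ] <- 0.5  # every column scores identically
  roi <- structure(list(row_band = c(9, 11), col_range = c(1, 10)),
                   class = "pleural_roi")
  set <- build_mmode_set(clip, roi = roi, n_candidates = 3, target_size = 32)
  cols <- c(set$main$source_column,
            vapply(set$pool, `[[`, numeric(1), "source_column"))
  expect_equal(cols, c(1L, 2L, 3L))
})

test_that("resized M-modes keep the class signal (temporal variation ordering)", {
  prof <- tiny_profile()
  v <- function(label, seed) {
    clip <- generate_clip(label, prof, c(48, 48), n_frames = 30, seed = seed)
    img <- build_mmode_set(clip, n_candidates = 1, target_size = 224)$main$image
    mean(abs(img[, -1] - img[, -ncol(img)]))
  }
  for (seed in 1:5) expect_gt(v(0, seed), v(1, seed))
})

test_that("preprocess_clip honours labels, segments and ROI overrides", {
  prof <- tiny_profile()
  clip <- generate_clip(1, prof, c(48, 48), n_frames = 65, seed = 2)
  res <- preprocess_clip(clip, fps = 10, clip_id = "cX", label = 1,
                         patient_id = "pX", target_size = 64)
  # 65 frames at 10 fps -> two 30-frame segments, 10 candidates each
  expect_equal(nrow(res$records), 20)
  expect_equal(sum(res$records$is_main), 2)
  expect_equal(unique(res$records$segment), c(1, 2))
  expect_true(all(grepl("^cX-s[12]_m", res$records$mmode_id)))

  # negative clips yield only the main record by default
  resn <- preprocess_clip(clip, fps = 10, clip_id = "cY", label = 0,
                          target_size = 64)
  expect_equal(nrow(resn$records), 2)
  expect_true(all(resn$records$is_main))

  # explicit ROI restricts the candidate columns
  roi <- structure(list(row_band = c(19, 21), col_range = c(1, 12)),
                   class = "pleural_roi")
  resr <- preprocess_clip(clip, fps = 10, clip_id = "cZ", label = 1,
                          roi = roi, target_size = 64)
  expect_true(all(resr$records$source_column <= 12))
})
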