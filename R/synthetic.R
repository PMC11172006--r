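# Synthetic multicenter lung-ultrasound generator.
#
# Emulates the statistical structure the fine-tuning protocol assumes:
# patient grouping (several clips per patient, one institution per patient),
# heavy class imbalance (~13% absent-sliding), a bright pleural band, and
# per-institution domain shift in gain and noise. Not a physical ultrasound
# simulator: no ray tracing, no RF modeling.

#' Institution acquisition profile
#'
#' Describes one center's acquisition distribution: image gain, additive
#' noise, where the pleural line sits, how acquisition metadata (vendor,
#' probe, preset, location) is distributed, and the depth setting.
#'
#' @param name institution tag used in the manifest.
#' @param gain multiplicative brightness factor (local reference = 1).
#' @param noise_sd additive Gaussian noise scale on [0,1] intensities.
#' @param pleural_row_range inclusive row interval the pleural band center is
#'   drawn from (1-based; must fit inside the frame).
#' @param vendor_weights,probe_weights,preset_weights,location_weights named
#'   nonnegative sampling weights for the categorical metadata.
#' @param depth_mean,depth_sd depth setting distribution (cm), truncated > 3.
#' @param jitter_prob probability that an absent-sliding clip receives a
#'   global lateral probe-motion jitter (mimics operator movement that can
#'   fake sliding); off by default.
#' @param sliding_scale fraction (0,1] of the sub-pleural texture energy
#'   that decorrelates when sliding is present; values < 1 emulate centers
#'   whose sliding signature is weaker (shallower pleural excursion,
#'   different presets), the main driver of cross-center domain shift.
#' @param weight relative size of the institution when sampling patients.
#' @return an `institution_profile` list.
#' @export
institution_profile <- function(name,
                                gain = 1,
                                noise_sd = 0.02,
                                sliding_scale = 1,
                                pleural_row_range = c(24, 40),
                                vendor_weights = c(sonosite = 1),
                                probe_weights = c(phased_array = 0.8,
                                                  curved_linear = 0.2),
                                preset_weights = c(abdominal = 0.6, lung = 0.3,
                                                   cardiac = 0.1),
                                location_weights = c(ICU = 0.7, ED = 0.3),
                                depth_mean = 12, depth_sd = 3,
                                jitter_prob = 0,
                                weight = 1) {
  check_weights <- function(w, what) {
    if (any(w < 0) || sum(w) <= 0 || is.null(names(w))) {
      stop_taaft("invalid ", what, " weights for institution ", name,
                 class = "taaft_config_error")
    }
  }
  check_weights(vendor_weights, "vendor")
  check_weights(probe_weights, "probe")
  check_weights(preset_weights, "preset")
  check_weights(location_weights, "location")
  stopifnot(length(pleural_row_range) == 2,
            pleural_row_range[1] <= pleural_row_range[2],
            pleural_row_range[1] >= 1)
  stopifnot(sliding_scale > 0, sliding_scale <= 1)
  structure(list(
    name = name, gain = gain, noise_sd = noise_sd,
    sliding_scale = sliding_scale,
    pleural_row_range = as.integer(pleural_row_range),
    vendor_weights = vendor_weights, probe_weights = probe_weights,
    preset_weights = preset_weights, location_weights = location_weights,
    depth_mean = depth_mean, depth_sd = depth_sd,
    jitter_prob = jitter_prob, weight = weight
  ), class = "institution_profile")
}

#' Default institution profiles
#'
#' `"local"` is a single bright, low-noise center (the pretraining domain).
#' `"external"` is a trio of shifted centers with lower gain and higher
#' noise — the shift that degrades a locally trained model's specificity —
#' plus heterogeneous vendor/preset mixes and one center contributing a
#' small share of linear-probe clips (which the default manifest filter
#' excludes).
#'
#' @param type "external" (default) or "local".
#' @return list of [institution_profile()] objects.
#' @export
default_institutions <- function(type = c("external", "local")) {
  type <- match.arg(type)
  if (type == "local") {
    return(list(
      institution_profile("local", gain = 1.0, noise_sd = 0.02,
                          vendor_weights = c(sonosite = 0.9, mindray = 0.1),
                          preset_weights = c(abdominal = 0.7, lung = 0.2,
                                             cardiac = 0.1),
                          location_weights = c(ICU = 0.7, ED = 0.3),
                          depth_mean = 11, depth_sd = 2.5)
    ))
  }
  list(
    institution_profile("ext_a", gain = 0.62, noise_sd = 0.015,
                        sliding_scale = 0.60, weight = 2,
                        vendor_weights = c(sonosite = 0.95, unavailable = 0.05),
                        probe_weights = c(phased_array = 0.85,
                                          curved_linear = 0.15),
                        preset_weights = c(abdominal = 0.45, lung = 0.45,
                                           cardiac = 0.1),
                        location_weights = c(ICU = 1),
                        depth_mean = 12, depth_sd = 3),
    institution_profile("ext_b", gain = 0.50, noise_sd = 0.012,
                        sliding_scale = 0.70, weight = 1,
                        vendor_weights = c(mindray = 1),
                        probe_weights = c(phased_array = 0.55,
                                          curved_linear = 0.45),
                        preset_weights = c(lung = 0.5, abdominal = 0.3,
                                           cardiac = 0.2),
                        location_weights = c(ED = 1),
                        depth_mean = 10, depth_sd = 2.5),
    institution_profile("ext_c", gain = 0.72, noise_sd = 0.018,
                        sliding_scale = 0.50, weight = 0.7,
                        vendor_weights = c(phillips = 0.5, sonosite = 0.3,
                                           mindray = 0.2),
                        probe_weights = c(phased_array = 0.45,
                                          curved_linear = 0.45,
                                          linear = 0.10),
                        preset_weights = c(abdominal = 0.5, lung = 0.3,
                                           cardiac = 0.1, unavailable = 0.1),
                        location_weights = c(ED = 0.6, ICU = 0.35,
                                             unavailable = 0.05),
                        depth_mean = 13, depth_sd = 3.5)
  )
}

#' Synthetic dataset configuration
#'
#' @param n_patients number of patients.
#' @param clips_per_patient inclusive integer range of clips per patient.
#' @param positive_fraction expected fraction of absent-sliding (positive)
#'   clips; default 0.13, the imbalance typical of pooled external LUS data.
#' @param frame_shape (rows, cols) of each B-mode frame; entries >= 32.
#' @param fps frame rate (frames/second).
#' @param clip_seconds clip duration; the default 3 s matches the
#'   preprocessing segment length, so each clip is one segment.
#' @param institutions list of [institution_profile()]s.
#' @param patient_prefix prefix for generated patient ids; give distinct
#'   prefixes to datasets that must stay patient-disjoint (e.g. "L" for a
#'   local cohort, "E" for an external one).
#' @param seed RNG seed making generation fully reproducible.
#' @return a `lus_config` list.
#' @export
lus_config <- function(n_patients = 60,
                       clips_per_patient = c(2, 4),
                       positive_fraction = 0.13,
                       frame_shape = c(64, 64),
                       fps = 30, clip_seconds = 3,
                       institutions = default_institutions("external"),
                       patient_prefix = "P",
                       seed = 1) {
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop_taaft("positive_fraction must be in (0,1)",
               class = "taaft_config_error")
  }
  if (any(frame_shape < 32)) {
    stop_taaft("frame_shape entries must be >= 32",
               class = "taaft_config_error")
  }
  for (p in institutions) {
    if (p$pleural_row_range[2] > frame_shape[1] - 1) {
      stop_taaft("pleural_row_range of ", p$name,
                 " does not fit inside the frame",
                 class = "taaft_config_error")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    clips_per_patient = as.integer(clips_per_patient),
    positive_fraction = positive_fraction,
    frame_shape = as.integer(frame_shape),
    fps = fps, clip_seconds = clip_seconds,
    institutions = institutions,
    patient_prefix = patient_prefix, seed = as.integer(seed)
  ), class = "lus_config")
}

#' Generate one synthetic B-mode cine clip
#'
#' Frames carry a bright horizontal pleural band at a row drawn from the
#' profile's `pleural_row_range`, static speckle above the band, and
#' sub-pleural speckle that decorrelates frame-to-frame (lateral drift plus
#' partial resampling) when lung sliding is present (`label = 0`) but is
#' frozen up to additive noise when sliding is absent (`label = 1`). The
#' band's brightness is modulated laterally by a smooth bump so that the
#' brightest-column choice is well defined.
#'
#' @param label 1 = absent lung sliding (positive), 0 = sliding present.
#' @param profile an [institution_profile()].
#' @param frame_shape (rows, cols).
#' @param n_frames number of frames (>= 2).
#' @param seed optional seed; when NULL the caller's RNG stream is used.
#' @return numeric array (rows, cols, frames) of intensities in [0,1].
#' @export
generate_clip <- function(label, profile, frame_shape = c(64, 64),
                          n_frames = 90, seed = NULL) {
  if (n_frames < 2) stop_taaft("n_frames must be >= 2",
                               class = "taaft_config_error")
  if (profile$pleural_row_range[2] > frame_shape[1] - 1) {
    stop_taaft("frame too small to contain the pleural band",
               class = "taaft_config_error")
  }
  gen <- function() {
    rows <- frame_shape[1]; cols <- frame_shape[2]
    g <- profile$gain
    p_row <- if (profile$pleural_row_range[1] == profile$pleural_row_range[2]) {
      profile$pleural_row_range[1]
    } else {
      sample(profile$pleural_row_range[1]:profile$pleural_row_range[2], 1)
    }
    band <- max(1, p_row - 1):min(rows, p_row + 1)
    above <- seq_len(min(band) - 1)
    below <- if (max(band) < rows) (max(band) + 1):rows else integer(0)

    # smooth lateral brightness modulation of the pleural band
    center <- sample(seq_len(cols), 1)
    mod <- exp(-((seq_len(cols) - center)^2) / (2 * (cols / 6)^2))
    band_intensity <- g * (0.72 + 0.22 * mod)

    above_tex <- matrix(stats::rnorm(length(above) * cols), length(above), cols)
    static_tex <- matrix(stats::rnorm(length(below) * cols), length(below), cols)
    cur <- matrix(stats::rnorm(length(below) * cols), length(below), cols)
    rho <- 0.90  # per-frame autocorrelation of sliding sub-pleural speckle
    a <- profile$sliding_scale %||% 1

    jitter <- label == 1 && profile$jitter_prob > 0 &&
      stats::runif(1) < profile$jitter_prob
    jshift <- if (jitter) cumsum(sample(-1:1, n_frames, replace = TRUE)) else
      integer(n_frames)

    clip <- array(0, dim = c(rows, cols, n_frames))
    for (t in seq_len(n_frames)) {
      if (label == 0 && t > 1) {
        # lateral drift by one pixel + partial resampling => decorrelation
        cur <- cbind(cur[, -1, drop = FALSE], stats::rnorm(length(below)))
        cur <- rho * cur + sqrt(1 - rho^2) *
          matrix(stats::rnorm(length(below) * cols), length(below), cols)
      }
      f <- matrix(0.04 * g, rows, cols)
      if (length(above) > 0) f[above, ] <- 0.08 * g + 0.12 * g * above_tex
      f[band, ] <- matrix(band_intensity, length(band), cols, byrow = TRUE)
      if (length(below) > 0) {
        # label 0: a mix of frozen and decorrelating texture (weight a);
        # label 1: fully frozen texture — identical frames up to noise
        tex <- if (label == 0) {
          sqrt(1 - a) * static_tex + sqrt(a) * cur
        } else {
          static_tex
        }
        f[below, ] <- 0.12 * g + 0.30 * g * tex
      }
      if (jshift[t] != 0) {
        s <- ((seq_len(cols) - 1 + jshift[t]) %% cols) + 1
        f <- f[, s, drop = FALSE]
      }
      if (profile$noise_sd > 0) {
        f <- f + matrix(stats::rnorm(rows * cols, sd = profile$noise_sd),
                        rows, cols)
      }
      clip[, , t] <- clamp(f)
    }
    clip
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

sample_weighted <- function(weights) {
  if (length(weights) == 1) return(names(weights))
  sample(names(weights), 1, prob = weights)
}

# Core generation loop. `clip_sink(clip, record)` is called per clip; when it
# returns a path that path is stored in the manifest. Used by both
# generate_dataset() and simulate_mmode_dataset().
generate_records <- function(cfg, clip_sink) {
  inst_w <- vapply(cfg$institutions, function(p) p$weight, numeric(1))
  n_frames <- floor(cfg$fps * cfg$clip_seconds)
  rows <- list()
  for (i in seq_len(cfg$n_patients)) {
    patient_id <- sprintf("%s%03d", cfg$patient_prefix %||% "P", i)
    prof <- cfg$institutions[[
      sample.int(length(cfg$institutions), 1, prob = inst_w)]]
    n_clips <- if (cfg$clips_per_patient[1] == cfg$clips_per_patient[2]) {
      cfg$clips_per_patient[1]
    } else {
      sample(cfg$clips_per_patient[1]:cfg$clips_per_patient[2], 1)
    }
    for (j in seq_len(n_clips)) {
      clip_id <- sprintf("%s_c%02d", patient_id, j)
      label <- stats::rbinom(1, 1, cfg$positive_fraction)
      depth <- max(3, stats::rnorm(1, prof$depth_mean, prof$depth_sd))
      record <- data.frame(
        clip_id = clip_id, patient_id = patient_id, label = label,
        institution = prof$name,
        vendor = sample_weighted(prof$vendor_weights),
        probe = sample_weighted(prof$probe_weights),
        preset = sample_weighted(prof$preset_weights),
        depth_cm = round(depth, 1),
        location = sample_weighted(prof$location_weights),
        fps = cfg$fps, path = "", excluded_reason = "",
        stringsAsFactors = FALSE
      )
      clip <- generate_clip(label, prof, cfg$frame_shape, n_frames)
      path <- clip_sink(clip, record)
      if (!is.null(path)) record$path <- path
      rows[[length(rows) + 1]] <- record
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic multicenter LUS dataset
#'
#' Every patient's clips share one institution; the class is assigned per
#' clip with probability `positive_fraction`. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [lus_config()].
#' @param out_dir optional directory; when given, clips are written as
#'   multi-page TIFFs and the manifest as `manifest.csv`.
#' @param keep_clips keep the generated clips in memory (named list).
#' @return `list(manifest, clips)`; `clips` is NULL when `keep_clips` is
#'   FALSE.
#' @export
generate_dataset <- function(cfg, out_dir = NULL, keep_clips = TRUE) {
  clips <- if (keep_clips) new.env(parent = emptyenv()) else NULL
  sink_fun <- function(clip, record) {
    if (keep_clips) assign(record$clip_id, clip, envir = clips)
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(record$clip_id, ".tif"))
      write_clip(clip, path)
      path
    } else {
      NULL
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  records <- with_seed(cfg$seed, generate_records(cfg, sink_fun))
  manifest <- as_manifest(records, provenance = sprintf(
    "synthetic(seed=%d, n_patients=%d)", cfg$seed, cfg$n_patients))
  if (!is.null(out_dir)) write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  clip_list <- if (keep_clips) as.list(clips)[manifest$clip_id] else NULL
  list(manifest = manifest, clips = clip_list)
}

#' Generate a synthetic dataset and preprocess it to M-mode records
#'
#' Memory-light path used for fine-tuning experiments: each clip is
#' generated, converted to its M-mode record set (candidate pool for
#' positive clips), and discarded. Deterministic under `cfg$seed`
#' (preprocessing consumes no randomness).
#'
#' @param cfg a [lus_config()].
#' @param n_candidates candidate M-modes per absent-sliding clip.
#' @param target_size output image side length.
#' @param pool_negatives also pool candidates for negative clips (default
#'   FALSE: negatives contribute only their main M-mode).
#' @param apply_filter apply [default_filter_rules()] before preprocessing.
#' @return an `mmode_dataset`: `list(records, images, manifest, exclusions)`.
#' @export
simulate_mmode_dataset <- function(cfg, n_candidates = 10, target_size = 224,
                                   pool_negatives = FALSE,
                                   apply_filter = TRUE) {
  acc_records <- list()
  acc_images <- new.env(parent = emptyenv())
  sink_fun <- function(clip, record) {
    res <- preprocess_clip(clip, fps = record$fps, clip_id = record$clip_id,
                           label = record$label,
                           patient_id = record$patient_id,
                           n_candidates = n_candidates,
                           target_size = target_size,
                           pool_negatives = pool_negatives)
    acc_records[[length(acc_records) + 1]] <<- res$records
    for (id in names(res$images)) assign(id, res$images[[id]], envir = acc_images)
    NULL
  }
  # filtering must not change RNG consumption: generate everything, filter after
  records <- with_seed(cfg$seed, generate_records(cfg, sink_fun))
  manifest <- as_manifest(records, provenance = sprintf(
    "synthetic(seed=%d, n_patients=%d)", cfg$seed, cfg$n_patients))
  mm_records <- do.call(rbind, acc_records)
  exclusions <- data.frame(clip_id = character(0), rule = character(0))
  if (apply_filter) {
    flt <- filter_manifest(manifest)
    manifest <- flt$manifest
    exclusions <- flt$exclusions
    keep <- mm_records$source_clip_id %in% manifest$clip_id
    mm_records <- mm_records[keep, , drop = FALSE]
  }
  images <- as.list(acc_images)[mm_records$mmode_id]
  structure(list(records = mm_records, images = images,
                 manifest = manifest, exclusions = exclusions),
            class = "mmode_dataset")
}

#' Write a clip as a multi-page grayscale TIFF
#' @param clip array (rows, cols, frames), intensities in [0,1].
#' @param path output file.
#' @export
write_clip <- function(clip, path) {
  pages <- lapply(seq_len(dim(clip)[3]), function(t) clip[, , t])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a clip from a multi-page TIFF or a directory of PNG frames
#' @param path TIFF file or directory of zero-padded grayscale PNGs.
#' @return array (rows, cols, frames).
#' @export
read_clip <- function(path) {
  to_gray <- function(m) if (length(dim(m)) == 3) m[, , 1] else m
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop_taaft("no PNG frames in ", path,
                                       class = "taaft_format_error")
    pages <- lapply(files, function(f) to_gray(png::readPNG(f)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, to_gray)
  }
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @export
print.mmode_dataset <- function(x, ...) {
  cat(sprintf(
    "<mmode_dataset> %d M-mode images (%d main, %d pooled) from %d clips, %d patients\n",
    nrow(x$records), sum(x$records$is_main), sum(!x$records$is_main),
    length(unique(x$records$source_clip_id)),
    length(unique(x$records$patient_id))))
  invisible(x)
}
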