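# Dataset manifest model: CSV I/O, record filters, characteristics summary.

MANIFEST_COLUMNS <- c(
  "clip_id", "patient_id", "label", "institution", "vendor", "probe",
  "preset", "depth_cm", "location", "fps", "path", "excluded_reason"
)
MANDATORY_COLUMNS <- c("clip_id", "patient_id", "label", "path", "fps")
METADATA_FIELDS <- c("institution", "vendor", "probe", "preset", "location")

#' Construct a clip manifest
#'
#' A manifest is one row per B-mode clip: patient linkage, the binary
#' lung-sliding label (1 = absent lung sliding, the positive class;
#' 0 = sliding and/or lung pulse present, the negative class) and the
#' acquisition metadata used by the subgroup audit.
#'
#' @param records data.frame with at least clip_id, patient_id, label, path,
#'   fps. Missing metadata columns are added and filled with "unavailable"
#'   (depth_cm with NA).
#' @param provenance free-text source tag stored as an attribute.
#' @return A `lus_manifest`: a data.frame with the canonical column set.
#' @export
as_manifest <- function(records, provenance = "unspecified") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(MANDATORY_COLUMNS, names(records))
  if (length(missing) > 0) {
    stop_taaft("manifest is missing mandatory column(s): ",
               paste(missing, collapse = ", "),
               class = "taaft_format_error")
  }
  for (col in setdiff(MANIFEST_COLUMNS, names(records))) {
    records[[col]] <- if (col == "depth_cm") NA_real_ else "unavailable"
  }
  if ("excluded_reason" %in% names(records)) {
    records$excluded_reason[is.na(records$excluded_reason)] <- ""
    records$excluded_reason[records$excluded_reason == "unavailable"] <- ""
  }
  records$label <- normalize_label(records$label)
  records$fps <- as.numeric(records$fps)
  records$depth_cm <- suppressWarnings(as.numeric(records$depth_cm))
  for (col in c("clip_id", "patient_id", METADATA_FIELDS, "path")) {
    records[[col]] <- as.character(records[[col]])
    blank <- is.na(records[[col]]) | records[[col]] == ""
    if (col %in% METADATA_FIELDS) records[[col]][blank] <- "unavailable"
  }
  records <- records[, MANIFEST_COLUMNS]
  validate_manifest(records)
  structure(records,
            provenance = provenance,
            class = c("lus_manifest", "data.frame"))
}

# Accept 0/1 plus human-readable aliases used in hand-edited fixtures.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "absent", "positive", "absent_sliding")] <- 1L
  out[x %in% c("0", "present", "sliding", "negative", "lung_pulse", "pulse")] <- 0L
  if (anyNA(out)) {
    stop_taaft("unrecognized label value(s): ",
               paste(unique(x[is.na(out)]), collapse = ", "),
               class = "taaft_format_error")
  }
  out
}

validate_manifest <- function(records) {
  if (anyDuplicated(records$clip_id)) {
    dup <- unique(records$clip_id[duplicated(records$clip_id)])
    stop_taaft("duplicate clip_id in manifest: ", paste(dup, collapse = ", "),
               class = "taaft_validation_error")
  }
  if (any(is.na(records$patient_id) | records$patient_id == "")) {
    stop_taaft("patient_id must be nonempty for every record",
               class = "taaft_validation_error")
  }
  if (any(!is.finite(records$fps) | records$fps <= 0)) {
    stop_taaft("fps must be positive for every record",
               class = "taaft_validation_error")
  }
  bad_depth <- !is.na(records$depth_cm) & records$depth_cm <= 0
  if (any(bad_depth)) {
    stop_taaft("depth_cm must be positive when present",
               class = "taaft_validation_error")
  }
  invisible(records)
}

#' Read a clip manifest from CSV
#'
#' Comma-separated, UTF-8, RFC 4180 quoting, header required. Labels may be
#' 0/1 or the aliases "absent"/"present". Empty metadata cells become
#' "unavailable"; row order is preserved.
#'
#' @param path CSV file path.
#' @param provenance source tag; defaults to the file path.
#' @return A [as_manifest()] object.
#' @export
read_manifest <- function(path, provenance = path) {
  if (!file.exists(path)) {
    stop_taaft("manifest file not found: ", path, class = "taaft_format_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  as_manifest(raw, provenance = provenance)
}

#' Write a clip manifest to CSV
#'
#' Inverse of [read_manifest()]: field values round-trip exactly.
#' @param manifest a `lus_manifest`.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, MANIFEST_COLUMNS],
                   path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Default manifest exclusion rules
#'
#' Linear-probe clips are excluded (their acquisition physics differ too much
#' from phased-array/curved-linear training data), as is any record carrying
#' a nonempty `excluded_reason` flag.
#' @return a list of rules consumable by [filter_manifest()].
#' @export
default_filter_rules <- function() {
  list(
    list(field = "probe", exclude = "linear"),
    list(field = "excluded_reason", exclude_nonempty = TRUE)
  )
}

#' Filter a manifest, logging every exclusion
#'
#' @param manifest a `lus_manifest`.
#' @param rules list of rules; each rule is `list(field=, exclude=)` (drop
#'   records whose field value is in `exclude`) or
#'   `list(field=, exclude_nonempty=TRUE)` (drop records with a nonempty
#'   value). An empty list is the identity.
#' @return `list(manifest =, exclusions =)` where `exclusions` is a
#'   data.frame of (clip_id, rule) pairs, one row per excluded record.
#' @export
filter_manifest <- function(manifest, rules = default_filter_rules()) {
  stopifnot(inherits(manifest, "lus_manifest"))
  drop <- rep(FALSE, nrow(manifest))
  fired <- rep(NA_character_, nrow(manifest))
  for (rule in rules) {
    if (is.null(rule$field) || !rule$field %in% names(manifest)) {
      stop_taaft("filter rule references unknown field: ",
                 rule$field %||% "<missing>", class = "taaft_config_error")
    }
    vals <- manifest[[rule$field]]
    hit <- if (isTRUE(rule$exclude_nonempty)) {
      !is.na(vals) & vals != ""
    } else {
      vals %in% rule$exclude
    }
    newly <- hit & !drop
    fired[newly] <- sprintf("%s:%s", rule$field,
                            if (isTRUE(rule$exclude_nonempty)) "nonempty"
                            else paste(rule$exclude, collapse = "|"))
    drop <- drop | hit
  }
  kept <- manifest[!drop, , drop = FALSE]
  if (nrow(kept) == 0 && nrow(manifest) > 0) {
    warning("all records excluded by filter rules", call. = FALSE)
  }
  exclusions <- data.frame(
    clip_id = manifest$clip_id[drop],
    rule = fired[drop],
    stringsAsFactors = FALSE
  )
  list(
    manifest = structure(kept, provenance = attr(manifest, "provenance"),
                         class = c("lus_manifest", "data.frame")),
    exclusions = exclusions
  )
}

#' Bin acquisition depth into the standard reporting bins
#'
#' Bins are left-closed: [0, 6), [6, 20), [20, Inf), reported as
#' "<6", "6-20", ">20"; missing depth maps to "unavailable".
#' @param depth_cm numeric vector of depths in centimeters.
#' @return character vector of bin labels.
#' @export
depth_bin <- function(depth_cm) {
  out <- rep("unavailable", length(depth_cm))
  ok <- !is.na(depth_cm)
  out[ok & depth_cm < 6] <- "<6"
  out[ok & depth_cm >= 6 & depth_cm < 20] <- "6-20"
  out[ok & depth_cm >= 20] <- ">20"
  out
}

#' Summarize manifest characteristics by class
#'
#' Produces the dataset-characteristics table: per-class patient and clip
#' counts, then per-class clip counts for each metadata field level, with
#' percentages of the clip (or patient) total. Depth is reported in the
#' standard bins.
#'
#' @param manifest a `lus_manifest`.
#' @return data.frame with columns section, field, level, n_negative,
#'   n_positive, pct_negative, pct_positive.
#' @export
summarize_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "lus_manifest"))
  m <- as.data.frame(manifest)
  n_clips <- nrow(m)
  pct <- function(n, denom) if (denom > 0) 100 * n / denom else 0

  rows <- list()
  # patients by class: a patient counts toward a class if they have >= 1 clip
  # of that class (a patient can appear in both rows)
  pat_pos <- length(unique(m$patient_id[m$label == 1]))
  pat_neg <- length(unique(m$patient_id[m$label == 0]))
  n_pat <- length(unique(m$patient_id))
  rows[[1]] <- data.frame(
    section = "patients", field = "class", level = "all",
    n_negative = pat_neg, n_positive = pat_pos,
    pct_negative = pct(pat_neg, n_pat), pct_positive = pct(pat_pos, n_pat),
    stringsAsFactors = FALSE
  )
  clip_pos <- sum(m$label == 1)
  clip_neg <- sum(m$label == 0)
  rows[[2]] <- data.frame(
    section = "clips", field = "class", level = "all",
    n_negative = clip_neg, n_positive = clip_pos,
    pct_negative = pct(clip_neg, n_clips), pct_positive = pct(clip_pos, n_clips),
    stringsAsFactors = FALSE
  )
  fields <- c(METADATA_FIELDS, "depth")
  for (field in fields) {
    vals <- if (field == "depth") depth_bin(m$depth_cm) else m[[field]]
    for (level in sort(unique(vals))) {
      sel <- vals == level
      npos <- sum(sel & m$label == 1)
      nneg <- sum(sel & m$label == 0)
      rows[[length(rows) + 1]] <- data.frame(
        section = "clips", field = field, level = level,
        n_negative = nneg, n_positive = npos,
        pct_negative = pct(nneg, n_clips), pct_positive = pct(npos, n_clips),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.lus_manifest <- function(x, ...) {
  cat(sprintf("<lus_manifest> %d clips, %d patients, %d positive (%.1f%%)\n",
              nrow(x), length(unique(x$patient_id)), sum(x$label == 1),
              if (nrow(x) > 0) 100 * mean(x$label == 1) else 0))
  cat(sprintf("  provenance: %s\n", attr(x, "provenance") %||% "unspecified"))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5))
  invisible(x)
}
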