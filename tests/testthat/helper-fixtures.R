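# Shared fixture builders. Everything is generated in code; small sizes keep
# unit tests fast (the acceptance suite builds its own larger datasets).

tiny_profile <- function(...) {
  institution_profile("tiny", pleural_row_range = c(18, 26), ...)
}

# A small single-institution config: 48x48 frames, 10 fps so a 3-s segment is
# 30 frames.
tiny_config <- function(n_patients = 8, seed = 7, positive_fraction = 0.25,
                        ...) {
  lus_config(n_patients = n_patients, clips_per_patient = c(1, 3),
             positive_fraction = positive_fraction,
             frame_shape = c(48, 48), fps = 10, clip_seconds = 3,
             institutions = list(tiny_profile()), seed = seed, ...)
}

manifest_csv_text <- function() {
  paste(
    "clip_id,patient_id,label,institution,vendor,probe,preset,depth_cm,location,fps,path,excluded_reason",
    "c1,p1,1,instA,sonosite,phased_array,lung,12,ICU,30,/x/c1.tif,",
    "c2,p1,0,instA,,curved_linear,abdominal,8,ED,30,/x/c2.tif,",
    "c3,p2,absent,instB,mindray,linear,cardiac,22,ICU,25,/x/c3.tif,",
    sep = "\n"
  )
}

write_fixture_manifest <- function(path = tempfile(fileext = ".csv")) {
  writeLines(manifest_csv_text(), path)
  path
}

# Deterministic toy manifest data.frame with n records spread over patients.
toy_records <- function(n = 10, n_patients = 5, labels = NULL) {
  data.frame(
    clip_id = sprintf("c%02d", seq_len(n)),
    patient_id = sprintf("p%02d", rep_len(seq_len(n_patients), n)),
    label = labels %||% rep_len(c(0, 0, 0, 1), n),
    path = "x.tif", fps = 30,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
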