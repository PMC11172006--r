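# Metadata subgroup audit: chi-squared independence of prediction
# correctness vs subgroup, one-way ANOVA of prediction error vs subgroup,
# stratified by ground-truth class, with within-subgroup fragility indices
# for significant chi-squared combinations.

#' Chi-squared test of correctness vs subgroup
#'
#' Pearson chi-squared (no continuity correction) on the 2 x G contingency
#' table of correctness by group. Groups with zero examples are dropped with
#' a warning. When one correctness outcome is absent entirely (all correct
#' or all incorrect) the rates are identical across groups and the
#' degenerate result chi-squared = 0, p = 1 is returned with a warning.
#'
#' @param correct logical vector.
#' @param group categorical vector of the same length.
#' @return list(statistic, df, p_value, table).
#' @export
chi_squared_independence <- function(correct, group) {
  stopifnot(length(correct) == length(group))
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) {
    stop_taaft("chi-squared independence needs at least 2 groups",
               class = "taaft_validation_error")
  }
  tab <- table(factor(correct, levels = c(FALSE, TRUE)), group)
  zero_cols <- colSums(tab) == 0
  if (any(zero_cols)) {
    warning("dropping zero-margin group(s): ",
            paste(colnames(tab)[zero_cols], collapse = ", "), call. = FALSE)
    tab <- tab[, !zero_cols, drop = FALSE]
  }
  G <- ncol(tab)
  if (G < 2) {
    stop_taaft("fewer than 2 nonempty groups", class = "taaft_validation_error")
  }
  if (any(rowSums(tab) == 0)) {
    warning("a correctness outcome is absent; returning degenerate ",
            "chi-squared = 0", call. = FALSE)
    return(list(statistic = 0, df = G - 1L, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}

#' One-way ANOVA of prediction error vs subgroup
#'
#' Classical one-way F test (equal-variance): F = MS_between / MS_within
#' with the upper-tail F p-value. A fully degenerate input (zero between-
#' and within-group variance) is reported as F = 0, p = 1.
#'
#' @param error numeric vector (e.g. |score - label|).
#' @param group categorical vector of the same length.
#' @return list(statistic, df_between, df_within, p_value).
#' @export
one_way_anova <- function(error, group) {
  stopifnot(length(error) == length(group))
  group <- droplevels(factor(group))
  G <- nlevels(group)
  n <- length(error)
  if (G < 2 || n <= G) {
    stop_taaft("one-way ANOVA needs >= 2 groups and n > G",
               class = "taaft_validation_error")
  }
  means <- tapply(error, group, mean)
  counts <- tapply(error, group, length)
  grand <- mean(error)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((error - means[group])^2)
  df1 <- G - 1L; df2 <- n - G
  if (ssb == 0) {
    return(list(statistic = 0, df_between = df1, df_within = df2, p_value = 1))
  }
  if (ssw == 0) {
    return(list(statistic = Inf, df_between = df1, df_within = df2,
                p_value = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df_between = df1, df_within = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Within-subgroup fragility index
#'
#' The minimum number of correctness flips among examples of one subgroup
#' level that renders the field's chi-squared test non-significant
#' (p > alpha). Because the statistic depends on the level only through its
#' correct/incorrect counts, the minimum is found exactly by searching over
#' the reachable compositions of the level (m flips move the level's correct
#' count by at most m). Returns NA when no amount of flipping within the
#' level can cross alpha, or when the level is empty.
#'
#' @param correct logical vector.
#' @param group categorical vector.
#' @param level the group value whose examples may be flipped.
#' @param alpha significance threshold (inclusive), default 0.05.
#' @return nonnegative integer flip count, or NA.
#' @export
fragility_index <- function(correct, group, level, alpha = 0.05) {
  base <- chi_squared_independence(correct, group)
  if (base$p_value > alpha) {
    stop_taaft("fragility index is only defined for combinations ",
               "significant at alpha = ", alpha,
               class = "taaft_validation_error")
  }
  idx <- which(group == level)
  if (length(idx) == 0) return(NA_integer_)
  n_level <- length(idx)
  n_true0 <- sum(correct[idx])
  p_for <- function(n_true) {
    mod <- correct
    mod[idx] <- c(rep(TRUE, n_true), rep(FALSE, n_level - n_true))
    chi_squared_independence(mod, group)$p_value
  }
  # m flips reach exactly the compositions with |n_true - n_true0| <= m,
  # and composition a needs |a - n_true0| flips; search in increasing cost
  for (m in seq_len(n_level)) {
    for (a in unique(c(n_true0 - m, n_true0 + m))) {
      if (a < 0 || a > n_level) next
      if (suppressWarnings(p_for(a)) > alpha) return(m)
    }
  }
  NA_integer_
}

AUDIT_FIELDS <- c("vendor", "probe", "preset", "depth", "institution")

#' Audit model performance across metadata subgroups
#'
#' Joins predictions to the manifest, derives correctness (thresholded
#' prediction vs label) and continuous error (|score - label|), then for
#' every metadata field and ground-truth stratum (positives probe
#' sensitivity effects, negatives specificity effects) runs the chi-squared
#' independence test on correctness and the one-way ANOVA on error. For
#' chi-squared-significant combinations, per-level fragility indices are
#' computed. Depth is binned (<6, 6-20, >20 cm); an "unavailable" metadata
#' level is kept as its own level when it has >= 5 examples in the stratum
#' and dropped otherwise. p-values are reported raw (no multiple-testing
#' correction).
#'
#' @param predictions data.frame with columns clip_id and score.
#' @param manifest a `lus_manifest` supplying labels and metadata.
#' @param fields metadata fields to audit; "depth" means binned depth_cm.
#' @param alpha significance threshold (inclusive), default 0.05.
#' @param threshold decision threshold for correctness, default 0.5.
#' @return a `subgroup_report`: list(tests, fragility, level_metrics, alpha,
#'   threshold, note).
#' @export
audit_subgroups <- function(predictions, manifest, fields = AUDIT_FIELDS,
                            alpha = 0.05, threshold = 0.5) {
  stopifnot(all(c("clip_id", "score") %in% names(predictions)))
  m <- as.data.frame(manifest)
  bad <- setdiff(fields, c(names(m), "depth"))
  if (length(bad) > 0) {
    stop_taaft("unknown audit field(s): ", paste(bad, collapse = ", "),
               class = "taaft_config_error")
  }
  j <- match(predictions$clip_id, m$clip_id)
  if (anyNA(j)) {
    stop_taaft("predictions contain clip_ids absent from the manifest",
               class = "taaft_validation_error")
  }
  d <- cbind(predictions, m[j, setdiff(names(m), "clip_id"), drop = FALSE])
  d$depth <- depth_bin(d$depth_cm)
  d$correct <- (d$score >= threshold) == (d$label == 1)
  d$error <- abs(d$score - d$label)

  tests <- list(); fragility <- list(); level_metrics <- list()
  for (field in fields) {
    for (stratum in c("positive", "negative")) {
      sub <- d[d$label == (stratum == "positive"), , drop = FALSE]
      g <- sub[[field]]
      # "unavailable" is a real level only when adequately populated
      if (sum(g == "unavailable") < 5) {
        sub <- sub[g != "unavailable", , drop = FALSE]
        g <- sub[[field]]
      }
      n_levels <- length(unique(g))
      if (nrow(sub) == 0 || n_levels < 2) next
      chi <- tryCatch(
        suppressWarnings(chi_squared_independence(sub$correct, g)),
        taaft_validation_error = function(e) NULL)
      aov_res <- tryCatch(one_way_anova(sub$error, g),
                          taaft_validation_error = function(e) NULL)
      if (!is.null(chi)) {
        tests[[length(tests) + 1]] <- data.frame(
          field = field, stratum = stratum, test = "chi_squared",
          statistic = chi$statistic, df = chi$df, p_value = chi$p_value,
          significant = chi$p_value <= alpha, stringsAsFactors = FALSE)
      }
      if (!is.null(aov_res)) {
        tests[[length(tests) + 1]] <- data.frame(
          field = field, stratum = stratum, test = "anova",
          statistic = aov_res$statistic, df = aov_res$df_between,
          p_value = aov_res$p_value,
          significant = aov_res$p_value <= alpha, stringsAsFactors = FALSE)
      }
      if (!is.null(chi) && chi$p_value <= alpha) {
        for (lev in unique(g)) {
          fi <- fragility_index(sub$correct, g, lev, alpha = alpha)
          fragility[[length(fragility) + 1]] <- data.frame(
            field = field, stratum = stratum, level = lev,
            n = sum(g == lev), fragility_index = fi,
            stringsAsFactors = FALSE)
        }
      }
    }
    # per-level sensitivity/specificity with counts (report layout)
    g_all <- d[[field]]
    for (lev in sort(unique(g_all))) {
      sel <- g_all == lev
      pos <- d$label[sel] == 1
      level_metrics[[length(level_metrics) + 1]] <- data.frame(
        field = field, level = lev,
        n = sum(sel), n_positive = sum(pos), n_negative = sum(!pos),
        sensitivity = if (any(pos)) mean(d$correct[sel][pos]) else NA_real_,
        specificity = if (any(!pos)) mean(d$correct[sel][!pos]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  bindr <- function(x, empty) if (length(x) > 0) do.call(rbind, x) else empty
  structure(list(
    tests = bindr(tests, data.frame()),
    fragility = bindr(fragility, data.frame()),
    level_metrics = bindr(level_metrics, data.frame()),
    alpha = alpha, threshold = threshold,
    note = "raw p-values; no multiple-testing correction across fields"
  ), class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("<subgroup_report> alpha = %.2f (inclusive), threshold = %.2f\n",
              x$alpha, x$threshold))
  if (nrow(x$tests) > 0) {
    sig <- x$tests[x$tests$significant, , drop = FALSE]
    cat(sprintf("  %d tests, %d significant\n", nrow(x$tests), nrow(sig)))
    if (nrow(sig) > 0) print(sig, row.names = FALSE)
  }
  cat("  note:", x$note, "\n")
  invisible(x)
}
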