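test_that("chi-squared matches closed forms on 2-group tables", {
  # [[10,0],[0,10]]: chi2 = 20, df 1
  correct <- c(rep(TRUE, 10), rep(FALSE, 10))
  group <- rep(c("g1", "g2"), each = 10)
  res <- chi_squared_independence(correct, group)
  expect_equal(res$statistic, 20, tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(res$statistic, chi2_closed_2x2(0, 10, 10, 0), tolerance = 1e-9)

  # perfectly independent table: chi2 = 0, p = 1
  correct2 <- rep(c(TRUE, FALSE), 10)
  res2 <- chi_squared_independence(correct2, rep(c("g1", "g2"), each = 10))
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)

  # random 2x2 tables against the closed form
  set.seed(5)
  for (rep in 1:20) {
    tab <- matrix(sample(1:30, 4, replace = TRUE), 2)
    correct <- rep(rep(c(FALSE, TRUE), 2), times = as.vector(tab))
    group <- rep(c("A", "A", "B", "B"), times = as.vector(tab))
    res <- chi_squared_independence(correct, group)
    expect_equal(res$statistic,
                 chi2_closed_2x2(tab[2, 1], tab[1, 1], tab[2, 2], tab[1, 2]),
                 tolerance = 1e-9)
  }
})

test_that("chi-squared degenerate and error paths behave as documented", {
  # three groups with identical correctness rates
  correct <- rep(c(TRUE, TRUE, FALSE), 3)
  group <- rep(c("a", "b", "c"), each = 3)
  expect_equal(chi_squared_independence(correct, group)$statistic, 0,
               tolerance = 1e-12)
  # single group is an error
  expect_error(chi_squared_independence(c(TRUE, FALSE), c("a", "a")),
               class = "taaft_validation_error")
  # all-correct input: degenerate zero statistic with warning
  expect_warning(
    res <- chi_squared_independence(rep(TRUE, 10), rep(c("a", "b"), 5)),
    "absent")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("one-way ANOVA matches closed forms and the t-squared identity", {
  # groups {0,1} and {2,3}: SSB = 4 (df 1), SSW = 1 (df 2) -> F = 8
  res <- one_way_anova(c(0, 1, 2, 3), c("a", "a", "b", "b"))
  expect_equal(res$statistic, 8, tolerance = 1e-9)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 2)

  # identical group means -> F = 0
  res0 <- one_way_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # two groups: F equals the squared equal-variance t statistic
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(12); g <- rep(c("a", "b"), times = c(5, 7))
    tt <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
    res <- one_way_anova(x, g)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
  expect_error(one_way_anova(c(1, 2), c("a", "a")),
               class = "taaft_validation_error")
})

test_that("fragility index equals the exhaustive flip search", {
  set.seed(21)
  found <- 0
  while (found < 8) {
    n1 <- sample(6:12, 1); n2 <- sample(6:12, 1)
    correct <- c(runif(n1) < 0.25, runif(n2) < 0.9)
    group <- rep(c("lowperf", "highperf"), times = c(n1, n2))
    p <- suppressWarnings(chi_squared_independence(correct, group)$p_value)
    if (is.na(p) || p > 0.05) next
    found <- found + 1
    for (lev in c("lowperf", "highperf")) {
      expect_equal(fragility_index(correct, group, lev),
                   fragility_brute(correct, group, lev, 0.05))
    }
  }
})

test_that("fragility index contract: definition bounds and error paths", {
  correct <- c(rep(FALSE, 9), TRUE, rep(TRUE, 9), FALSE)
  group <- rep(c("bad", "good"), each = 10)
  fi <- fragility_index(correct, group, "bad")
  expect_gte(fi, 1)
  # flipping fi-1 examples cannot cross alpha (oracle-checked minimality)
  expect_equal(fi, fragility_brute(correct, group, "bad", 0.05))
  # empty level -> absent
  expect_true(is.na(fragility_index(correct, group, "ghost")))
  # non-significant input is an error
  balanced <- rep(c(TRUE, FALSE), 10)
  expect_error(fragility_index(balanced, group, "bad"),
               class = "taaft_validation_error")
  # monotonicity: a larger alpha never increases the index
  fi_10 <- fragility_index(correct, group, "bad", alpha = 0.10)
  expect_gte(fi_10, fi)
})

test_that("audit flags an engineered specificity effect in the right stratum", {
  set.seed(31)
  n <- 240
  inst <- sample(c("ext_a", "ext_b", "ext_c"), n, replace = TRUE)
  label <- rbinom(n, 1, 0.2)
  manifest <- as_manifest(data.frame(
    clip_id = sprintf("c%03d", 1:n), patient_id = sprintf("p%03d", 1:n),
    label = label, institution = inst, vendor = "sonosite",
    probe = "phased_array", preset = "lung", depth_cm = 10, location = "ICU",
    fps = 30, path = "x", stringsAsFactors = FALSE))
  # negatives from ext_b get wrong (high) scores often: depressed specificity
  score <- ifelse(label == 1, 0.9,
                  ifelse(inst == "ext_b" & runif(n) < 0.6, 0.9, 0.1))
  preds <- data.frame(clip_id = manifest$clip_id, score = score)
  rep_ <- audit_subgroups(preds, manifest, fields = c("institution", "vendor"))
  chi <- rep_$tests[rep_$tests$test == "chi_squared" &
                      rep_$tests$field == "institution", ]
  expect_true(chi$significant[chi$stratum == "negative"])
  expect_false(isTRUE(chi$significant[chi$stratum == "positive"]))
  # fragility indices computed for the significant combination
  frag <- rep_$fragility
  expect_true(any(frag$field == "institution" & frag$stratum == "negative"))
  expect_true(all(frag$fragility_index >= 1, na.rm = TRUE))
  # level metrics carry per-level specificity
  lm <- rep_$level_metrics
  spec_b <- lm$specificity[lm$field == "institution" & lm$level == "ext_b"]
  spec_a <- lm$specificity[lm$field == "institution" & lm$level == "ext_a"]
  expect_lt(spec_b, spec_a)
  # determinism
  rep2 <- audit_subgroups(preds, manifest, fields = c("institution", "vendor"))
  expect_identical(rep_$tests, rep2$tests)
})

test_that("audit with uniform correctness reports nothing significant", {
  n <- 60
  manifest <- as_manifest(data.frame(
    clip_id = sprintf("c%03d", 1:n), patient_id = sprintf("p%03d", 1:n),
    label = rep(c(1, 0, 0, 0), 15),
    institution = rep(c("A", "B", "C"), each = 20), vendor = "v",
    probe = "phased_array", preset = "lung", depth_cm = 10, location = "ICU",
    fps = 30, path = "x", stringsAsFactors = FALSE))
  preds <- data.frame(clip_id = manifest$clip_id,
                      score = ifelse(manifest$label == 1, 0.9, 0.1))
  rep_ <- audit_subgroups(preds, manifest, fields = "institution")
  expect_false(any(rep_$tests$significant))
  expect_equal(nrow(rep_$fragility), 0)
})

test_that("audit validates fields and prediction joins", {
  m <- as_manifest(toy_records(4))
  preds <- data.frame(clip_id = m$clip_id, score = 0.5)
  expect_error(audit_subgroups(preds, m, fields = "shoe_size"),
               class = "taaft_config_error")
  bad <- data.frame(clip_id = "zzz", score = 0.5)
  expect_error(audit_subgroups(bad, m), class = "taaft_validation_error")
})
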