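test_that("build_matrix enforces the ten-feature schema with explicit missing", {
  empty <- build_matrix(data.frame())
  expect_equal(names(empty), names(feature_schema()))
  expect_equal(nrow(empty), 0L)

  uv <- data.frame(
    cnt = 3L, in_exac = TRUE, in_dbsnp_rare = FALSE, ma_category = "high",
    pp2_category = "benign", context = NA_character_, pattern = "CT",
    sample_frequency = 0.5, mean_vaf = 0.25, flank_weight = NA_real_,
    stringsAsFactors = FALSE
  )
  x <- build_matrix(uv)
  expect_equal(as.character(x$context), "missing")
  expect_true(is.na(x$flank_weight))
  expect_equal(levels(x$pattern), c("CA", "CG", "CT", "TA", "TC", "TG"))
  # out-of-schema category maps to missing with a warning
  uv$ma_category <- "catastrophic"
  expect_warning(x2 <- build_matrix(uv), "outside schema")
  expect_equal(as.character(x2$ma_category), "missing")
})

test_that("the feature matrix round-trips through the TSV interchange format", {
  sim <- simulate_cohort(tiny_config(601))
  uv <- collapse_cohort(sim_cohort_calls(sim), sim_sources(sim))
  path <- tempfile(fileext = ".tsv")
  write_unique_variants(uv, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  x1 <- build_matrix(uv)
  x2 <- build_matrix(back)
  expect_equal(x1, x2, ignore_attr = TRUE)
})

test_that("balanced sets have exact per-class counts and are reproducible", {
  set.seed(71)
  labels <- sample(rep(c("somatic", "germline"), c(5000, 5000)))
  sets <- balanced_training_sets(labels, n_sets = 10, per_class = 700, seed = 3)
  expect_length(sets, 10)
  for (s in sets) {
    expect_equal(sum(labels[s] == "somatic"), 700L)
    expect_equal(sum(labels[s] == "germline"), 700L)
    expect_false(anyDuplicated(s) > 0) # without replacement within a set
  }
  sets2 <- balanced_training_sets(labels, n_sets = 10, per_class = 700, seed = 3)
  expect_identical(sets, sets2)
  expect_warning(
    balanced_training_sets(labels[1:900], n_sets = 1, per_class = 700, seed = 1),
    "reduced"
  )
  expect_error(
    balanced_training_sets(rep("somatic", 10), n_sets = 1, seed = 1),
    "both classes"
  )
})

test_that("sample-based training sets take all somatic plus equal germline", {
  sim <- simulate_cohort(small_config(602))
  uv <- collapsed_labeled(sim)
  idx <- training_set_from_samples(uv, 10, seed = 5)
  lab <- uv$label[idx]
  expect_equal(sum(lab == "somatic"), sum(lab == "germline"))
  smap <- attr(uv, "sample_index")
  chosen <- attr(idx, "samples")
  som <- idx[uv$label[idx] == "somatic"]
  expect_true(all(vapply(smap[som], function(s) any(s %in% chosen), TRUE)))
  # every somatic allele in the chosen samples is present
  all_som <- which(uv$label == "somatic" &
    vapply(smap, function(s) any(s %in% chosen), TRUE))
  expect_setequal(unname(som), all_som)
  expect_identical(
    sort(training_set_from_samples(uv, 10, seed = 5)),
    sort(idx)
  )
  expect_error(training_set_from_samples(uv, 1000, seed = 1), "exceeds")
})

test_that("all classifier kinds fit a separable problem perfectly in-sample", {
  d <- separable_matrix(60)
  for (kind in c("naive_bayes", "tree_ensemble", "boosted_tree", "logistic")) {
    m <- isown_train(d$x, d$y, kind = kind, seed = 2)
    p <- predict(m, d$x)
    expect_equal(p$label, d$y, info = kind)
    expect_true(all(p$score >= 0 & p$score <= 1), info = kind)
  }
})

test_that("prediction is deterministic, thresholded at 0.5, and schema-checked", {
  d <- separable_matrix(40)
  m <- isown_train(d$x, d$y, kind = "naive_bayes", seed = 2)
  p1 <- predict(m, d$x)
  p2 <- predict(m, d$x)
  expect_identical(p1, p2)
  expect_equal(p1$label, ifelse(p1$score >= 0.5, "somatic", "germline"))
  expect_equal(nrow(predict(m, mat_subset(d$x, integer()))), 0L)
  broken <- d$x[, -3]
  expect_error(predict(m, broken), "in_dbsnp_rare")
  expect_error(isown_train(d$x, rep("somatic", nrow(d$x)), kind = "naive_bayes"),
    "both classes")
})

test_that("the naive Bayes posterior matches a hand-computed two-feature toy", {
  # balanced toy: one binary feature (in_exac), one Gaussian (mean_vaf);
  # everything else missing or constant so it cancels between classes
  uv <- data.frame(
    cnt = NA_real_, in_exac = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    in_dbsnp_rare = FALSE, ma_category = "missing", pp2_category = "missing",
    context = NA_character_, pattern = "CA",
    sample_frequency = NA_real_,
    mean_vaf = c(0.48, 0.52, 0.50, 0.20, 0.30, 0.25),
    flank_weight = NA_real_, stringsAsFactors = FALSE
  )
  y <- c("germline", "germline", "germline", "somatic", "somatic", "somatic")
  x <- build_matrix(uv)
  m <- isown_train(x, y, kind = "naive_bayes", seed = 1)

  # closed-form posterior with Laplace-1 smoothing and per-class Gaussians
  post <- function(exac, v) {
    lik <- function(cl) {
      vals <- uv$mean_vaf[y == cl]
      p_exac <- (sum(uv$in_exac[y == cl] == exac) + 1) / (3 + 2)
      p_exac * stats::dnorm(v, mean(vals), stats::sd(vals))
    }
    0.5 * lik("somatic") / (0.5 * lik("somatic") + 0.5 * lik("germline"))
  }
  q <- uv[c(1, 4), ]
  q$in_exac <- c(TRUE, FALSE)
  q$mean_vaf <- c(0.45, 0.27)
  got <- predict(m, build_matrix(q))$score
  want <- c(post(TRUE, 0.45), post(FALSE, 0.27))
  expect_equal(got, want, tolerance = 1e-9)

  # missing features drop out of the product: with the VAF masked the
  # posterior is driven by the membership term alone
  q$mean_vaf <- NA_real_
  got2 <- predict(m, build_matrix(q))$score
  p_e <- function(exac) {
    ps <- (sum(uv$in_exac[y == "somatic"] == exac) + 1) / 5
    pg <- (sum(uv$in_exac[y == "germline"] == exac) + 1) / 5
    ps / (ps + pg)
  }
  expect_equal(got2, c(p_e(TRUE), p_e(FALSE)), tolerance = 1e-9)
})

test_that("the six measures follow their defining formulas", {
  met <- classification_metrics(list(tp = 9, fn = 1, fp = 0, tn = 10))
  expect_equal(met$recall, 0.9)
  expect_equal(met$precision, 1.0)
  expect_equal(met$fpr, 0.0)
  expect_equal(met$accuracy, 0.95)
  expect_equal(met$f1, 2 * 1 * 0.9 / 1.9)
  # harmonic-mean fixed point
  m2 <- classification_metrics(list(tp = 1, fn = 1, fp = 1, tn = 1))
  expect_equal(m2$f1, 0.5)
  # undefined measures are NA, not zero
  m3 <- classification_metrics(list(tp = 0, fn = 0, fp = 0, tn = 5))
  expect_true(is.na(m3$recall) && is.na(m3$precision) && is.na(m3$f1))
  expect_equal(m3$accuracy, 1)
})

test_that("AUC equals the brute-force pair-counting probability", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c("germline", "germline", "somatic", "somatic")), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("somatic", "germline"), 5)), 0.5)
  expect_warning(a <- roc_auc(1:3, rep("somatic", 3)), "one class")
  expect_true(is.na(a))
  set.seed(81)
  scores <- round(runif(200), 2) # rounding forces ties
  labels <- sample(c("somatic", "germline"), 200, TRUE)
  pos <- scores[labels == "somatic"]
  neg <- scores[labels == "germline"]
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(roc_auc(scores, labels), mean(pairs))
})

test_that("model selection prefers AUC, then F1, then kind name", {
  r <- data.frame(
    kind = c("a_kind", "b_kind"), auc = c(0.99, 0.96), f1 = c(0.9, 0.95)
  )
  expect_equal(select_best(r), "a_kind")
  r2 <- data.frame(kind = c("b_kind", "a_kind"), auc = 0.95, f1 = c(0.93, 0.95))
  expect_equal(select_best(r2), "a_kind")
  r3 <- data.frame(kind = c("b_kind", "a_kind"), auc = 0.95, f1 = 0.9)
  expect_equal(select_best(r3), "a_kind")
  expect_equal(select_best(r[1, ]), "a_kind")
})

test_that("information gain matches direct entropy computations", {
  y <- rep(c("somatic", "germline"), each = 50)
  expect_equal(info_gain(y, y), 1.0) # feature identical to balanced label
  expect_equal(info_gain(rep("x", 100), y), 0.0)
  set.seed(91)
  f <- sample(letters[1:4], 400, TRUE, prob = c(.4, .3, .2, .1))
  yy <- ifelse(runif(400) < ifelse(f %in% c("a", "b"), 0.8, 0.3), "somatic", "germline")
  tab <- table(f, yy)
  h <- function(p) {
    p <- p[p > 0] / sum(p)
    -sum(p * log2(p))
  }
  want <- h(table(yy)) - sum(rowSums(tab) / 400 * apply(tab, 1, h))
  expect_equal(info_gain(f, yy), want)
  expect_gte(info_gain(f, yy), 0)
})

test_that("cross-validation is reproducible and perfect on separable data", {
  d <- separable_matrix(100)
  sets <- list(seq_along(d$y))
  cv <- cross_validate(d$x, d$y, sets, kind = "naive_bayes", seed = 4)
  expect_equal(cv$per_set$f1, 1.0)
  expect_equal(cv$per_set$fpr, 0.0)
  expect_equal(cv$per_set$auc, 1.0)
  cv2 <- cross_validate(d$x, d$y, sets, kind = "naive_bayes", seed = 4)
  expect_identical(cv$per_set, cv2$per_set)
})

test_that("catalogue count and sample frequency carry more information than context", {
  sim <- simulate_cohort(small_config(603))
  uv <- collapsed_labeled(sim)
  keep <- uv$label %in% c("somatic", "germline")
  x <- build_matrix(uv[keep, , drop = FALSE])
  y <- uv$label[keep]
  expect_gt(info_gain(x$cnt, y), info_gain(x$context, y))
  expect_gt(info_gain(x$sample_frequency, y), info_gain(x$context, y))
})
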