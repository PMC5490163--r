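#' Classifier feature schema
#'
#' The ten features presented to the classifiers. The common-polymorphism
#' membership is consumed by pre-labeling and is deliberately not part of
#' the schema; the rare-polymorphism membership is the feature.
#'
#' @return Named list: `name` -> list(type = "continuous"/"categorical",
#'   levels).
#' @export
feature_schema <- function() {
  list(
    cnt = list(type = "continuous"),
    in_exac = list(type = "categorical", levels = c("FALSE", "TRUE")),
    in_dbsnp_rare = list(type = "categorical", levels = c("FALSE", "TRUE")),
    ma_category = list(type = "categorical", levels = MA_LEVELS),
    pp2_category = list(type = "categorical", levels = PP2_LEVELS),
    context = list(type = "categorical", levels = CONTEXT_LEVELS),
    pattern = list(type = "categorical", levels = PATTERN_LEVELS),
    sample_frequency = list(type = "continuous"),
    mean_vaf = list(type = "continuous"),
    flank_weight = list(type = "continuous")
  )
}

#' Build the classifier feature matrix from unique variants
#'
#' Produces a data frame with exactly the ten schema columns in fixed
#' order. Missing values stay explicit: categorical missing becomes the
#' dedicated `"missing"` level (for features that define one) and
#' continuous missing stays `NA`; nothing is numerically imputed. A
#' category level outside the schema is mapped to missing with a warning.
#'
#' @param uv A `unique_variants` data frame (or any data frame carrying the
#'   schema columns).
#' @return Data frame with attribute `"schema"`; factors carry the full
#'   fixed level sets.
#' @export
build_matrix <- function(uv) {
  sch <- feature_schema()
  out <- vector("list", length(sch))
  names(out) <- names(sch)
  n <- nrow(uv)
  for (f in names(sch)) {
    spec <- sch[[f]]
    v <- if (f %in% names(uv)) uv[[f]] else rep(NA, n)
    if (spec$type == "continuous") {
      out[[f]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      if ("missing" %in% spec$levels) v[is.na(v)] <- "missing"
      bad <- !is.na(v) & !v %in% spec$levels
      if (any(bad)) {
        warning(sprintf(
          "feature '%s': %d value(s) outside schema levels mapped to missing",
          f, sum(bad)
        ), call. = FALSE)
        v[bad] <- if ("missing" %in% spec$levels) "missing" else NA_character_
      }
      out[[f]] <- factor(v, levels = spec$levels)
    }
  }
  m <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(m, "schema") <- sch
  m
}

check_schema <- function(newdata, schema) {
  missing_cols <- setdiff(names(schema), names(newdata))
  if (length(missing_cols)) {
    stop("feature matrix lacks schema column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in names(schema)) {
    if (schema[[f]]$type == "categorical" &&
      !identical(levels(newdata[[f]]), schema[[f]]$levels)) {
      stop("schema mismatch in column: ", f, call. = FALSE)
    }
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# training-set construction

#' Balanced training sets for cross-validation
#'
#' Draws `n_sets` class-balanced sets, each with `per_class` somatic and
#' `per_class` germline variants sampled without replacement within a set.
#' If a class has fewer than `per_class` members, `per_class` is reduced to
#' the minority size with a warning.
#'
#' @param labels Character vector of `somatic`/`germline` labels for the
#'   labeled unique variants.
#' @param n_sets Number of sets (default 1000).
#' @param per_class Variants per class per set (default 700).
#' @param seed Run-level seed.
#' @return List of integer index vectors into `labels`.
#' @export
balanced_training_sets <- function(labels, n_sets = 1000, per_class = 700,
                                   seed = 1) {
  idx_s <- which(labels == "somatic")
  idx_g <- which(labels == "germline")
  if (!length(idx_s) || !length(idx_g)) {
    stop("both classes must be present to build balanced sets", call. = FALSE)
  }
  m <- min(length(idx_s), length(idx_g))
  if (m < per_class) {
    warning(sprintf(
      "per_class reduced from %d to minority class size %d",
      per_class, m
    ), call. = FALSE)
    per_class <- m
  }
  set.seed(substream_seed(seed, "balanced_sets"))
  lapply(seq_len(n_sets), function(i) {
    c(
      sample(idx_s, per_class),
      sample(idx_g, per_class)
    )
  })
}

#' Training set from a chosen number of cohort samples
#'
#' Emulates training-set growth with cohort size: all somatic unique
#' variants called in the chosen samples, plus an equal number of randomly
#' selected germline unique variants (drawn from germlines called in those
#' samples; topped up from the remaining germlines if too few).
#'
#' @param uv Labeled `unique_variants` (needs `label` and the
#'   `"sample_index"` attribute from [collapse_cohort()]).
#' @param n_samples Number of training samples to use.
#' @param sample_pool Sample ids eligible for training (default: the whole
#'   cohort).
#' @param candidates Row indices eligible for training (default: all rows).
#'   Typically the variants that were not pre-labeled, so the balanced draw
#'   is made among the alleles the classifier will actually see.
#' @param seed Run-level seed.
#' @return Integer index vector into `uv`, with the chosen sample ids in
#'   `attr(, "samples")`.
#' @export
training_set_from_samples <- function(uv, n_samples, sample_pool = NULL,
                                      candidates = NULL, seed = 1) {
  smap <- attr(uv, "sample_index")
  if (is.null(smap)) stop("uv lacks the sample_index attribute", call. = FALSE)
  all_samples <- sample_pool %||% sort(unique(unlist(smap)))
  if (n_samples > length(all_samples)) {
    stop("n_samples exceeds available training samples", call. = FALSE)
  }
  ok <- rep(FALSE, nrow(uv))
  ok[candidates %||% seq_len(nrow(uv))] <- TRUE
  set.seed(substream_seed(seed, "train_samples"))
  chosen <- sample(all_samples, n_samples)
  in_chosen <- vapply(smap, function(s) any(s %in% chosen), TRUE)
  som <- which(uv$label == "somatic" & in_chosen & ok)
  if (!length(som)) stop("no somatic variants in the chosen samples", call. = FALSE)
  germ_pool <- which(uv$label == "germline" & in_chosen & ok)
  if (length(germ_pool) < length(som)) {
    extra <- which(uv$label == "germline" & !in_chosen & ok)
    germ_pool <- c(germ_pool, sample(extra, min(
      length(extra),
      length(som) - length(germ_pool)
    )))
  }
  germ <- if (length(germ_pool) > length(som)) {
    sample(germ_pool, length(som))
  } else {
    germ_pool
  }
  out <- c(som, germ)
  attr(out, "samples") <- chosen
  out
}

# ---------------------------------------------------------------------------
# naive Bayes with mixed categorical/Gaussian likelihoods

nb_fit <- function(x, y, laplace = 1, var_floor = 1e-6) {
  schema <- attr(x, "schema")
  classes <- c("somatic", "germline")
  prior <- c(mean(y == "somatic"), mean(y == "germline"))
  names(prior) <- classes
  params <- list()
  for (f in names(schema)) {
    v <- x[[f]]
    if (schema[[f]]$type == "categorical") {
      lev <- setdiff(levels(v), "missing") # missing is omitted, not a category
      tabs <- lapply(classes, function(cl) {
        obs <- v[y == cl & !is.na(v) & v != "missing"]
        cnt <- table(factor(obs, levels = lev))
        (cnt + laplace) / (sum(cnt) + laplace * length(lev))
      })
      names(tabs) <- classes
      params[[f]] <- list(type = "categorical", levels = lev, prob = tabs)
    } else {
      stats_by <- lapply(classes, function(cl) {
        obs <- v[y == cl & !is.na(v)]
        if (length(obs) < 2) {
          c(mean = if (length(obs)) mean(obs) else 0, var = 1)
        } else {
          c(mean = mean(obs), var = max(stats::var(obs), var_floor))
        }
      })
      names(stats_by) <- classes
      params[[f]] <- list(type = "continuous", stats = stats_by)
    }
  }
  list(prior = prior, params = params, laplace = laplace)
}

nb_score <- function(fit, x) {
  n <- nrow(x)
  ll <- matrix(rep(log(fit$prior), each = n), nrow = n)
  colnames(ll) <- names(fit$prior)
  for (f in names(fit$params)) {
    p <- fit$params[[f]]
    v <- x[[f]]
    if (p$type == "categorical") {
      v <- as.character(v)
      use <- !is.na(v) & v != "missing" & v %in% p$levels
      if (any(use)) {
        for (cl in colnames(ll)) {
          ll[use, cl] <- ll[use, cl] + log(as.numeric(p$prob[[cl]][v[use]]))
        }
      }
    } else {
      use <- !is.na(v)
      if (any(use)) {
        for (cl in colnames(ll)) {
          s <- p$stats[[cl]]
          ll[use, cl] <- ll[use, cl] +
            stats::dnorm(v[use], s["mean"], sqrt(s["var"]), log = TRUE)
        }
      }
    }
  }
  # posterior for the somatic class; scores over classes sum to 1
  1 / (1 + exp(ll[, "germline"] - ll[, "somatic"]))
}

# ---------------------------------------------------------------------------
# encodings for the tree / linear kinds

#' @noRd
encode_trees <- function(x) {
  # categorical: missing as a dedicated level (already in the factors);
  # continuous: sentinel + indicator, no numeric imputation
  out <- x
  for (f in names(out)) {
    if (is.numeric(out[[f]]) && anyNA(out[[f]])) {
      out[[paste0(f, "_missing")]] <- factor(ifelse(is.na(out[[f]]), "yes", "no"),
        levels = c("no", "yes")
      )
      out[[f]][is.na(out[[f]])] <- -1
    } else if (is.numeric(out[[f]])) {
      out[[paste0(f, "_missing")]] <- factor("no", levels = c("no", "yes"))
    }
  }
  out
}

#' @noRd
encode_onehot <- function(x) {
  cols <- list()
  for (f in names(x)) {
    v <- x[[f]]
    if (is.numeric(v)) {
      cols[[f]] <- v # NA kept: boosted trees route missing natively
    } else {
      for (lev in levels(v)) {
        cols[[paste0(f, "=", lev)]] <- as.numeric(v == lev)
      }
    }
  }
  do.call(cbind, cols)
}

# ---------------------------------------------------------------------------
# the fitted-model interface

#' Train a somatic/germline classifier
#'
#' Fits one of the supported classifier kinds on a feature matrix from
#' [build_matrix()]. `naive_bayes` (Laplace-smoothed categorical and
#' Gaussian continuous likelihoods, missing features omitted from the
#' product) is implemented in the package; `tree_ensemble` is a random
#' forest, `boosted_tree` a gradient-boosted tree ensemble standing in for
#' boosted decision-tree learners, and `logistic` a baseline linear model.
#' Tree and linear kinds receive categorical missing as a dedicated level
#' and continuous missing as sentinel-plus-indicator (boosted trees route
#' `NA` natively).
#'
#' @param x Feature matrix (data frame) from [build_matrix()].
#' @param y Character vector of labels (`somatic`/`germline`).
#' @param kind One of `"naive_bayes"`, `"tree_ensemble"`, `"boosted_tree"`,
#'   `"logistic"`.
#' @param seed Run-level seed (forest bootstrap / boosting substreams).
#' @param num_trees Trees for the ensemble kinds.
#' @return An `isown_model` object.
#' @seealso [predict.isown_model()], [cross_validate()]
#' @export
isown_train <- function(x, y, kind = c(
                          "naive_bayes", "tree_ensemble",
                          "boosted_tree", "logistic"
                        ),
                        seed = 1, num_trees = 300) {
  kind <- match.arg(kind)
  schema <- attr(x, "schema") %||% feature_schema()
  check_schema(x, schema)
  y <- as.character(y)
  if (nrow(x) == 0 || length(unique(y)) < 2) {
    stop("training set must be non-empty with both classes", call. = FALSE)
  }
  if (!all(y %in% c("somatic", "germline"))) {
    stop("labels must be somatic/germline", call. = FALSE)
  }
  fit <- switch(kind,
    naive_bayes = nb_fit(x, y),
    tree_ensemble = {
      xt <- encode_trees(x)
      ranger::ranger(
        x = xt, y = factor(y, levels = c("germline", "somatic")),
        probability = TRUE, num.trees = num_trees,
        respect.unordered.factors = "order",
        seed = substream_seed(seed, "forest"), num.threads = 1
      )
    },
    boosted_tree = {
      xm <- encode_onehot(x)
      set.seed(substream_seed(seed, "boost"))
      dtrain <- xgboost::xgb.DMatrix(xm,
        label = as.numeric(y == "somatic"),
        nthread = 1
      )
      xgboost::xgb.train(
        params = list(
          objective = "binary:logistic", max_depth = 4,
          eta = 0.3, nthread = 1, seed = substream_seed(seed, "boost")
        ),
        data = dtrain, nrounds = 100, verbose = 0
      )
    },
    logistic = {
      xt <- encode_trees(x)
      xm <- encode_onehot(xt)
      set.seed(substream_seed(seed, "logistic"))
      suppressWarnings(stats::glm.fit(
        x = cbind(1, xm), y = as.numeric(y == "somatic"),
        family = stats::binomial()
      ))$coefficients
    }
  )
  structure(
    list(
      kind = kind,
      feature_schema = schema,
      fit = fit,
      provenance = list(
        seed = seed, n_train = nrow(x),
        class_counts = table(y), trained = format(Sys.time(), "%Y-%m-%d")
      )
    ),
    class = "isown_model"
  )
}

#' Predict somatic scores and labels for new variants
#'
#' @param object An `isown_model`.
#' @param newdata Feature matrix from [build_matrix()] (schema checked).
#' @param threshold Score threshold for the hard label (default 0.5;
#'   `score >= threshold` is somatic).
#' @param ... Unused.
#' @return Data frame with `score` (somatic posterior in \[0, 1\]) and
#'   `label`.
#' @export
predict.isown_model <- function(object, newdata, threshold = 0.5, ...) {
  check_schema(newdata, object$feature_schema)
  if (nrow(newdata) == 0) {
    return(data.frame(score = numeric(), label = character(), stringsAsFactors = FALSE))
  }
  score <- switch(object$kind,
    naive_bayes = nb_score(object$fit, newdata),
    tree_ensemble = {
      p <- stats::predict(object$fit, data = encode_trees(newdata), num.threads = 1)
      p$predictions[, "somatic"]
    },
    boosted_tree = {
      stats::predict(
        object$fit,
        xgboost::xgb.DMatrix(encode_onehot(newdata), nthread = 1)
      )
    },
    logistic = {
      xm <- cbind(1, encode_onehot(encode_trees(newdata)))
      beta <- object$fit
      beta[is.na(beta)] <- 0
      stats::plogis(as.numeric(xm %*% beta))
    }
  )
  score <- pmin(pmax(score, 0), 1)
  data.frame(
    score = score,
    label = ifelse(score >= threshold, "somatic", "germline"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.isown_model <- function(x, ...) {
  cat(sprintf(
    "Somatic/germline classifier (%s), trained on %d variants (%s)\n",
    x$kind, x$provenance$n_train,
    paste(sprintf("%s=%d", names(x$provenance$class_counts), x$provenance$class_counts),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' @export
summary.isown_model <- function(object, ...) {
  print(object)
  cat("Features:", paste(names(object$feature_schema), collapse = ", "), "\n")
  cat("Seed:", object$provenance$seed, "\n")
  invisible(object)
}

#' Persist / restore a trained model with its schema and provenance
#' @param model An `isown_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "isown_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "isown_model")) stop("not an isown model file: ", path, call. = FALSE)
  m
}

# ---------------------------------------------------------------------------
# performance measures

#' Confusion counts with somatic as the positive class
#' @param predicted,truth Character vectors of `somatic`/`germline` labels.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  list(
    tp = sum(predicted == "somatic" & truth == "somatic"),
    fp = sum(predicted == "somatic" & truth == "germline"),
    tn = sum(predicted == "germline" & truth == "germline"),
    fn = sum(predicted == "germline" & truth == "somatic")
  )
}

#' The six performance measures (all but AUC) from confusion counts
#'
#' Recall TP/(TP+FN); precision TP/(TP+FP); F1 the harmonic mean of the
#' two; false positive rate FP/(FP+TN); accuracy (TP+TN)/total. A measure
#' whose denominator is zero is reported as `NA` (undefined), never zeroed.
#'
#' @param cc Confusion counts from [confusion_counts()].
#' @return Data frame with `recall, precision, f1, fpr, accuracy`.
#' @export
classification_metrics <- function(cc) {
  div <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- div(cc$tp, cc$tp + cc$fn)
  precision <- div(cc$tp, cc$tp + cc$fp)
  f1 <- if (!is.na(recall) && !is.na(precision) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  data.frame(
    recall = recall, precision = precision, f1 = f1,
    fpr = div(cc$fp, cc$fp + cc$tn),
    accuracy = div(cc$tp + cc$tn, cc$tp + cc$fn + cc$tn + cc$fp)
  )
}

#' Area under the ROC curve
#'
#' The probability that the classifier scores a random somatic variant
#' above a random germline one; computed by the rank (Mann-Whitney)
#' formulation with ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Character labels (`somatic` positive).
#' @return AUC in \[0, 1\], or `NA` with a warning when only one class is
#'   present.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == "somatic"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pick the best classifier kind from aggregate reports
#'
#' Highest mean AUC wins; ties break by mean F1, then lexicographically by
#' kind name.
#'
#' @param reports Data frame with columns `kind`, `auc`, `f1`.
#' @return The winning kind (character scalar).
#' @export
select_best <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  o <- order(-reports$auc, -reports$f1, reports$kind)
  reports$kind[o[1]]
}

# ---------------------------------------------------------------------------
# cross-validation

stratified_folds <- function(y, folds, seed) {
  set.seed(substream_seed(seed, "folds"))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < folds) {
      stop("a class has fewer members than folds; cannot stratify", call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Tenfold cross-validation over balanced training sets
#'
#' For each balanced set, assigns stratified folds, trains on the in-fold
#' variants and scores the held-out fold; metrics (including AUC) are
#' computed on the pooled out-of-fold predictions of that set. The
#' aggregate reports the mean over sets with a normal-approximation 95% CI.
#'
#' @param x Feature matrix from [build_matrix()].
#' @param y Labels aligned with `x`.
#' @param sets List of index vectors (e.g. from
#'   [balanced_training_sets()]).
#' @param kind Classifier kind, as in [isown_train()].
#' @param folds Number of folds (default 10).
#' @param seed Run-level seed.
#' @param num_trees Trees for ensemble kinds.
#' @return List with `per_set` (data frame of per-set metrics) and
#'   `aggregate` (mean, ci_lo, ci_hi per measure).
#' @export
cross_validate <- function(x, y, sets, kind = "naive_bayes", folds = 10,
                           seed = 1, num_trees = 150) {
  per_set <- lapply(seq_along(sets), function(i) {
    idx <- sets[[i]]
    xs <- x[idx, , drop = FALSE]
    attr(xs, "schema") <- attr(x, "schema") %||% feature_schema()
    ys <- y[idx]
    fold <- stratified_folds(ys, folds, seed + i)
    scores <- numeric(length(ys))
    for (k in seq_len(folds)) {
      tr <- fold != k
      model <- isown_train(xs[tr, , drop = FALSE], ys[tr],
        kind = kind,
        seed = seed + i, num_trees = num_trees
      )
      xk <- xs[!tr, , drop = FALSE]
      attr(xk, "schema") <- attr(xs, "schema")
      scores[!tr] <- predict(model, xk)$score
    }
    cc <- confusion_counts(ifelse(scores >= 0.5, "somatic", "germline"), ys)
    cbind(set = i, classification_metrics(cc), auc = roc_auc(scores, ys))
  })
  per_set <- do.call(rbind, per_set)
  measures <- c("recall", "precision", "f1", "fpr", "accuracy", "auc")
  agg <- do.call(rbind, lapply(measures, function(m) {
    v <- per_set[[m]]
    mu <- mean(v, na.rm = TRUE)
    se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    data.frame(
      measure = m, mean = mu,
      ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se
    )
  }))
  list(per_set = per_set, aggregate = agg)
}

# ---------------------------------------------------------------------------
# feature relevance

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a feature for the somatic/germline label
#'
#' `H(label) - H(label | feature)` in bits. Continuous features are
#' discretized into equal-frequency bins (quantile cut points, duplicates
#' merged); missing values form their own category.
#'
#' @param feature Numeric or categorical feature vector.
#' @param labels Binary labels.
#' @param bins Equal-frequency bins for continuous features (default 10).
#' @return Information gain in bits (non-negative).
#' @export
info_gain <- function(feature, labels, bins = 10) {
  if (is.numeric(feature)) {
    br <- unique(stats::quantile(feature,
      probs = seq(0, 1, length.out = bins + 1),
      na.rm = TRUE
    ))
    f <- if (length(br) > 1) {
      as.character(cut(feature, breaks = br, include.lowest = TRUE))
    } else {
      rep("all", length(feature))
    }
  } else {
    f <- as.character(feature)
  }
  f[is.na(f)] <- "missing"
  h_y <- entropy_bits(table(labels))
  tab <- table(f, labels)
  h_cond <- sum(rowSums(tab) / sum(tab) * apply(tab, 1, entropy_bits))
  max(h_y - h_cond, 0)
}

#' Information gain for every schema feature
#' @param x Feature matrix from [build_matrix()].
#' @param labels Labels aligned with `x`.
#' @param bins Passed to [info_gain()].
#' @return Data frame sorted by decreasing gain.
#' @export
info_gain_all <- function(x, labels, bins = 10) {
  g <- vapply(names(feature_schema()), function(f) info_gain(x[[f]], labels, bins), 0)
  out <- data.frame(feature = names(g), gain_bits = as.numeric(g))
  out[order(-out$gain_bits), ]
}
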