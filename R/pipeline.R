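#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's knobs and input paths. Can be built directly or
#' loaded from a YAML file; the full configuration is serialized into each
#' output's provenance header so a run can be reproduced from its outputs.
#'
#' @param vcf Character vector of per-sample VCF paths (or a glob).
#' @param cosmic,dbsnp_common,dbsnp_rare,exac,impact,genome Annotation
#'   source paths.
#' @param truth Optional truth-label TSV (training / evaluation).
#' @param model Model file path (output of train, input of predict).
#' @param out Output path or directory.
#' @param min_depth,require_pass,drop_homozygous,coding_only,include_silent
#'   Filter settings, as in [filter_config()].
#' @param flank_window_bp,ci_level Flanking-feature settings.
#' @param prelabel_cnt_threshold Pre-labeling catalogue-count threshold.
#' @param classifier Classifier kind.
#' @param n_train_samples Training samples for `train` mode (default: all).
#' @param n_sets,per_class Balanced-set settings for `crossval` mode.
#' @param seed Run-level seed.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf = NULL, cosmic = NULL, dbsnp_common = NULL,
                       dbsnp_rare = NULL, exac = NULL, impact = NULL,
                       genome = NULL, truth = NULL, model = NULL, out = NULL,
                       min_depth = 10, require_pass = TRUE,
                       drop_homozygous = FALSE, coding_only = TRUE,
                       include_silent = FALSE, flank_window_bp = 2e6,
                       ci_level = 0.95, prelabel_cnt_threshold = 100,
                       classifier = "naive_bayes", n_train_samples = NULL,
                       n_sets = 1000, per_class = 700, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}

pipeline_sources <- function(config, need_genome = TRUE) {
  missing_src <- c()
  if (is.null(config$impact)) missing_src <- c(missing_src, "impact")
  if (need_genome && is.null(config$genome)) missing_src <- c(missing_src, "genome")
  if (length(missing_src)) {
    stop("missing annotation source(s): ", paste(missing_src, collapse = ", "),
      call. = FALSE
    )
  }
  load_annotation_sources(
    cosmic = config$cosmic, dbsnp_common = config$dbsnp_common,
    dbsnp_rare = config$dbsnp_rare, exac = config$exac,
    impact = config$impact, genome = config$genome
  )
}

# filter -> annotate -> features -> collapse -> prelabel, with stage logging
pipeline_collapse <- function(config) {
  sources <- pipeline_sources(config)
  fc <- filter_config(
    config$min_depth, config$require_pass, config$drop_homozygous,
    config$coding_only, config$include_silent
  )
  paths <- config$vcf
  if (length(paths) == 1 && grepl("[*?]", paths)) paths <- Sys.glob(paths)
  cohort <- read_cohort(paths, fc, sources$impact)
  stage_log(
    "filter", "%d samples, %d calls kept, %d dropped",
    cohort$n_samples, nrow(cohort$calls), sum(cohort$filter_log)
  )
  uv <- collapse_cohort(cohort, sources, config$flank_window_bp, config$ci_level)
  stage_log("collapse", "%d unique variants from %d calls", nrow(uv), nrow(cohort$calls))
  uv <- prelabel_variants(uv, config$prelabel_cnt_threshold)
  stage_log(
    "prelabel", "somatic %d, germline %d, to classifier %d",
    sum(uv$prelabel == "somatic"), sum(uv$prelabel == "germline"),
    sum(uv$prelabel == "unlabeled")
  )
  uv
}

#' Run the pipeline end to end
#'
#' Stage order is fixed: filter, annotate, feature computation, collapse,
#' prelabel, classify. Per-stage variant counts are logged to stderr.
#'
#' Modes: `train` fits a classifier on truth-labeled collapsed variants and
#' saves it; `predict` labels a cohort with a trained model (pre-labeled
#' variants keep their rule-based label and never reach the classifier);
#' `crossval` evaluates classifier kinds on balanced sets and reports
#' aggregate measures; `evaluate` scores a predictions file against truth
#' labels.
#'
#' @param config A [run_config()] (or YAML path).
#' @param mode One of `"train"`, `"predict"`, `"crossval"`, `"evaluate"`.
#' @return Mode-dependent: the model (train), the predictions data frame
#'   (predict), the cross-validation report (crossval), or a metrics data
#'   frame (evaluate).
#' @export
run_pipeline <- function(config, mode = c("train", "predict", "crossval", "evaluate")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_run_config(config)

  if (mode == "evaluate") {
    stopifnot(!is.null(config$truth), !is.null(config$out))
    preds <- read_predictions(config$out)
    truth <- utils::read.delim(config$truth, stringsAsFactors = FALSE)
    if (nrow(preds) == 0) {
      warning("no predictions to evaluate; empty report", call. = FALSE)
      return(classification_metrics(confusion_counts(character(), character())))
    }
    cc <- truth_confusion(preds, truth)
    met <- cbind(classification_metrics(cc), auc = NA_real_)
    if (length(unique(preds$predicted_label)) > 0 && all(!is.na(preds$score))) {
      tk <- allele_key(truth$chrom, truth$pos, truth$ref, truth$alt)
      lab <- truth$label[match(
        allele_key(preds$chrom, preds$pos, preds$ref, preds$alt), tk
      )]
      keep <- lab %in% c("somatic", "germline")
      if (length(unique(lab[keep])) == 2) met$auc <- roc_auc(preds$score[keep], lab[keep])
    }
    return(met)
  }

  uv <- pipeline_collapse(config)

  if (mode == "crossval") {
    truth <- utils::read.delim(config$truth, stringsAsFactors = FALSE)
    uv <- attach_labels(uv, truth)
    lab <- uv$label[uv$prelabel == "unlabeled"]
    x <- build_matrix(uv[uv$prelabel == "unlabeled", , drop = FALSE])
    usable <- lab %in% c("somatic", "germline")
    sets <- balanced_training_sets(
      ifelse(usable, lab, "drop")[usable],
      n_sets = config$n_sets, per_class = config$per_class, seed = config$seed
    )
    xs <- x[usable, , drop = FALSE]
    attr(xs, "schema") <- attr(x, "schema")
    res <- cross_validate(xs, lab[usable], sets,
      kind = config$classifier,
      seed = config$seed
    )
    stage_log("crossval", "%s mean AUC %.4f", config$classifier,
      res$aggregate$mean[res$aggregate$measure == "auc"])
    return(res)
  }

  if (mode == "train") {
    stopifnot(!is.null(config$truth))
    truth <- utils::read.delim(config$truth, stringsAsFactors = FALSE)
    uv <- attach_labels(uv, truth)
    cls <- uv$prelabel == "unlabeled" & uv$label %in% c("somatic", "germline")
    idx <- if (!is.null(config$n_train_samples)) {
      training_set_from_samples(uv, config$n_train_samples,
        candidates = which(cls), seed = config$seed
      )
    } else {
      which(cls)
    }
    x <- build_matrix(uv[idx, , drop = FALSE])
    model <- isown_train(x, uv$label[idx], kind = config$classifier, seed = config$seed)
    stage_log("train", "%s on %d variants", config$classifier, length(idx))
    if (!is.null(config$model)) save_model(model, config$model)
    return(model)
  }

  # predict
  stopifnot(!is.null(config$model))
  model <- load_model(config$model)
  cls <- uv$prelabel == "unlabeled"
  x <- build_matrix(uv[cls, , drop = FALSE])
  pr <- predict(model, x)
  out <- uv[c("chrom", "pos", "ref", "alt", "n_samples_with_call")]
  out$predicted_label <- uv$prelabel
  out$score <- ifelse(uv$prelabel == "somatic", 1, 0)
  out$provenance <- "prelabeled"
  out$predicted_label[cls] <- pr$label
  out$score[cls] <- pr$score
  out$provenance[cls] <- "classified"
  stage_log(
    "predict", "%d somatic / %d germline (classified %d, prelabeled %d)",
    sum(out$predicted_label == "somatic"), sum(out$predicted_label == "germline"),
    sum(cls), sum(!cls)
  )
  if (!is.null(config$out)) write_predictions(out, config$out)
  out
}
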