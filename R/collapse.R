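#' Collapse per-sample flanking assessments into a weight
#'
#' Across the samples carrying a variant, the weight is the fraction of
#' germline-like assessments over the total number of carrier samples;
#' not-applicable assessments stay in the denominator. If every assessment
#' is not applicable the weight itself is missing.
#'
#' @param assessments Character vector of `germline_like`, `somatic_like`,
#'   `not_applicable`.
#' @return Fraction in \[0, 1\], or `NA` if all assessments are
#'   not applicable.
#' @export
flank_weight <- function(assessments) {
  stopifnot(length(assessments) > 0)
  if (all(assessments == "not_applicable")) {
    return(NA_real_)
  }
  sum(assessments == "germline_like") / length(assessments)
}

#' Resolve per-sample truth labels for one collapsed allele
#'
#' The collapsing assumption is that an allele is somatic or germline across
#' all samples; alleles whose paired-caller labels disagree violate it and
#' are excluded from training and from accuracy denominators.
#'
#' @param labels Character vector of `somatic` / `germline` labels.
#' @return `"somatic"`, `"germline"`, or `"excluded"`.
#' @export
resolve_label <- function(labels) {
  stopifnot(length(labels) > 0, all(labels %in% c("somatic", "germline")))
  u <- unique(labels)
  if (length(u) == 1) u else "excluded"
}

#' Collapse a cohort call set into unique variants with the ten features
#'
#' Aggregates all calls sharing (chrom, pos, ref, alt) into one unique
#' variant: sample frequency is carriers over cohort size, the collapsed VAF
#' is the unweighted mean of the per-call VAFs (a single call keeps its
#' actual VAF), and the per-call flanking assessments are collapsed by
#' [flank_weight()]. External annotations and the sequence context are
#' per-allele and identical across carriers by construction.
#'
#' @param cohort A `cohort_calls` object from [read_cohort()].
#' @param sources An `annotation_sources` object (genome required for the
#'   sequence context).
#' @param flank_window_bp Flank search window (default 2e6).
#' @param ci_level Confidence level for VAF intervals (default 0.95).
#' @return A `unique_variants` data frame: allele key columns,
#'   `n_samples_with_call`, `sample_frequency`, `mean_vaf`, `flank_weight`,
#'   the annotation columns, `context`, `pattern`. Cohort size is carried in
#'   `attr(, "n_samples")`; the per-allele carrier sample ids in
#'   `attr(, "sample_index")`.
#' @export
collapse_cohort <- function(cohort, sources, flank_window_bp = 2e6,
                            ci_level = 0.95) {
  stopifnot(inherits(cohort, "cohort_calls"))
  calls <- cohort$calls
  if (nrow(calls) == 0) {
    uv <- empty_unique_variants()
    attr(uv, "n_samples") <- cohort$n_samples
    attr(uv, "sample_index") <- list()
    return(uv)
  }

  # reference consistency: one ref base per genomic position
  pos_key <- paste(calls$chrom, calls$pos, sep = ":")
  ref_per_pos <- tapply(calls$ref, pos_key, function(r) length(unique(r)))
  if (any(ref_per_pos > 1)) {
    stop(
      "conflicting reference alleles at position(s): ",
      paste(utils::head(names(ref_per_pos)[ref_per_pos > 1], 5), collapse = ", "),
      call. = FALSE
    )
  }

  # per-call intrinsic features
  call_vaf <- vaf(calls$alt_count, calls$depth)
  assess <- rep("not_applicable", nrow(calls))
  for (sid in cohort$sample_ids) {
    rows <- which(calls$sample_id == sid)
    if (length(rows)) {
      assess[rows] <- flanking_assessments(
        calls[rows, , drop = FALSE],
        sources$common, flank_window_bp, ci_level
      )
    }
  }

  key <- allele_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  grp <- match(key, unique(key))
  first <- which(!duplicated(key))
  n_call <- tabulate(grp, nbins = length(first))

  uv <- data.frame(
    chrom = calls$chrom[first],
    pos = calls$pos[first],
    ref = calls$ref[first],
    alt = calls$alt[first],
    n_samples_with_call = n_call,
    sample_frequency = n_call / cohort$n_samples,
    mean_vaf = as.vector(rowsum(call_vaf, grp)) / n_call,
    flank_weight = as.vector(tapply(assess, grp, flank_weight)),
    stringsAsFactors = FALSE
  )
  ann <- annotate_alleles(uv, sources)
  uv <- cbind(uv, ann)
  uv$context <- sequence_context(sources$genome, uv$chrom, uv$pos)
  uv$pattern <- substitution_pattern(uv$ref, uv$alt)
  class(uv) <- c("unique_variants", "data.frame")
  attr(uv, "n_samples") <- cohort$n_samples
  attr(uv, "sample_index") <- split(calls$sample_id, grp)
  uv
}

empty_unique_variants <- function() {
  uv <- data.frame(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    n_samples_with_call = integer(), sample_frequency = numeric(),
    mean_vaf = numeric(), flank_weight = numeric(),
    cnt = integer(), in_exac = logical(), in_dbsnp_common = logical(),
    in_dbsnp_rare = logical(), ma_category = character(),
    pp2_category = character(), coding_effect = character(),
    context = character(), pattern = character(), stringsAsFactors = FALSE
  )
  class(uv) <- c("unique_variants", "data.frame")
  uv
}

#' Attach collapsed truth labels to unique variants
#'
#' @param uv A `unique_variants` data frame.
#' @param truth Data frame with `chrom, pos, ref, alt, label`
#'   (`somatic`/`germline`), either allele-level (one row per allele) or
#'   per-sample (multiple rows per allele; disagreements resolve to
#'   `excluded` via [resolve_label()]).
#' @return `uv` with a `label` column (`somatic`, `germline`, `excluded`,
#'   or `unlabeled` for alleles the truth set does not cover).
#' @export
attach_labels <- function(uv, truth) {
  tk <- allele_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  resolved <- tapply(truth$label, tk, resolve_label)
  k <- allele_key(uv$chrom, uv$pos, uv$ref, uv$alt)
  lab <- as.vector(resolved[k])
  lab[is.na(lab)] <- "unlabeled"
  uv$label <- lab
  uv
}

#' Dump the collapsed feature matrix to TSV (classifier interchange format)
#' @param uv A `unique_variants` data frame.
#' @param path Output path.
#' @export
write_unique_variants <- function(uv, path) {
  utils::write.table(as.data.frame(uv), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
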