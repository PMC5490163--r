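#' Quality-filter configuration for cohort ingestion
#'
#' Mirrors the filtering applied to tumor-only call sets before
#' classification: minimum read depth of 10x, caller PASS status, single
#' nucleotide substitutions only, no `N` reference alleles, and restriction
#' to coding (by default non-silent) variants. Homozygous calls are only
#' dropped on request; several public paired call sets ship with homozygous
#' variants already removed, so the step is a dataset-harmonization knob
#' rather than part of the method.
#'
#' @param min_depth Minimum total read depth (default 10).
#' @param require_pass Keep only records whose FILTER column is `PASS`.
#' @param drop_homozygous Drop calls whose genotype is homozygous alternate.
#' @param coding_only Drop calls without a coding functional annotation
#'   (annotation `unknown` is treated as non-coding and dropped).
#' @param include_silent Keep synonymous coding calls as well.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10, require_pass = TRUE,
                          drop_homozygous = FALSE, coding_only = TRUE,
                          include_silent = FALSE) {
  if (!is.numeric(min_depth) || min_depth < 1) {
    stop("min_depth must be >= 1", call. = FALSE)
  }
  structure(
    list(
      min_depth = as.integer(min_depth),
      require_pass = isTRUE(require_pass),
      drop_homozygous = isTRUE(drop_homozygous),
      coding_only = isTRUE(coding_only),
      include_silent = isTRUE(include_silent)
    ),
    class = "filter_config"
  )
}

#' Is a ref/alt pair a single nucleotide variant?
#'
#' Indels, multi-base substitutions and symbolic alleles are all rejected;
#' only single-base A/C/G/T to A/C/G/T substitutions pass.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Logical vector.
#' @export
is_snv <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  ref %in% BASES & alt %in% BASES
}

parse_sample_vcf <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read VCF: ", path, call. = FALSE)
  }
  v <- try(vcfR::read.vcfR(path, verbose = FALSE), silent = TRUE)
  if (inherits(v, "try-error")) {
    stop("failed to parse VCF: ", path, call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  sample_id <- if (ncol(v@gt) >= 2) colnames(v@gt)[2] else {
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  if (nrow(fix) == 0) {
    return(list(
      sample_id = sample_id,
      records = data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), depth = integer(), alt_count = integer(),
        filter_status = character(), genotype_class = character(),
        stringsAsFactors = FALSE
      )
    ))
  }
  gt <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "GT") else NULL
  dp <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "DP", as.numeric = TRUE) else NULL
  ad <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "AD") else NULL

  geno <- rep("unknown", nrow(fix))
  if (!is.null(gt)) {
    g <- gsub("\\|", "/", as.vector(gt[, 1]))
    geno[g %in% c("0/1", "1/0")] <- "het"
    geno[g %in% "1/1"] <- "hom"
  }

  depth <- rep(NA_integer_, nrow(fix))
  alt_count <- rep(NA_integer_, nrow(fix))
  if (!is.null(ad)) {
    parts <- strsplit(ifelse(is.na(as.vector(ad[, 1])), "", as.vector(ad[, 1])), ",", fixed = TRUE)
    ref_n <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, "")))
    alt_n <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
    # depth = sum of allelic depths when the caller provides them, so that
    # alt_count/depth stays internally consistent for the VAF
    depth <- ref_n + alt_n
    alt_count <- alt_n
  }
  if (!is.null(dp)) {
    use_dp <- is.na(depth)
    depth[use_dp] <- as.integer(dp[use_dp, 1])
  }

  list(
    sample_id = sample_id,
    records = data.frame(
      chrom = fix$CHROM,
      pos = suppressWarnings(as.integer(fix$POS)),
      ref = fix$REF,
      alt = fix$ALT,
      depth = depth,
      alt_count = alt_count,
      filter_status = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
      genotype_class = geno,
      stringsAsFactors = FALSE
    )
  )
}

FILTER_REASONS <- c(
  "parse", "non-SNV", "N-ref", "non-PASS",
  "low-depth", "homozygous", "non-coding/silent"
)

#' Read and filter a cohort of per-sample VCFs
#'
#' Reads one single-sample VCF per path, applies the quality filters in a
#' fixed order (parse, non-SNV, N-ref, non-PASS, low-depth, homozygous,
#' non-coding/silent; each dropped record is charged to the first failing
#' reason) and returns the clean cohort call set. Multi-allelic records
#' (comma-separated ALT) fail the SNV test and are excluded, not decomposed.
#'
#' @param vcf_paths Character vector of VCF file paths, one sample each.
#' @param config A [filter_config()].
#' @param coding_table Optional functional-annotation table (data frame with
#'   columns `chrom, pos, ref, alt, effect`; effect in
#'   `nonsilent/silent/unknown/stopgain/stoploss`) or an
#'   `annotation_sources` object. Required when `config$coding_only` is TRUE.
#' @return A `cohort_calls` object: list with `calls` (data frame),
#'   `sample_ids`, `n_samples`, `filter_log` (named drop counts).
#' @export
read_cohort <- function(vcf_paths, config = filter_config(), coding_table = NULL) {
  parsed <- lapply(vcf_paths, parse_sample_vcf)
  ids <- vapply(parsed, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  calls <- do.call(rbind, lapply(parsed, function(p) {
    if (nrow(p$records) == 0) {
      return(cbind(sample_id = character(), p$records))
    }
    cbind(sample_id = p$sample_id, p$records, stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- data.frame(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), depth = integer(),
      alt_count = integer(), filter_status = character(),
      genotype_class = character(), stringsAsFactors = FALSE
    )
  }
  filter_cohort_calls(calls, ids, config, coding_table)
}

#' @noRd
filter_cohort_calls <- function(calls, sample_ids, config, coding_table) {
  log <- stats::setNames(integer(length(FILTER_REASONS)), FILTER_REASONS)
  n_in <- nrow(calls)
  drop_for <- function(keepable, bad, reason) {
    hit <- keepable & bad
    log[reason] <<- log[reason] + sum(hit)
    keepable & !bad
  }
  keep <- rep(TRUE, n_in)
  keep <- drop_for(keep, is.na(calls$pos) | is.na(calls$depth) | is.na(calls$alt_count) |
    calls$alt_count > calls$depth, "parse")
  # shape first (indels, multi-base or symbolic alleles), so that a
  # single-base N reference is charged to its own reason next
  snv_shaped <- nchar(calls$ref) == 1 & calls$alt %in% BASES &
    calls$ref %in% c(BASES, "N")
  keep <- drop_for(keep, !snv_shaped, "non-SNV")
  keep <- drop_for(keep, calls$ref == "N", "N-ref")
  if (config$require_pass) {
    keep <- drop_for(keep, calls$filter_status != "PASS", "non-PASS")
  }
  keep <- drop_for(keep, calls$depth < config$min_depth, "low-depth")
  if (config$drop_homozygous) {
    keep <- drop_for(keep, calls$genotype_class == "hom", "homozygous")
  }
  if (config$coding_only) {
    if (is.null(coding_table)) {
      stop("coding_only filtering requires a functional-annotation table", call. = FALSE)
    }
    eff <- lookup_coding_effect(calls, coding_table)
    bad <- eff %in% "unknown" | is.na(eff)
    if (!config$include_silent) bad <- bad | eff %in% "silent"
    keep <- drop_for(keep, bad, "non-coding/silent")
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(
      calls = out,
      sample_ids = sample_ids,
      n_samples = length(sample_ids),
      filter_log = log[log > 0]
    ),
    class = "cohort_calls"
  )
}

lookup_coding_effect <- function(calls, coding_table) {
  if (inherits(coding_table, "annotation_sources")) {
    tab <- coding_table$impact
  } else {
    tab <- coding_table
  }
  if (nrow(calls) == 0) {
    return(character())
  }
  k <- allele_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  eff <- tab$effect[match(k, allele_key(tab$chrom, tab$pos, tab$ref, tab$alt))]
  # stopgain/stoploss are protein-truncating, hence non-silent coding
  eff[eff %in% c("stopgain", "stoploss")] <- "nonsilent"
  eff
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat("Tumor-only cohort call set\n")
  cat(sprintf("  samples: %d   calls kept: %d\n", x$n_samples, nrow(x$calls)))
  if (length(x$filter_log)) {
    cat("  dropped: ", paste(sprintf("%s=%d", names(x$filter_log), x$filter_log),
      collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' Write predicted labels for collapsed variants
#'
#' @param variants Data frame of unique variants carrying `chrom, pos, ref,
#'   alt, predicted_label, score, provenance` (provenance `prelabeled` or
#'   `classified`) and optionally `n_samples_with_call`.
#' @param path Output file path.
#' @param format `"tsv"` (default) or a minimal `"vcf"` with INFO keys
#'   `ISOWN_LABEL`, `ISOWN_SCORE`, `ISOWN_SRC`.
#' @export
write_predictions <- function(variants, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(
    all(variants$predicted_label %in% c("somatic", "germline")),
    all(variants$score >= 0 & variants$score <= 1),
    all(variants$provenance %in% c("prelabeled", "classified"))
  )
  nsc <- variants$n_samples_with_call %||% rep(NA_integer_, nrow(variants))
  if (format == "tsv") {
    out <- data.frame(
      chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
      alt = variants$alt, predicted_label = variants$predicted_label,
      score = variants$score, provenance = variants$provenance,
      n_samples_with_call = nsc, stringsAsFactors = FALSE
    )
    ok <- try(suppressWarnings(utils::write.table(out, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write: ", path, call. = FALSE)
  } else {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=ISOWN_LABEL,Number=1,Type=String,Description=\"Predicted class\">",
      "##INFO=<ID=ISOWN_SCORE,Number=1,Type=Float,Description=\"Somatic posterior score\">",
      "##INFO=<ID=ISOWN_SRC,Number=1,Type=String,Description=\"prelabeled or classified\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    rows <- if (nrow(variants)) {
      sprintf(
        "%s\t%d\t.\t%s\t%s\t.\t.\tISOWN_LABEL=%s;ISOWN_SCORE=%s;ISOWN_SRC=%s",
        variants$chrom, variants$pos, variants$ref, variants$alt,
        variants$predicted_label, format(variants$score, digits = 6, trim = TRUE),
        variants$provenance
      )
    } else {
      character()
    }
    ok <- try(suppressWarnings(writeLines(c(hdr, rows), path)), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Read back a predictions file written by [write_predictions()]
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Data frame of predictions.
#' @export
read_predictions <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln)) {
      return(data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), predicted_label = character(), score = numeric(),
        provenance = character(), stringsAsFactors = FALSE
      ))
    }
    f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
    info <- strsplit(f[, 8], ";", fixed = TRUE)
    get <- function(tag) {
      vapply(info, function(kv) {
        sub(paste0(tag, "="), "", kv[startsWith(kv, paste0(tag, "="))][1])
      }, "")
    }
    data.frame(
      chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4], alt = f[, 5],
      predicted_label = get("ISOWN_LABEL"),
      score = as.numeric(get("ISOWN_SCORE")),
      provenance = get("ISOWN_SRC"), stringsAsFactors = FALSE
    )
  }
}
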