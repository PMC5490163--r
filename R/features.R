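#' Six-category substitution pattern
#'
#' The substitution is the two-base string reference+alternate, collapsed to
#' a pyrimidine reference: when the reference base is a purine (A or G) both
#' alleles are complemented first, so every substitution maps onto one of
#' CA, CG, CT, TA, TC, TG. A G>T change is therefore "CA" and A>G is "TC".
#'
#' @param ref,alt Single-base character vectors, `ref != alt`.
#' @return Character vector of patterns.
#' @export
substitution_pattern <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(!ref %in% BASES | !alt %in% BASES)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, COMPLEMENT[ref], ref)
  a <- ifelse(flip, COMPLEMENT[alt], alt)
  unname(paste0(r, a))
}

#' Trinucleotide sequence context
#'
#' Returns the three reference bases centered on the variant position, read
#' off the forward strand of the reference genome, uppercased. Unlike the
#' substitution pattern this feature is deliberately not
#' complement-collapsed: it takes 64 values. Positions at a chromosome end,
#' on an unknown chromosome, or whose window contains a non-ACGT base yield
#' `NA` (feature missing for that call).
#'
#' @param genome Named character vector of chromosome sequences (or anything
#'   [load_annotation_sources()] accepts as a genome).
#' @param chrom,pos Chromosome names and 1-based positions.
#' @return Character vector of 3-base contexts or `NA`.
#' @export
sequence_context <- function(genome, chrom, pos) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  n <- length(pos)
  out <- rep(NA_character_, n)
  idx <- match(chrom, names(genome))
  len <- nchar(genome)[idx]
  ok <- !is.na(idx) & pos - 1 >= 1 & pos + 1 <= len
  if (any(ok)) {
    out[ok] <- toupper(substr(
      genome[idx[ok]],
      pos[ok] - 1, pos[ok] + 1
    ))
  }
  bad <- !is.na(out) & !grepl("^[ACGT]{3}$", out)
  out[bad] <- NA_character_
  out
}

#' Variant allele frequency
#'
#' Fraction of reads supporting the alternate allele.
#' @param alt_count,depth Integer vectors, `0 <= alt_count <= depth`,
#'   `depth >= 1`.
#' @return Numeric vector in \[0, 1\].
#' @export
vaf <- function(alt_count, depth) {
  if (any(depth < 1)) stop("depth must be >= 1", call. = FALSE)
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  }
  alt_count / depth
}

#' Exact binomial (Clopper-Pearson) confidence interval for a VAF
#'
#' Equal-tailed exact interval via the beta quantile representation;
#' `lo = 0` when no reads support the allele and `hi = 1` when all do.
#'
#' @param successes,trials Integer vectors of alt-supporting and total reads.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `point`, `lo`, `hi`, `level`.
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (any(trials < 1) || any(successes < 0 | successes > trials)) {
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  }
  a <- 1 - level
  lo <- ifelse(successes == 0, 0, stats::qbeta(a / 2, successes, trials - successes + 1))
  hi <- ifelse(successes == trials, 1, stats::qbeta(1 - a / 2, successes + 1, trials - successes))
  data.frame(point = successes / trials, lo = lo, hi = hi, level = level)
}

intervals_overlap <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 & lo2 <= hi1

#' Flanking-assessment decision from three VAF confidence intervals
#'
#' Given the candidate variant's interval and the intervals of its nearest
#' upstream (v1) and downstream (v2) common polymorphisms in the same
#' sample: if both flanks exist and both overlap the candidate's interval
#' the call looks germline (shared local copy-number context); if the
#' candidate overlaps neither flank while the flanks overlap each other it
#' looks somatic; every other configuration, including a missing flank, is
#' not applicable. Interval overlap is closed
#' (`lo1 <= hi2 && lo2 <= hi1`).
#'
#' @param x_lo,x_hi Candidate interval.
#' @param v1_lo,v1_hi,v2_lo,v2_hi Flank intervals (`NA` = flank not found).
#' @return Character vector: `germline_like`, `somatic_like`,
#'   `not_applicable`.
#' @export
flank_decision <- function(x_lo, x_hi, v1_lo, v1_hi, v2_lo, v2_hi) {
  n <- length(x_lo)
  out <- rep("not_applicable", n)
  have <- !is.na(v1_lo) & !is.na(v2_lo)
  o1 <- intervals_overlap(x_lo, x_hi, v1_lo, v1_hi)
  o2 <- intervals_overlap(x_lo, x_hi, v2_lo, v2_hi)
  o12 <- intervals_overlap(v1_lo, v1_hi, v2_lo, v2_hi)
  out[have & o1 & o2] <- "germline_like"
  out[have & !o1 & !o2 & o12] <- "somatic_like"
  out
}

#' Flanking-region assessment for every call of one sample
#'
#' For each call, the nearest same-chromosome call strictly upstream and the
#' nearest strictly downstream within the window that is catalogued as a
#' common polymorphism (and heterozygous, where genotype is known) serve as
#' flanks; ties at equal distance go to the lower coordinate. The decision
#' is taken by [flank_decision()] on the Clopper-Pearson VAF intervals. A
#' call is never its own flank; a call at the exact position of a candidate
#' flank is ignored for that side.
#'
#' @param sample_calls Data frame of one sample's calls (`chrom, pos, ref,
#'   alt, depth, alt_count, genotype_class`).
#' @param common_keys Character vector of `chrom:pos:ref:alt` keys of common
#'   polymorphisms.
#' @param window Flank search window in bp (default 2e6).
#' @param ci_level Confidence level for the VAF intervals.
#' @return Character vector (one per call): `germline_like`,
#'   `somatic_like`, `not_applicable`.
#' @export
flanking_assessments <- function(sample_calls, common_keys, window = 2e6,
                                 ci_level = 0.95) {
  n <- nrow(sample_calls)
  if (n == 0) {
    return(character())
  }
  ci <- binomial_ci(sample_calls$alt_count, sample_calls$depth, ci_level)
  keys <- allele_key(
    sample_calls$chrom, sample_calls$pos,
    sample_calls$ref, sample_calls$alt
  )
  is_flank <- keys %in% common_keys &
    sample_calls$genotype_class %in% c("het", "unknown")
  out <- rep("not_applicable", n)
  for (ch in unique(sample_calls$chrom)) {
    on_ch <- which(sample_calls$chrom == ch)
    cand <- on_ch[is_flank[on_ch]]
    if (!length(cand)) next
    cand <- cand[order(sample_calls$pos[cand])]
    cpos <- sample_calls$pos[cand]
    xpos <- sample_calls$pos[on_ch]
    # nearest candidate strictly below / strictly above each position
    up_i <- findInterval(xpos - 1, cpos) # last candidate with pos <  xpos
    dn_i <- findInterval(xpos, cpos) + 1 # first candidate with pos > xpos
    up <- ifelse(up_i >= 1, cand[pmax(up_i, 1)], NA_integer_)
    dn <- ifelse(dn_i <= length(cand), cand[pmin(dn_i, length(cand))], NA_integer_)
    up[!is.na(up) & xpos - sample_calls$pos[up] > window] <- NA_integer_
    dn[!is.na(dn) & sample_calls$pos[dn] - xpos > window] <- NA_integer_
    out[on_ch] <- flank_decision(
      ci$lo[on_ch], ci$hi[on_ch],
      ifelse(is.na(up), NA_real_, ci$lo[up]), ifelse(is.na(up), NA_real_, ci$hi[up]),
      ifelse(is.na(dn), NA_real_, ci$lo[dn]), ifelse(is.na(dn), NA_real_, ci$hi[dn])
    )
  }
  out
}

#' Pass annotation impact categories through as classifier features
#'
#' @param ann Annotation data frame from [annotate_alleles()].
#' @return Data frame with `ma_category` and `pp2_category`.
#' @export
impact_features <- function(ann) {
  data.frame(
    ma_category = ann$ma_category, pp2_category = ann$pp2_category,
    stringsAsFactors = FALSE
  )
}
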