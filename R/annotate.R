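#' Load external annotation sources
#'
#' All evidence databases are consumed as allele-keyed tab-separated tables
#' (header `chrom pos ref alt` plus value columns), 1-based coordinates,
#' exact (chrom, pos, ref, alt) match. The somatic catalogue carries a `cnt`
#' column (number of tumor samples in which the mutation was reported); the
#' impact table carries `ma` (functional-impact level), `pp2`
#' (damaging-effect level) and `effect`
#' (`nonsilent/silent/unknown/stopgain/stoploss`).
#'
#' @param cosmic,dbsnp_common,dbsnp_rare,exac,impact File paths to the TSV
#'   tables, or data frames with the same columns (used by the simulator).
#'   Any of the membership sets may be omitted (`NULL` = empty set).
#' @param genome FASTA path, a named character vector of chromosome
#'   sequences, or a `Biostrings::DNAStringSet`.
#' @return An `annotation_sources` object.
#' @export
load_annotation_sources <- function(cosmic = NULL, dbsnp_common = NULL,
                                    dbsnp_rare = NULL, exac = NULL,
                                    impact = NULL, genome = NULL) {
  read_tab <- function(x, what, value_cols = character()) {
    if (is.null(x)) {
      return(data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), stringsAsFactors = FALSE
      ))
    }
    tab <- if (is.data.frame(x)) {
      x
    } else {
      out <- try(utils::read.delim(x, stringsAsFactors = FALSE, colClasses = "character"),
        silent = TRUE
      )
      if (inherits(out, "try-error")) stop("cannot read ", what, " table: ", x, call. = FALSE)
      out
    }
    need <- c("chrom", "pos", "ref", "alt", value_cols)
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop(what, " table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    tab$pos <- suppressWarnings(as.integer(tab$pos))
    if (anyNA(tab$pos)) {
      stop(what, " table: malformed pos at row(s) ",
        paste(utils::head(which(is.na(tab$pos)), 5), collapse = ", "),
        call. = FALSE
      )
    }
    tab
  }
  cos <- read_tab(cosmic, "somatic-catalogue", "cnt")
  if (nrow(cos)) {
    cos$cnt <- as.integer(cos$cnt)
    if (anyNA(cos$cnt) || any(cos$cnt < 0)) {
      stop("somatic-catalogue table: malformed cnt", call. = FALSE)
    }
  } else {
    cos$cnt <- integer()
  }
  imp <- read_tab(impact, "impact", c("ma", "pp2", "effect"))

  gen <- genome
  if (is.character(gen) && length(gen) == 1 && file.exists(gen)) {
    gen <- Biostrings::readDNAStringSet(gen)
  }
  if (inherits(gen, "DNAStringSet")) {
    gen <- stats::setNames(as.character(gen), sub("\\s.*$", "", names(gen)))
  }

  structure(
    list(
      cosmic = cos,
      cosmic_key = allele_key(cos$chrom, cos$pos, cos$ref, cos$alt),
      common = key_set(read_tab(dbsnp_common, "common-polymorphism")),
      rare = key_set(read_tab(dbsnp_rare, "rare-polymorphism")),
      exac = key_set(read_tab(exac, "population-exome")),
      impact = imp,
      impact_key = allele_key(imp$chrom, imp$pos, imp$ref, imp$alt),
      genome = gen
    ),
    class = "annotation_sources"
  )
}

key_set <- function(tab) allele_key(tab$chrom, tab$pos, tab$ref, tab$alt)

#' @export
print.annotation_sources <- function(x, ...) {
  cat("Annotation sources\n")
  cat(sprintf(
    "  somatic catalogue: %d  common: %d  rare: %d  exome: %d  impact: %d\n",
    nrow(x$cosmic), length(x$common), length(x$rare), length(x$exac),
    nrow(x$impact)
  ))
  cat(sprintf(
    "  genome: %s\n",
    if (is.null(x$genome)) "none" else paste(length(x$genome), "sequence(s)")
  ))
  invisible(x)
}

#' Annotate variant alleles against the external databases
#'
#' Pure exact-match lookup: an allele absent from a source gets the "absent"
#' default (cnt 0, membership FALSE, impact `missing`). Stopgain/stoploss
#' effects from the functional-annotation table override the
#' functional-impact level, since truncating mutations are outside the
#' impact predictor's output and are carried as extra categories of that
#' feature.
#'
#' @param keys Data frame with `chrom, pos, ref, alt` (one row per allele).
#' @param sources An `annotation_sources` object.
#' @return Data frame with columns `cnt, in_exac, in_dbsnp_common,
#'   in_dbsnp_rare, ma_category, pp2_category, coding_effect`.
#' @export
annotate_alleles <- function(keys, sources) {
  stopifnot(inherits(sources, "annotation_sources"))
  k <- allele_key(keys$chrom, keys$pos, keys$ref, keys$alt)
  m_cos <- match(k, sources$cosmic_key)
  cnt <- ifelse(is.na(m_cos), 0L, sources$cosmic$cnt[m_cos])
  m_imp <- match(k, sources$impact_key)
  ma <- rep("missing", length(k))
  pp2 <- rep("missing", length(k))
  eff <- rep("unknown", length(k))
  hit <- !is.na(m_imp)
  if (any(hit)) {
    ma[hit] <- sources$impact$ma[m_imp[hit]]
    pp2[hit] <- sources$impact$pp2[m_imp[hit]]
    raw_eff <- sources$impact$effect[m_imp[hit]]
    trunc <- raw_eff %in% c("stopgain", "stoploss")
    ma[hit][trunc] <- raw_eff[trunc]
    eff[hit] <- ifelse(raw_eff %in% c("stopgain", "stoploss"), "nonsilent", raw_eff)
  }
  ma[is.na(ma) | !ma %in% MA_LEVELS] <- "missing"
  pp2[is.na(pp2) | !pp2 %in% PP2_LEVELS] <- "missing"
  data.frame(
    cnt = as.integer(cnt),
    in_exac = k %in% sources$exac,
    in_dbsnp_common = k %in% sources$common,
    in_dbsnp_rare = k %in% sources$rare,
    ma_category = ma,
    pp2_category = pp2,
    coding_effect = eff,
    stringsAsFactors = FALSE
  )
}

#' Annotate one allele
#'
#' Scalar convenience wrapper around [annotate_alleles()].
#' @param chrom,pos,ref,alt Allele coordinates (1-based) and bases.
#' @param sources An `annotation_sources` object.
#' @return One-row data frame of annotations.
#' @export
annotate_allele <- function(chrom, pos, ref, alt, sources) {
  annotate_alleles(
    data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE
    ),
    sources
  )
}
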