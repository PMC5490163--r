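#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

MA_LEVELS <- c("high", "medium", "low", "neutral", "stopgain", "stoploss", "missing")
PP2_LEVELS <- c("probably_damaging", "possibly_damaging", "benign", "missing")
EFFECT_LEVELS <- c("nonsilent", "silent", "unknown")
PATTERN_LEVELS <- c("CA", "CG", "CT", "TA", "TC", "TG")
CONTEXT_LEVELS <- c(
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)),
  "missing"
)

#' Allele key string
#'
#' Annotation sources, truth tables and collapsed variants are all keyed by
#' the 1-based genomic coordinate plus the substitution, as
#' `chrom:pos:ref:alt`.
#' @noRd
allele_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Derive a named substream seed from the run-level seed
#'
#' All randomness in the package fans out from one run-level seed; each named
#' consumer (set sampling, fold assignment, forest bootstrap, ...) gets its
#' own reproducible substream so adding a consumer does not perturb the
#' others. Kept below 2^31 - 1.
#' @noRd
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

stage_log <- function(stage, ...) {
  message(sprintf("[isown] %-12s %s", stage, sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
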