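#' Deterministic pre-labeling rules
#'
#' Two rules bypass the classifier entirely: (a) an allele reported by the
#' somatic catalogue in at least `cnt_threshold` tumor samples is labeled
#' somatic; (b) otherwise, an allele catalogued as a common polymorphism and
#' absent from the somatic catalogue (cnt = 0) is labeled germline. The
#' rules are disjoint by construction: the germline rule requires absence
#' from the somatic catalogue. Everything else stays unlabeled and goes to
#' the classifier.
#'
#' @param ann Annotation data frame (needs `cnt` and `in_dbsnp_common`).
#' @param cnt_threshold Somatic-catalogue sample-count threshold, inclusive
#'   (default 100).
#' @return Data frame with `decision` (`somatic`/`germline`/`unlabeled`) and
#'   `rule` (`high_cnt`/`dbsnp_not_cosmic`/`none`).
#' @export
prelabel <- function(ann, cnt_threshold = 100) {
  if (!is.numeric(cnt_threshold) || cnt_threshold < 1) {
    stop("cnt_threshold must be >= 1", call. = FALSE)
  }
  n <- nrow(ann)
  decision <- rep("unlabeled", n)
  rule <- rep("none", n)
  som <- ann$cnt >= cnt_threshold
  germ <- !som & ann$in_dbsnp_common & ann$cnt == 0
  decision[som] <- "somatic"
  rule[som] <- "high_cnt"
  decision[germ] <- "germline"
  rule[germ] <- "dbsnp_not_cosmic"
  data.frame(decision = decision, rule = rule, stringsAsFactors = FALSE)
}

#' Apply pre-labeling to collapsed unique variants
#'
#' @param uv A `unique_variants` data frame.
#' @param cnt_threshold Passed to [prelabel()].
#' @return `uv` with `prelabel` and `prelabel_rule` columns.
#' @export
prelabel_variants <- function(uv, cnt_threshold = 100) {
  pl <- prelabel(uv, cnt_threshold)
  uv$prelabel <- pl$decision
  uv$prelabel_rule <- pl$rule
  uv
}
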