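#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated tumor-only cohort:
#' a random reference genome, a pool of common germline polymorphisms
#' recurring across samples at population frequencies, private rare
#' germline variants, and private somatic mutations with subclonal allele
#' frequencies. Defaults emulate a moderately mutated exome cohort: 50
#' samples, ~100 somatic SNVs per sample (Poisson), a collapsed
#' germline:somatic ratio near 5:1, somatic VAF beta-distributed with mean
#' 0.25, germline VAF binomial around 0.5 with a fraction of the genome
#' under copy-number segments that shift germline VAFs coherently, read
#' depth negative-binomial around 100x, functional-impact skew
#' (germline-neutral 0.42 vs somatic-neutral 0.25) and substitution-pattern
#' enrichment (somatic in CA, germline in TC).
#'
#' @param seed Run-level seed; identical configs and seeds give identical
#'   cohorts.
#' @param n_samples Cohort size.
#' @param n_chrom,chrom_length Genome shape.
#' @param common_pool_size Number of common germline alleles in the
#'   population.
#' @param common_freq_shape Beta shape parameters of population
#'   frequencies.
#' @param dbsnp_common_coverage Fraction of the common pool catalogued as
#'   common polymorphisms.
#' @param rare_per_sample Mean private rare germline variants per sample.
#' @param somatic_per_sample Mean somatic mutations per sample (Poisson).
#' @param somatic_vaf_mean,somatic_vaf_conc Beta mean/concentration of the
#'   somatic VAF mixture.
#' @param purity Tumor purity (scalar or range to draw per sample);
#'   multiplies somatic VAFs.
#' @param depth_mean,depth_size Negative-binomial read-depth model.
#' @param min_alt_reads Caller detection limit; calls with fewer
#'   alt-supporting reads are not emitted.
#' @param cn_segments_per_sample,cn_segment_length Copy-number segments per
#'   sample (Poisson mean) and their length; germline VAF centers inside a
#'   segment shift to 1/3 or 2/3.
#' @param cnt_somatic_coverage Fraction of somatic alleles present in the
#'   somatic catalogue.
#' @param cnt_mu,cnt_size Negative-binomial tail of catalogue sample
#'   counts (plus one).
#' @param driver_prob Probability that a catalogued somatic allele is a
#'   recurrent driver with count >= 100.
#' @param germline_cnt_contamination Fraction of germline alleles carrying
#'   a small spurious catalogue count.
#' @param dbsnp_rare_coverage,rare_exac_coverage,common_exac_coverage,
#'   common_in_rare_overlap,somatic_dbsnp_rare_contamination,somatic_exac_contamination
#'   Membership coverages of the polymorphism/exome databases.
#' @param silent_fraction,unknown_fraction Fractions of alleles annotated
#'   silent / unknown (exercise the coding filters).
#' @param impact_model,pp2_model Per-class category probabilities.
#' @param truncation_model Per-class stopgain/stoploss probabilities.
#' @param pattern_weights Per-class weights over the six substitution
#'   categories (order CA, CG, CT, TA, TC, TG).
#' @param hom_fraction Fraction of common germline calls emitted as
#'   homozygous (default 0: emulates paired call sets shipped without
#'   homozygous variants).
#' @param fail_filter_fraction Fraction of calls emitted with a non-PASS
#'   caller filter.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1,
                          n_samples = 50,
                          n_chrom = 4,
                          chrom_length = 1e6,
                          common_pool_size = 22500,
                          common_freq_shape = c(1.2, 6),
                          dbsnp_common_coverage = 0.9,
                          rare_per_sample = 50,
                          somatic_per_sample = 100,
                          somatic_vaf_mean = 0.25,
                          somatic_vaf_conc = 8,
                          purity = 1,
                          depth_mean = 100,
                          depth_size = 10,
                          min_alt_reads = 3,
                          cn_segments_per_sample = 3,
                          cn_segment_length = 2e5,
                          cnt_somatic_coverage = 0.45,
                          cnt_mu = 8,
                          cnt_size = 0.25,
                          driver_prob = 0.06,
                          germline_cnt_contamination = 0.02,
                          dbsnp_rare_coverage = 0.8,
                          rare_exac_coverage = 0.25,
                          common_exac_coverage = 0.95,
                          common_in_rare_overlap = 0.05,
                          somatic_dbsnp_rare_contamination = 0.02,
                          somatic_exac_contamination = 0.02,
                          silent_fraction = 0.08,
                          unknown_fraction = 0.02,
                          impact_model = list(
                            germline = c(
                              high = 0.05, medium = 0.15, low = 0.28,
                              neutral = 0.42, missing = 0.10
                            ),
                            somatic = c(
                              high = 0.17, medium = 0.27, low = 0.22,
                              neutral = 0.25, missing = 0.09
                            )
                          ),
                          pp2_model = list(
                            germline = c(
                              probably_damaging = 0.15,
                              possibly_damaging = 0.20,
                              benign = 0.55, missing = 0.10
                            ),
                            somatic = c(
                              probably_damaging = 0.42,
                              possibly_damaging = 0.25,
                              benign = 0.25, missing = 0.08
                            )
                          ),
                          truncation_model = list(
                            germline = c(stopgain = 0.004, stoploss = 0.002),
                            somatic = c(stopgain = 0.05, stoploss = 0.01)
                          ),
                          pattern_weights = list(
                            germline = c(0.08, 0.08, 0.25, 0.07, 0.37, 0.15),
                            somatic = c(0.35, 0.10, 0.25, 0.08, 0.12, 0.10)
                          ),
                          hom_fraction = 0,
                          fail_filter_fraction = 0.01) {
  cfg <- as.list(environment())
  probs <- c(
    cfg$dbsnp_common_coverage, cfg$cnt_somatic_coverage, cfg$driver_prob,
    cfg$germline_cnt_contamination, cfg$dbsnp_rare_coverage,
    cfg$rare_exac_coverage, cfg$common_exac_coverage,
    cfg$common_in_rare_overlap, cfg$somatic_dbsnp_rare_contamination,
    cfg$somatic_exac_contamination, cfg$silent_fraction,
    cfg$unknown_fraction, cfg$hom_fraction, cfg$fail_filter_fraction,
    cfg$somatic_vaf_mean, cfg$purity
  )
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$rare_per_sample, cfg$somatic_per_sample) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# alt allele consistent with the requested substitution pattern and the
# actual reference base (complemented when the reference is a purine)
draw_alts <- function(ref, class_weights) {
  n <- length(ref)
  alt <- character(n)
  second <- substr(PATTERN_LEVELS, 2, 2)
  pyr <- substr(PATTERN_LEVELS, 1, 1)
  for (b in BASES) {
    idx <- which(ref == b)
    if (!length(idx)) next
    flip <- b %in% c("A", "G")
    want <- if (flip) COMPLEMENT[b] else b
    sub_pat <- which(pyr == want)
    w <- class_weights[sub_pat]
    pick <- sub_pat[sample.int(3, length(idx), replace = TRUE, prob = w / sum(w))]
    a <- second[pick]
    if (flip) a <- COMPLEMENT[a]
    alt[idx] <- a
  }
  unname(alt)
}

#' Simulate a self-contained tumor-only cancer cohort
#'
#' Generates the reference genome, all per-sample calls, the five
#' annotation tables and the allele-level truth labels; optionally writes
#' everything to disk (`genome.fa`, `sample_*.vcf`, `cosmic.tsv`,
#' `dbsnp_common.tsv`, `dbsnp_rare.tsv`, `exac.tsv`, `impact.tsv`,
#' `truth.tsv`) in formats that parse back through [read_cohort()] and
#' [load_annotation_sources()] unchanged.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed); `NULL` keeps everything
#'   in memory.
#' @return A `sim_cohort` object: `genome` (named character), `calls`
#'   (per-sample call data frame), `truth` (allele-level labels), `tables`
#'   (annotation data frames), `sample_ids`, `config`, and `paths` when
#'   written.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(substream_seed(config$seed, "simulate"))
  ns <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))

  chroms <- paste0("chr", seq_len(config$n_chrom))
  genome <- stats::setNames(
    vapply(
      chroms,
      function(ch) paste(sample(BASES, config$chrom_length, replace = TRUE), collapse = ""),
      ""
    ),
    chroms
  )

  n_som_per_sample <- stats::rpois(ns, config$somatic_per_sample)
  n_rare_per_sample <- stats::rpois(ns, config$rare_per_sample)
  n_common <- config$common_pool_size
  n_alleles <- n_common + sum(n_rare_per_sample) + sum(n_som_per_sample)
  n_positions <- config$n_chrom * config$chrom_length
  if (n_alleles > n_positions) {
    stop("infeasible config: more alleles than genome positions", call. = FALSE)
  }
  flat <- sample.int(n_positions, n_alleles)
  al_chrom <- chroms[(flat - 1) %/% config$chrom_length + 1]
  al_pos <- (flat - 1) %% config$chrom_length + 1L
  al_ref <- substr(genome[al_chrom], al_pos, al_pos)

  cls <- rep(c("common", "rare", "somatic"),
    times = c(n_common, sum(n_rare_per_sample), sum(n_som_per_sample))
  )
  is_germ <- cls != "somatic"
  al_alt <- character(n_alleles)
  al_alt[is_germ] <- draw_alts(al_ref[is_germ], config$pattern_weights$germline)
  al_alt[!is_germ] <- draw_alts(al_ref[!is_germ], config$pattern_weights$somatic)

  alleles <- data.frame(
    chrom = al_chrom, pos = al_pos, ref = al_ref, alt = al_alt,
    class = cls, stringsAsFactors = FALSE
  )
  alleles$key <- allele_key(al_chrom, al_pos, al_ref, al_alt)

  # ------------------------------------------------------------------ calls
  common_idx <- which(cls == "common")
  freqs <- pmin(pmax(stats::rbeta(
    n_common, config$common_freq_shape[1],
    config$common_freq_shape[2]
  ), 0.01), 0.6)
  carrier <- matrix(stats::runif(n_common * ns) < freqs, nrow = n_common)
  common_calls <- which(carrier, arr.ind = TRUE)

  rare_sample <- rep(seq_len(ns), times = n_rare_per_sample)
  som_sample <- rep(seq_len(ns), times = n_som_per_sample)

  call_allele <- c(
    common_idx[common_calls[, 1]],
    which(cls == "rare"),
    which(cls == "somatic")
  )
  call_sample <- c(common_calls[, 2], rare_sample, som_sample)
  n_calls <- length(call_allele)
  call_germ <- is_germ[call_allele]

  # copy-number segments, per sample: coherent germline VAF shifts
  n_seg <- stats::rpois(ns, config$cn_segments_per_sample)
  segs <- if (sum(n_seg)) {
    data.frame(
      sample = rep(seq_len(ns), n_seg),
      chrom = sample(chroms, sum(n_seg), replace = TRUE),
      start = sample.int(config$chrom_length, sum(n_seg)),
      shift = sample(c(1 / 3, 2 / 3), sum(n_seg), replace = TRUE)
    )
  } else {
    data.frame(sample = integer(), chrom = character(), start = integer(), shift = numeric())
  }
  center <- rep(0.5, n_calls)
  if (nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      hit <- call_sample == segs$sample[i] &
        al_chrom[call_allele] == segs$chrom[i] &
        al_pos[call_allele] >= segs$start[i] &
        al_pos[call_allele] < segs$start[i] + config$cn_segment_length
      center[hit & call_germ] <- segs$shift[i]
    }
  }

  hom <- call_germ & cls[call_allele] == "common" &
    stats::runif(n_calls) < config$hom_fraction
  center[hom] <- 0.98

  purity <- if (length(config$purity) == 2) {
    stats::runif(ns, config$purity[1], config$purity[2])
  } else {
    rep(config$purity, ns)
  }
  m <- config$somatic_vaf_mean
  vaf_true <- center
  n_som_calls <- sum(!call_germ)
  vaf_true[!call_germ] <- pmin(
    stats::rbeta(
      n_som_calls, m * config$somatic_vaf_conc,
      (1 - m) * config$somatic_vaf_conc
    ) * purity[call_sample[!call_germ]],
    0.95
  )

  depth <- pmax(stats::rnbinom(n_calls, size = config$depth_size, mu = config$depth_mean), 1L)
  alt_count <- stats::rbinom(n_calls, depth, vaf_true)
  detected <- alt_count >= config$min_alt_reads

  calls <- data.frame(
    sample_id = sample_ids[call_sample[detected]],
    chrom = al_chrom[call_allele[detected]],
    pos = al_pos[call_allele[detected]],
    ref = al_ref[call_allele[detected]],
    alt = al_alt[call_allele[detected]],
    depth = as.integer(depth[detected]),
    alt_count = as.integer(alt_count[detected]),
    filter_status = ifelse(
      stats::runif(sum(detected)) < config$fail_filter_fraction, "q10", "PASS"
    ),
    genotype_class = ifelse(hom[detected], "hom", "het"),
    stringsAsFactors = FALSE
  )
  o <- order(calls$sample_id, calls$chrom, calls$pos)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL

  emitted <- unique(call_allele[detected])
  alleles <- alleles[sort(emitted), , drop = FALSE]
  rownames(alleles) <- NULL
  n_em <- nrow(alleles)
  germ_em <- alleles$class != "somatic"

  # ------------------------------------------------------- annotation tables
  cnt <- integer(n_em)
  in_cosmic <- !germ_em & stats::runif(n_em) < config$cnt_somatic_coverage
  cnt[in_cosmic] <- 1L + stats::rnbinom(sum(in_cosmic), size = config$cnt_size, mu = config$cnt_mu)
  driver <- in_cosmic & stats::runif(n_em) < config$driver_prob
  cnt[driver] <- sample(100:3000, sum(driver), replace = TRUE)
  contam <- germ_em & stats::runif(n_em) < config$germline_cnt_contamination
  cnt[contam] <- sample(1:5, sum(contam), replace = TRUE)

  in_common_db <- alleles$class == "common" & stats::runif(n_em) < config$dbsnp_common_coverage
  in_rare_db <- (alleles$class == "rare" & stats::runif(n_em) < config$dbsnp_rare_coverage) |
    (alleles$class == "common" & stats::runif(n_em) < config$common_in_rare_overlap) |
    (!germ_em & stats::runif(n_em) < config$somatic_dbsnp_rare_contamination)
  in_exac <- (alleles$class == "common" & stats::runif(n_em) < config$common_exac_coverage) |
    (alleles$class == "rare" & stats::runif(n_em) < config$rare_exac_coverage) |
    (!germ_em & stats::runif(n_em) < config$somatic_exac_contamination)

  u <- stats::runif(n_em)
  effect <- ifelse(u < config$silent_fraction, "silent",
    ifelse(u < config$silent_fraction + config$unknown_fraction, "unknown", "nonsilent")
  )
  draw_cat <- function(model_g, model_s) {
    out <- character(n_em)
    gi <- which(germ_em)
    si <- which(!germ_em)
    out[gi] <- sample(names(model_g), length(gi), replace = TRUE, prob = model_g)
    out[si] <- sample(names(model_s), length(si), replace = TRUE, prob = model_s)
    out
  }
  ma <- draw_cat(config$impact_model$germline, config$impact_model$somatic)
  pp2 <- draw_cat(config$pp2_model$germline, config$pp2_model$somatic)
  tr_g <- config$truncation_model$germline
  tr_s <- config$truncation_model$somatic
  ut <- stats::runif(n_em)
  p_sg <- ifelse(germ_em, tr_g["stopgain"], tr_s["stopgain"])
  p_sl <- ifelse(germ_em, tr_g["stoploss"], tr_s["stoploss"])
  effect[effect == "nonsilent" & ut < p_sg] <- "stopgain"
  effect[effect == "nonsilent" & ut >= p_sg & ut < p_sg + p_sl] <- "stoploss"
  silent_like <- effect %in% c("silent", "unknown")
  ma[silent_like] <- "missing"
  pp2[silent_like] <- "missing"

  keycols <- alleles[c("chrom", "pos", "ref", "alt")]
  tables <- list(
    cosmic = cbind(keycols[cnt > 0, , drop = FALSE], cnt = cnt[cnt > 0]),
    dbsnp_common = keycols[in_common_db, , drop = FALSE],
    dbsnp_rare = keycols[in_rare_db, , drop = FALSE],
    exac = keycols[in_exac, , drop = FALSE],
    impact = cbind(keycols, ma = ma, pp2 = pp2, effect = effect)
  )
  truth <- cbind(keycols,
    label = ifelse(germ_em, "germline", "somatic"),
    stringsAsFactors = FALSE
  )

  sim <- structure(
    list(
      config = config, genome = genome, calls = calls, truth = truth,
      tables = tables, sample_ids = sample_ids, purity = purity
    ),
    class = "sim_cohort"
  )
  if (!is.null(dir)) sim$paths <- write_sim_cohort(sim, dir)
  sim
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d samples, %d calls, %d unique alleles (%d somatic / %d germline)\n",
    length(x$sample_ids), nrow(x$calls), nrow(x$truth),
    sum(x$truth$label == "somatic"), sum(x$truth$label == "germline")
  ))
  invisible(x)
}

write_sim_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  fa <- file.path(dir, "genome.fa")
  con <- file(fa, "w")
  for (ch in names(sim$genome)) {
    writeLines(paste0(">", ch), con)
    s <- sim$genome[[ch]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  close(con)
  paths$genome <- fa

  paths$vcf <- vapply(sim$sample_ids, function(sid) {
    sc <- sim$calls[sim$calls$sample_id == sid, , drop = FALSE]
    p <- file.path(dir, paste0("sample_", sid, ".vcf"))
    hdr <- c(
      "##fileformat=VCFv4.2",
      paste0("##contig=<ID=", names(sim$genome), ",length=", nchar(sim$genome), ">"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
    )
    gt <- ifelse(sc$genotype_class == "hom", "1/1", "0/1")
    rows <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:DP:AD\t%s:%d:%d,%d",
      sc$chrom, sc$pos, sc$ref, sc$alt, sc$filter_status,
      gt, sc$depth, sc$depth - sc$alt_count, sc$alt_count
    )
    writeLines(c(hdr, rows), p)
    p
  }, "")

  for (tb in names(sim$tables)) {
    p <- file.path(dir, paste0(tb, ".tsv"))
    utils::write.table(sim$tables[[tb]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[tb]] <- p
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- p
  paths
}

#' Annotation sources backed by a simulated cohort's tables
#' @param sim A `sim_cohort`.
#' @return An `annotation_sources` object.
#' @export
sim_sources <- function(sim) {
  load_annotation_sources(
    cosmic = sim$tables$cosmic, dbsnp_common = sim$tables$dbsnp_common,
    dbsnp_rare = sim$tables$dbsnp_rare, exac = sim$tables$exac,
    impact = sim$tables$impact, genome = sim$genome
  )
}

#' Filtered cohort call set from a simulated cohort (in memory)
#'
#' Runs the in-memory calls through the same filtering path as
#' [read_cohort()].
#' @param sim A `sim_cohort`.
#' @param config A [filter_config()].
#' @return A `cohort_calls` object.
#' @export
sim_cohort_calls <- function(sim, config = filter_config()) {
  filter_cohort_calls(sim$calls, sim$sample_ids, config, sim$tables$impact)
}

#' Confusion counts of allele-level predictions against simulated truth
#'
#' @param predictions Data frame with `chrom, pos, ref, alt,
#'   predicted_label`.
#' @param truth Truth data frame (`chrom, pos, ref, alt, label`); labels
#'   `excluded` are omitted from all cells.
#' @return Confusion counts as in [confusion_counts()].
#' @export
truth_confusion <- function(predictions, truth) {
  pk <- allele_key(predictions$chrom, predictions$pos, predictions$ref, predictions$alt)
  tk <- allele_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  m <- match(pk, tk)
  if (anyNA(m)) {
    stop("prediction(s) for allele(s) absent from truth: ",
      paste(utils::head(pk[is.na(m)], 3), collapse = ", "),
      call. = FALSE
    )
  }
  lab <- truth$label[m]
  keep <- lab != "excluded"
  confusion_counts(predictions$predicted_label[keep], lab[keep])
}
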