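# Shared fixtures: everything is generated in code at test time.

# a small, fast cohort for structural tests
tiny_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_samples = 6, n_chrom = 2, chrom_length = 5e4,
    common_pool_size = 300, rare_per_sample = 10, somatic_per_sample = 15
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# a mid-size cohort for classifier tests
small_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_samples = 20, n_chrom = 3, chrom_length = 3e5,
    common_pool_size = 5000, rare_per_sample = 40, somatic_per_sample = 60
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# collapse + prelabel + truth labels for a simulated cohort
collapsed_labeled <- function(sim, filter = filter_config()) {
  cc <- sim_cohort_calls(sim, filter)
  uv <- collapse_cohort(cc, sim_sources(sim))
  attach_labels(prelabel_variants(uv), sim$truth)
}

# feature matrix subset that keeps the schema attribute
mat_subset <- function(x, idx) {
  out <- x[idx, , drop = FALSE]
  attr(out, "schema") <- attr(x, "schema")
  out
}

# in-memory annotation sources built from explicit rows
make_sources <- function(cosmic = NULL, common = NULL, rare = NULL,
                         exac = NULL, impact = NULL, genome = NULL) {
  load_annotation_sources(
    cosmic = cosmic, dbsnp_common = common, dbsnp_rare = rare,
    exac = exac, impact = impact, genome = genome
  )
}

key_df <- function(chrom, pos, ref, alt, ...) {
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt, ...,
    stringsAsFactors = FALSE
  )
}

# write a single-sample VCF with explicit records
write_test_vcf <- function(path, sample_id, records) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##contig=<ID=chr2,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id)
  )
  rows <- if (nrow(records)) {
    sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:DP:AD\t%s:%d:%d,%d",
      records$chrom, records$pos, records$ref, records$alt,
      records$filter %||% "PASS",
      records$gt %||% "0/1",
      records$depth, records$depth - records$alt_count, records$alt_count
    )
  } else {
    character()
  }
  writeLines(c(hdr, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# end-to-end pipeline metrics on a simulated cohort: train on a subset of
# samples, predict every allele through prelabel + classifier, evaluate on
# alleles outside the classifier training set
e2e_metrics <- function(sim, n_train_samples, seed, kind = "naive_bayes",
                        sample_pool = NULL, eval_samples = NULL) {
  uv <- collapsed_labeled(sim)
  cls <- uv$prelabel == "unlabeled" & uv$label %in% c("somatic", "germline")
  train_idx <- training_set_from_samples(uv, n_train_samples,
    sample_pool = sample_pool, candidates = which(cls), seed = seed
  )
  x <- build_matrix(uv)
  model <- isown_train(mat_subset(x, train_idx), uv$label[train_idx],
    kind = kind, seed = seed
  )
  pred <- uv$prelabel
  need <- which(pred == "unlabeled")
  pred[need] <- predict(model, mat_subset(x, need))$label
  test <- setdiff(seq_len(nrow(uv)), train_idx)
  if (!is.null(eval_samples)) {
    smap <- attr(uv, "sample_index")
    in_eval <- vapply(smap, function(s) any(s %in% eval_samples), TRUE)
    test <- intersect(test, which(in_eval))
  }
  classification_metrics(confusion_counts(pred[test], uv$label[test]))
}

# a feature matrix where the catalogue count alone separates the classes,
# all other features held uninformative
separable_matrix <- function(n_per_class, seed = 1) {
  set.seed(seed)
  uv <- data.frame(
    cnt = c(rep(0L, n_per_class), 40L + sample.int(20, n_per_class, TRUE)),
    in_exac = FALSE, in_dbsnp_rare = FALSE,
    ma_category = "missing", pp2_category = "missing",
    context = NA_character_, pattern = "CA",
    sample_frequency = 0.1, mean_vaf = 0.4, flank_weight = NA_real_,
    stringsAsFactors = FALSE
  )
  list(
    x = build_matrix(uv),
    y = rep(c("germline", "somatic"), each = n_per_class)
  )
}

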