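impact_all_nonsilent <- function(records) {
  key_df(records$chrom, records$pos, records$ref, records$alt,
    ma = "medium", pp2 = "benign", effect = "nonsilent"
  )
}

test_that("is_snv accepts single-base substitutions only", {
  expect_true(is_snv("C", "G"))
  expect_false(is_snv("C", "CT")) # insertion
  expect_false(is_snv("CA", "GT")) # multi-base substitution
  expect_false(is_snv("C", "<DEL>"))
  expect_equal(is_snv(c("A", "AT", "N"), c("G", "A", "A")), c(TRUE, FALSE, FALSE))
})

test_that("each quality filter drops records for its stated reason, in order", {
  rec <- data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L),
    ref = c("C", "C", "N", "C", "C", "C", "C"),
    alt = c("G", "CT", "A", "G", "G", "G", "G"),
    depth = c(50L, 50L, 50L, 50L, 9L, 50L, 50L),
    alt_count = c(20L, 20L, 20L, 20L, 4L, 48L, 20L),
    filter = c("PASS", "PASS", "PASS", "q10", "PASS", "PASS", "PASS"),
    gt = c("0/1", "0/1", "0/1", "0/1", "0/1", "1/1", "0/1"),
    stringsAsFactors = FALSE
  )
  path <- write_test_vcf(tempfile(fileext = ".vcf"), "S1", rec)
  # last record annotated silent, the rest nonsilent (N-ref row unannotated)
  imp <- impact_all_nonsilent(rec)
  imp$effect[7] <- "silent"
  cohort <- read_cohort(path, filter_config(drop_homozygous = TRUE), imp)

  expect_equal(nrow(cohort$calls), 1L)
  expect_equal(cohort$calls$pos, 100L)
  expect_equal(
    cohort$filter_log,
    c(
      "non-SNV" = 1L, "N-ref" = 1L, "non-PASS" = 1L, "low-depth" = 1L,
      "homozygous" = 1L, "non-coding/silent" = 1L
    )
  )
  # conservation: in = kept + dropped
  expect_equal(nrow(rec), nrow(cohort$calls) + sum(cohort$filter_log))
})

test_that("an empty VCF yields an empty cohort with one sample", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"), "S_empty", data.frame())
  cohort <- read_cohort(path, filter_config(coding_only = FALSE))
  expect_equal(nrow(cohort$calls), 0L)
  expect_equal(cohort$n_samples, 1L)
  expect_length(cohort$filter_log, 0)
})

test_that("duplicate sample ids and unreadable files are fatal", {
  rec <- data.frame(
    chrom = "chr1", pos = 100L, ref = "C", alt = "G",
    depth = 50L, alt_count = 20L, stringsAsFactors = FALSE
  )
  p1 <- write_test_vcf(tempfile(fileext = ".vcf"), "DUP", rec)
  p2 <- write_test_vcf(tempfile(fileext = ".vcf"), "DUP", rec)
  expect_error(read_cohort(c(p1, p2), filter_config(coding_only = FALSE)), "duplicate sample id")
  expect_error(
    read_cohort(file.path(tempdir(), "nope-missing.vcf"), filter_config(coding_only = FALSE)),
    "nope-missing"
  )
})

test_that("depth is the sum of allelic depths when AD is present", {
  rec <- data.frame(
    chrom = "chr1", pos = 100L, ref = "C", alt = "G",
    depth = 60L, alt_count = 20L, stringsAsFactors = FALSE
  )
  path <- write_test_vcf(tempfile(fileext = ".vcf"), "S1", rec)
  cohort <- read_cohort(path, filter_config(coding_only = FALSE))
  expect_equal(cohort$calls$depth, 60L)
  expect_equal(cohort$calls$alt_count, 20L)
  expect_equal(cohort$calls$genotype_class, "het")
})

test_that("filtering an already-filtered cohort drops nothing further", {
  sim <- simulate_cohort(tiny_config(301))
  cc <- sim_cohort_calls(sim)
  again <- isown:::filter_cohort_calls(
    cc$calls, cc$sample_ids, filter_config(), sim$tables$impact
  )
  expect_equal(nrow(again$calls), nrow(cc$calls))
  expect_length(again$filter_log, 0)
})

test_that("simulated VCFs round-trip through the reader", {
  sim <- simulate_cohort(tiny_config(302), dir = tempfile("simdir"))
  cohort_files <- read_cohort(unname(sim$paths$vcf), filter_config(), sim$tables$impact)
  cohort_mem <- sim_cohort_calls(sim)
  a <- cohort_files$calls[order(
    cohort_files$calls$sample_id,
    cohort_files$calls$chrom, cohort_files$calls$pos
  ), ]
  b <- cohort_mem$calls[order(
    cohort_mem$calls$sample_id,
    cohort_mem$calls$chrom, cohort_mem$calls$pos
  ), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("prediction files round-trip in both formats", {
  set.seed(77)
  n <- 100
  preds <- key_df(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    pos = sample.int(1e5, n),
    ref = sample(c("C", "T"), n, TRUE),
    alt = sample(c("A", "G"), n, TRUE),
    predicted_label = sample(c("somatic", "germline"), n, TRUE),
    score = round(runif(n), 6),
    provenance = sample(c("prelabeled", "classified"), n, TRUE),
    n_samples_with_call = sample.int(20, n, TRUE)
  )
  for (fmt in c("tsv", "vcf")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_predictions(preds, path, fmt)
    back <- read_predictions(path, fmt)
    expect_equal(sort(table(back$predicted_label)), sort(table(preds$predicted_label)))
    expect_equal(back$pos, preds$pos)
    expect_equal(back$score, preds$score, tolerance = 1e-6)
    expect_equal(back$provenance, preds$provenance)
  }
  # header-only file for zero variants
  path <- tempfile(fileext = ".tsv")
  write_predictions(preds[0, ], path, "tsv")
  expect_equal(nrow(read_predictions(path)), 0L)
})

test_that("invalid prediction payloads and unwritable paths are rejected", {
  bad <- key_df("chr1", 1L, "C", "G",
    predicted_label = "maybe", score = 0.5, provenance = "classified"
  )
  expect_error(write_predictions(bad, tempfile()))
  ok <- bad
  ok$predicted_label <- "somatic"
  expect_error(write_predictions(ok, "/nonexistent-dir/x.tsv"), "cannot write")
})
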