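test_that("identical config and seed give byte-identical cohorts", {
  d1 <- tempfile("sim1")
  d2 <- tempfile("sim2")
  s1 <- simulate_cohort(tiny_config(701), dir = d1)
  s2 <- simulate_cohort(tiny_config(701), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
  s3 <- simulate_cohort(tiny_config(702))
  expect_false(identical(s1$calls, s3$calls))
})

test_that("somatic burden and carrier counts follow their sampling models", {
  cfg <- cohort_config(
    seed = 703, n_samples = 10, somatic_per_sample = 100,
    common_pool_size = 2000, rare_per_sample = 10,
    n_chrom = 2, chrom_length = 2e5, min_alt_reads = 0
  )
  sim <- simulate_cohort(cfg)
  n_som <- sum(sim$truth$label == "somatic")
  # Poisson(10 * 100): 4 SD band
  expect_gt(n_som, 1000 - 4 * sqrt(1000))
  expect_lt(n_som, 1000 + 4 * sqrt(1000))

  # a high-frequency allele recurs at its population frequency
  cfg2 <- cohort_config(
    seed = 704, n_samples = 50, somatic_per_sample = 5,
    common_pool_size = 400, rare_per_sample = 2,
    common_freq_shape = c(50, 50), # tight around 0.5
    n_chrom = 2, chrom_length = 1e5, min_alt_reads = 0,
    dbsnp_common_coverage = 1
  )
  sim2 <- simulate_cohort(cfg2)
  calls <- sim2$calls
  # common-pool alleles only (full catalogue coverage set above); private
  # rare germline variants would drag the mean down
  common_keys <- paste(sim2$tables$dbsnp_common$chrom, sim2$tables$dbsnp_common$pos)
  carriers <- table(paste(calls$chrom, calls$pos)[paste(calls$chrom, calls$pos) %in% common_keys])
  # mean carrier count across the pool ~ Binomial(50, ~0.5)
  expect_gt(mean(carriers), 50 * 0.40)
  expect_lt(mean(carriers), 50 * 0.60)
})

test_that("VAF distributions sit where they are configured", {
  cfg <- cohort_config(
    seed = 705, n_samples = 30, somatic_per_sample = 60,
    common_pool_size = 3000, rare_per_sample = 20,
    cn_segments_per_sample = 0, depth_mean = 150, min_alt_reads = 0,
    n_chrom = 2, chrom_length = 3e5
  )
  sim <- simulate_cohort(cfg)
  k <- paste(sim$calls$chrom, sim$calls$pos, sim$calls$ref, sim$calls$alt, sep = ":")
  tk <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref, sim$truth$alt, sep = ":")
  lab <- sim$truth$label[match(k, tk)]
  v <- sim$calls$alt_count / sim$calls$depth
  expect_gt(sum(lab == "germline"), 1000)
  expect_gt(mean(v[lab == "germline"]), 0.47)
  expect_lt(mean(v[lab == "germline"]), 0.53)
  expect_lt(abs(mean(v[lab == "somatic"]) - cfg$somatic_vaf_mean), 0.03)
})

test_that("truth covers every emitted call and labels are allele-level", {
  sim <- simulate_cohort(tiny_config(706))
  k <- paste(sim$calls$chrom, sim$calls$pos, sim$calls$ref, sim$calls$alt)
  tk <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$ref, sim$truth$alt)
  expect_true(all(k %in% tk))
  expect_false(anyDuplicated(tk) > 0)
})

test_that("an infeasible configuration is rejected", {
  expect_error(
    simulate_cohort(cohort_config(
      seed = 1, n_samples = 5, n_chrom = 1, chrom_length = 100,
      common_pool_size = 5000
    )),
    "infeasible"
  )
  expect_error(cohort_config(dbsnp_common_coverage = 1.4), "probabilities")
  expect_error(cohort_config(rare_per_sample = -1), "rates")
})

test_that("truth_confusion counts by allele and flags unknown predictions", {
  truth <- key_df(
    "chr1", 1:10, "C", "T",
    label = rep(c("somatic", "germline"), each = 5)
  )
  perfect <- key_df("chr1", 1:10, "C", "T", predicted_label = truth$label)
  cc <- truth_confusion(perfect, truth)
  expect_equal(cc$fp + cc$fn, 0)
  allg <- perfect
  allg$predicted_label <- "germline"
  cc2 <- truth_confusion(allg, truth)
  expect_equal(cc2$tp, 0)
  expect_equal(cc2$fn, 5)
  # excluded alleles drop out of all cells
  truth$label[1] <- "excluded"
  cc3 <- truth_confusion(perfect, truth)
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 9)
  stranger <- key_df("chrX", 99L, "C", "T", predicted_label = "somatic")
  expect_error(truth_confusion(stranger, truth), "absent from truth")
})

test_that("random predictions land at their expected confusion rates", {
  set.seed(707)
  n <- 4000
  truth <- key_df(
    "chr1", 1:n, "C", "T",
    label = sample(c("somatic", "germline"), n, TRUE)
  )
  p <- 0.3
  preds <- key_df(
    "chr1", 1:n, "C", "T",
    predicted_label = ifelse(runif(n) < p, "somatic", "germline")
  )
  cc <- truth_confusion(preds, truth)
  n_som <- sum(truth$label == "somatic")
  # tp ~ Binomial(n_som, 0.3): 4 SD band
  expect_lt(abs(cc$tp - n_som * p), 4 * sqrt(n_som * p * (1 - p)))
  expect_lt(
    abs(cc$fp - (n - n_som) * p),
    4 * sqrt((n - n_som) * p * (1 - p))
  )
})

test_that("removing the separating structure degrades recovery", {
  # separability degrades along the axes the classifier exploits: catalogue
  # and membership coverage, and the gap between the somatic VAF and the
  # heterozygous 0.5 center (somatic mutations approaching clonality)
  f1_at <- function(vaf_mean, cnt_cov, seed) {
    cfg <- small_config(seed,
      somatic_vaf_mean = vaf_mean, cnt_somatic_coverage = cnt_cov,
      driver_prob = 0.06 * cnt_cov / 0.45,
      common_exac_coverage = 0.5 + 0.45 * cnt_cov,
      dbsnp_common_coverage = 0.55 + 0.8 * cnt_cov
    )
    sim <- simulate_cohort(cfg)
    e2e_metrics(sim, n_train_samples = 10, seed = seed)$f1
  }
  seeds <- 711:715
  strong <- vapply(seeds, function(s) f1_at(0.25, 0.45, s), 0)
  mid <- vapply(seeds, function(s) f1_at(0.35, 0.25, s), 0)
  weak <- vapply(seeds, function(s) f1_at(0.45, 0.05, s), 0)
  expect_gt(mean(strong), mean(mid))
  expect_gt(mean(mid), mean(weak))
})
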