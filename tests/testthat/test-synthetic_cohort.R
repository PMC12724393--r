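small_config <- function(seed = 1L, n = c(FC = 30L, CER = 30L)) {
  cohort_config(n_per_region = n, seed = seed)
}

test_that("cohorts are bit-identical for the same config and seed", {
  a <- simulate_cohort(small_config(seed = 42))
  b <- simulate_cohort(small_config(seed = 42))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$deletions, b$deletions)
  expect_identical(a$snvs, b$snvs)
  expect_identical(a$coverage, b$coverage)
  c2 <- simulate_cohort(small_config(seed = 43))
  expect_false(identical(a$deletions, c2$deletions))
})

test_that("generated tables satisfy every reader invariant (round trip)", {
  cohort <- simulate_cohort(small_config(seed = 7))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  dels <- read_deletion_table(file.path(dir, "deletions.tsv"))
  expect_equal(nrow(dels), nrow(cohort$deletions))
  snvs <- read_snv_table(file.path(dir, "snvs.tsv"))
  expect_equal(nrow(snvs), nrow(cohort$snvs))
  cov <- read_coverage_table(file.path(dir, "coverage.tsv"))
  expect_equal(nrow(cov), nrow(cohort$metadata))
  expect_true(all(dels$bp3 > dels$bp5 + 1))
  expect_true(all(snvs$vaf >= 0 & snvs$vaf <= 1))
})

test_that("copy number and burden structure reflect the configured regions", {
  cohort <- simulate_cohort(small_config(seed = 3, n = c(FC = 60L,
                                                         CER = 60L)))
  cn <- mtdna_copy_number(cohort$coverage$mt_mean_depth,
                          cohort$coverage$autosomal_mean_depth)
  region <- cohort$metadata$region[match(cohort$coverage$sample_id,
                                         cohort$metadata$sample_id)]
  fold <- mean(cn[region == "FC"]) / mean(cn[region == "CER"])
  expect_gt(fold, 2.5)
  expect_lt(fold, 4.2)
  # FC carries more junctions per sample than CER
  per_sample <- table(factor(cohort$deletions$sample_id,
                             levels = cohort$metadata$sample_id))
  expect_gt(mean(per_sample[cohort$metadata$region == "FC"]),
            2 * mean(per_sample[cohort$metadata$region == "CER"]))
})

test_that("haplogroup category drives homoplasmic SNV counts", {
  cohort <- simulate_cohort(small_config(seed = 5, n = c(FC = 40L,
                                                         CER = 40L)))
  profiles <- do.call(rbind, lapply(cohort$metadata$sample_id, function(s) {
    calls <- cohort$snvs[cohort$snvs$sample_id == s, ]
    hap <- cohort$metadata$haplogroup[cohort$metadata$sample_id == s]
    variant_profile(calls, hap)
  }))
  hv_mean <- mean(profiles$homoplasmic_count[profiles$hv_category == "HV"])
  non_mean <- mean(profiles$homoplasmic_count[profiles$hv_category ==
                                                "NonHV"])
  expect_gt(non_mean, 25)
  expect_lt(non_mean, 40)
  expect_gt(hv_mean, 7)
  expect_lt(hv_mean, 17)
})

test_that("age slope of the generator is recoverable by exp_regression", {
  # the common-deletion read % among carriers isolates the per-junction
  # growth rate; the comparison target is the log-scale slope the
  # generating process implies after detection-floor truncation, which the
  # generator reports in closed form
  cohort <- simulate_cohort(small_config(seed = 11, n = c(FC = 80L,
                                                          CER = 10L)))
  meta <- cohort$metadata[cohort$metadata$region == "FC", ]
  common <- vapply(meta$sample_id, function(s) {
    sel <- cohort$deletions$sample_id == s & cohort$deletions$bp5 == 8471L &
      cohort$deletions$bp3 == 13449L
    sum(cohort$deletions$read_pct[sel])
  }, numeric(1))
  carrier <- common > 0
  fit <- exp_regression(common[carrier], meta$age[carrier])
  slope <- unname(fit$coefficients["age"])
  truth <- cohort$derived$common_deletion_log_slope$FC
  se <- unname(fit$standard_errors["age"])
  expect_lt(abs(slope - truth), 3 * se)
  # the derived estimand sits below the raw parameter (truncation) but
  # within a plausible band of it
  raw <- cohort$ground_truth$deletion_params$FC$age_slope
  expect_lt(truth, raw)
  expect_gt(truth, 0.6 * raw)
})

test_that("plant_association shifts only the target junction for carriers", {
  cfg <- small_config(seed = 9, n = c(FC = 60L, CER = 10L))
  cohort <- simulate_cohort(cfg)
  planted <- plant_association(cohort, 14798L, 7816L, 14807L, effect_sd = 3)
  # zero effect is the identity
  expect_identical(plant_association(cohort, 14798L, 7816L, 14807L, 0),
                   cohort)
  expect_error(plant_association(cohort, 14798L, 1L, 2L, 1), "unknown")

  carriers <- unique(cohort$snvs$sample_id[cohort$snvs$position == 14798L &
                                             cohort$snvs$vaf >= 0.9])
  read_of <- function(coh, ids, b5, b3) {
    sel <- coh$deletions$bp5 == b5 & coh$deletions$bp3 == b3 &
      coh$deletions$sample_id %in% ids
    sum(coh$deletions$read_pct[sel])
  }
  expect_gt(read_of(planted, carriers, 7816L, 14807L),
            read_of(cohort, carriers, 7816L, 14807L))
  # another junction's distribution is untouched
  expect_equal(read_of(planted, cohort$metadata$sample_id, 8471L, 13449L),
               read_of(cohort, cohort$metadata$sample_id, 8471L, 13449L))
  # non-carrier values on the target junction are untouched
  non <- setdiff(cohort$metadata$sample_id, carriers)
  expect_equal(read_of(planted, non, 7816L, 14807L),
               read_of(cohort, non, 7816L, 14807L))
})

test_that("planted association is recovered by the scan", {
  cfg <- small_config(seed = 13, n = c(FC = 120L, CER = 10L))
  cohort <- simulate_cohort(cfg)
  cohort <- plant_association(cohort, 14798L, 7816L, 14807L, effect_sd = 3)
  geno <- genotype_matrix(cohort$snvs, cohort$metadata$sample_id)
  pairs <- eligible_pairs(geno, cohort$deletions, cohort$metadata, "FC")
  expect_true(any(pairs$snp_position == 14798L & pairs$bp5 == 7816L))
  covar <- data.frame(
    sample_id = cohort$metadata$sample_id,
    benchmark_coverage = cohort$coverage$benchmark_coverage[
      match(cohort$metadata$sample_id, cohort$coverage$sample_id)],
    age = cohort$metadata$age,
    sex_male = as.integer(cohort$metadata$sex == "M"),
    stringsAsFactors = FALSE)
  res <- run_mtgwas(pairs, geno, cohort$deletions, covar, cohort$metadata)
  hit <- res[res$snp_position == 14798L & res$bp5 == 7816L, ]
  expect_true(hit$significant)
  expect_gt(hit$beta, 0)
})
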