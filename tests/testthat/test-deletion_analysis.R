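test_that("deletion size follows the retained-base breakpoint convention", {
  expect_equal(deletion_size(8471, 13449), 4977L)  # the common deletion
  expect_equal(deletion_size(12369, 14004), 1634L)
  expect_equal(deletion_size(100, 102), 1L)
  # wrapped junction measured circularly
  expect_equal(deletion_size(16500, 100), 16569L - 16400L - 1L)
})

test_that("deletion table reader validates and diagnoses rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tbp5\tbp3\treads\tread_pct\tbenchmark_coverage",
               "s1\t8471\t13449\t25\t0.05\t50000",
               "s1\t6100\t6400\t10\t0.02\t50000",
               "s2\t500\t2000\t5\t0.01\t40000"), f)
  calls <- read_deletion_table(f)
  expect_equal(nrow(calls), 3L)
  expect_false(any(calls$wraps))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tbp5\tbp3\treads\tread_pct\tbenchmark_coverage",
               "s1\t100\t101\t5\t0.01\t1000"), f2)  # bp3 <= bp5 + 1
  expect_error(read_deletion_table(f2), "invalid deletion rows.*1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tbp5\tbp3\treads\tread_pct\tbenchmark_coverage", f3)
  expect_equal(nrow(read_deletion_table(f3)), 0L)

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tbp5\tread_pct", "s\t1\t2"), f4)
  expect_error(read_deletion_table(f4), "missing")
})

test_that("annotate_impact reproduces the common-deletion annotation", {
  cat <- default_catalog()
  ann <- annotate_impact(8471, 13449, cat)
  expect_setequal(ann$complexes, c("I", "IV", "V"))
  expect_false("III" %in% ann$complexes)
  expect_setequal(ann$MDPs, c("mtALTND4", "SHMOOSE"))
  expect_true(all(c("MT-ATP6", "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4") %in%
                    ann$genes$name[ann$genes$impact == "removed"]))
  expect_equal(ann$genes$impact[ann$genes$name == "MT-ND5"], "truncated")
  expect_false(ann$removes_OL)

  # a deletion confined to the control region impacts nothing coding
  ann2 <- annotate_impact(16050, 16500, cat)
  expect_length(ann2$complexes, 0L)
  expect_length(ann2$MDPs, 0L)

  # OL removal flag
  ann3 <- annotate_impact(5700, 5850, cat)
  expect_true(ann3$removes_OL)
})

test_that("annotate_impact agrees with the per-base oracle on random junctions", {
  cat <- default_catalog()
  set.seed(11)
  # spot-check a subset here; the full 1000-junction sweep runs in the
  # acceptance suite
  for (k in 1:50) {
    bp5 <- sample(2:16000, 1L)
    bp3 <- bp5 + 1L + sample.int(min(9000L, 16568L - bp5), 1L)
    ann <- annotate_impact(bp5, bp3, cat)
    want <- brute_span_features(cat, bp5 + 1L, bp3 - 1L)
    got_names <- c(ann$genes$name, ann$tRNAs, ann$MDPs)
    want_sub <- want$name[want$name %in%
                            cat$name[cat$category %in%
                                       c("protein", "tRNA", "MDP")]]
    expect_setequal(got_names, want_sub)
  }
})

test_that("sample metrics compute the normalised burden quantities", {
  cat <- default_catalog()
  top30 <- default_top30_catalog()
  # 5 unique junctions at benchmark 5000 -> 10 per 10k
  calls <- do.call(rbind, lapply(1:5, function(i) {
    del_row("s1", 6000 + i * 10, 9000 + i * 10, benchmark = 5000)
  }))
  m <- sample_metrics(calls, cat, top30)
  expect_equal(m$deletions_per_10k, 10)
  expect_equal(m$cumulative_read_pct, sum(calls$read_pct))

  # single common-deletion call: cumulative = top30 = common; size >= 1000
  one <- del_row("s1", 8471, 13449, read_pct = 0.05)
  m1 <- sample_metrics(one, cat, top30)
  expect_equal(m1$cumulative_read_pct, 0.05)
  expect_equal(m1$top30_read_pct, 0.05)
  expect_equal(m1$common_del_read_pct, 0.05)
  expect_equal(m1$read_pct_lt1000, 0)
  expect_equal(m1$read_pct_ge1000, 0.05)

  # no calls -> all zero
  m0 <- sample_metrics(one[0, ], cat, top30)
  expect_true(all(unlist(m0) == 0))

  # inconsistent benchmark coverage is an error
  bad <- rbind(del_row("s1", 6000, 9000, benchmark = 5000),
               del_row("s1", 6100, 9100, benchmark = 6000))
  expect_error(sample_metrics(bad, cat, top30), "benchmark")
})

test_that("metric identities hold and row order does not matter", {
  cat <- default_catalog()
  top30 <- default_top30_catalog()
  set.seed(3)
  calls <- do.call(rbind, lapply(1:12, function(i) {
    bp5 <- sample(1000:15000, 1L)
    bp3 <- bp5 + 1L + sample.int(min(6000L, 16568L - bp5), 1L)
    del_row("s", bp5, bp3, read_pct = runif(1, 0, 0.2))
  }))
  m <- sample_metrics(calls, cat, top30)
  expect_equal(m$cumulative_read_pct, m$read_pct_lt1000 + m$read_pct_ge1000)
  expect_lte(m$top30_read_pct, m$cumulative_read_pct + 1e-12)
  expect_true(all(unlist(m) >= 0))
  # per-complex read % bounded by cumulative; Complex I dominates any single
  # ND gene by construction of the union
  expect_lte(m$cplx_I, m$cumulative_read_pct + 1e-12)
  # permutation invariance
  m2 <- sample_metrics(calls[sample(nrow(calls)), ], cat, top30)
  expect_equal(m, m2)
})

test_that("cohort summary reports per-region stats and fold change", {
  metrics <- data.frame(sample_id = c("a", "b", "c", "d"),
                        x = c(2, 2, 1, 1))
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     region = c("FC", "FC", "CER", "CER"))
  s <- cohort_summary(metrics, meta)
  expect_equal(s$fold_change[s$metric == "x"], 2)
  # identical vectors give fold change 1
  metrics$x <- 1
  expect_equal(cohort_summary(metrics, meta)$fold_change, 1)
  # empty region errors
  meta2 <- data.frame(sample_id = "zz", region = "FC")
  expect_error(cohort_summary(metrics[0, , drop = FALSE], meta2),
               "zero samples")
})
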