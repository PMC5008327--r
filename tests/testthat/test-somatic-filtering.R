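test_that("each rejection is audited under the first failed rule", {
  cfg <- filter_config()
  # one clean pass plus one planted violation per rule, in rule order
  calls <- rbind(
    make_variant(pos = 1L),
    make_variant(pos = 2L, tumor_depth = 10L, tumor_alt_count = 5L),   # depth
    make_variant(pos = 3L, tumor_alt_count = 3L, tumor_depth = 40L),   # alt reads? vaf 3/40 < .1 too
    make_variant(pos = 4L, tumor_alt_count = 8L, tumor_depth = 100L),  # tumor VAF
    make_variant(pos = 5L, normal_alt_count = 20L),                    # normal VAF 0.2
    make_variant(pos = 6L, dbsnp_member = TRUE),                       # dbSNP
    make_variant(pos = 7L, functional_class = "silent")                # class
  )
  res <- filter_somatic_variants(calls, cfg)
  expect_identical(nrow(res$retained), 1L)
  expect_identical(unname(res$audit),
                   c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(sum(res$audit), nrow(calls) - nrow(res$retained))
})

test_that("normal contamination and silent variants are rejected", {
  v <- make_variant(normal_depth = 100L, normal_alt_count = 20L)
  res <- filter_somatic_variants(v)
  expect_identical(nrow(res$retained), 0L)
  expect_identical(unname(res$audit["normal_vaf"]), 1L)

  s <- filter_somatic_variants(make_variant(functional_class = "silent"))
  expect_identical(unname(s$audit["functional_class"]), 1L)
})

test_that("audit equals planted per-rule counts on a 1,000-call fixture", {
  set.seed(14)
  n <- 1000L
  rule <- sample(c("pass", "depth", "alt_reads", "tumor_vaf", "normal_vaf",
                   "dbsnp", "functional_class"), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    v <- make_variant(pos = i)
    switch(rule[i],
           depth = { v$tumor_depth <- 5L; v$tumor_alt_count <- 5L },
           alt_reads = { v$tumor_depth <- 20L; v$tumor_alt_count <- 3L },
           tumor_vaf = { v$tumor_depth <- 200L; v$tumor_alt_count <- 10L },
           normal_vaf = v$normal_alt_count <- 30L,
           dbsnp = v$dbsnp_member <- TRUE,
           functional_class = v$functional_class <- "noncoding",
           pass = NULL)
    v
  })
  calls <- do.call(rbind, rows)
  res <- filter_somatic_variants(calls)
  planted <- table(factor(rule, levels = c("depth", "alt_reads", "tumor_vaf",
                                           "normal_vaf", "dbsnp",
                                           "functional_class")))
  # alt_reads fixture (3/20 = 0.15 VAF) fails alt_reads first; tumor_vaf
  # fixture (10/200) passes depth and alt reads, fails VAF; attribution is
  # unambiguous by construction
  expect_identical(unname(res$audit), as.integer(planted))
  expect_identical(nrow(res$retained), sum(rule == "pass"))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  spec <- cohort_spec(rng_seed = 77)
  calls <- simulate_somatic_variants(spec)
  cfg <- filter_config()
  once <- filter_somatic_variants(calls, cfg)
  twice <- filter_somatic_variants(once$retained, cfg)
  expect_equal(twice$retained, once$retained)
  expect_identical(sum(twice$audit), 0L)

  # relaxing any single threshold never shrinks the retained set
  relaxed <- list(
    filter_config(min_tumor_depth = 1L),
    filter_config(min_normal_depth = 1L),
    filter_config(min_tumor_alt_reads = 0L),
    filter_config(min_tumor_vaf = 0.06),
    filter_config(max_normal_vaf = 0.049),
    filter_config(exclude_dbsnp = FALSE),
    filter_config(retained_functional_classes = c(nonsilent_classes(), "silent"))
  )
  for (rc in relaxed)
    expect_gte(nrow(filter_somatic_variants(calls, rc)$retained),
               nrow(once$retained))
})

test_that("invalid filter configurations fail before any filtering", {
  expect_error(filter_config(min_tumor_vaf = 0.05, max_normal_vaf = 0.10),
               "max_normal_vaf")
  expect_error(filter_config(min_tumor_depth = 0), "depth")
  expect_error(filter_config(retained_functional_classes = "exotic"), "unknown")
})

test_that("clinical subgroup classification honors the 36-month boundary", {
  meta <- data.frame(
    sample_id = sprintf("P%d", 1:6),
    risk_group = c("high", "high", "high", "high", "low", "intermediate"),
    adverse_event = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    months_to_event = c(12, NA, 36.0, 40, NA, NA),
    stringsAsFactors = FALSE)
  expect_identical(classify_subgroup(meta),
                   c("hr_event3", "high_risk", "hr_event3", "high_risk",
                     "low_risk", "intermediate_risk"))
  bad <- meta; bad$months_to_event[2] <- 10
  expect_error(classify_subgroup(bad), "iff")
})

test_that("per-sample summary uses the lower median and exact counts", {
  counts <- c(S1 = 3L, S2 = 17L, S3 = 40L)
  v <- do.call(rbind, lapply(names(counts), function(s) {
    x <- random_variants(counts[[s]], seed = match(s, names(counts)))
    x$sample_id <- s
    x
  }))
  res <- per_sample_summary(v)
  expect_identical(setNames(res$per_sample$n_nonsilent, res$per_sample$sample_id),
                   counts)
  expect_identical(res$median_nonsilent, 17L)

  one <- random_variants(5, seed = 4); one$sample_id <- "only"
  expect_identical(per_sample_summary(one)$median_nonsilent, 5L)

  # even number of samples: lower median
  v2 <- rbind(v, transform(random_variants(20, seed = 9), sample_id = "S4"))
  expect_identical(per_sample_summary(v2)$median_nonsilent, 17L)
})
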