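test_that("evidence and flag filtering removes the right groups", {
  m <- matrix(100, 5, 9)
  tbl <- toy_protein_table(m, razor = c(1L, 2L, 5L, 3L, 4L),
                           reverse = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                           contaminant = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                           samples = toy_protein_design()$sample)
  out <- filter_protein_groups(tbl)
  expect_equal(out$group_id, c("grp2", "grp5"))
  log <- attr(out, "filter_log")
  expect_equal(log$n[log$step == "single_peptide"], 1)

  # clean table passes unchanged
  clean <- toy_protein_table(m, samples = toy_protein_design()$sample)
  expect_equal(nrow(filter_protein_groups(clean)), 5)

  # total removal warns and returns an empty table
  allone <- toy_protein_table(m, razor = rep(1L, 5),
                              samples = toy_protein_design()$sample)
  expect_warning(out0 <- filter_protein_groups(allone), "removed")
  expect_equal(nrow(out0), 0)
})

test_that("log2 transformation maps zeros to missing and 1 to valid 0", {
  design <- toy_protein_design(2, 2)
  m <- matrix(c(8, 0, 1, 4), 1)
  tbl <- toy_protein_table(m, stage = "filtered", samples = design$sample)
  out <- log2_lfq(tbl, design)
  vals <- as.numeric(out[1, design$sample])
  expect_equal(vals, c(3, NA, 0, 2))
  expect_equal(attr(out, "missing_per_sample")$n_missing, c(0L, 1L, 0L, 0L))

  neg <- toy_protein_table(matrix(c(-1, 1, 1, 1), 1), stage = "filtered",
                           samples = design$sample)
  expect_error(log2_lfq(neg, design), "Negative")
})

test_that("the valid-value filter requires 60% in at least one group", {
  design <- toy_protein_design(6, 3)
  # row 1: 4/6 bait (0.667), 0/3 control -> kept
  # row 2: 3/6 bait (0.5), 1/3 control (0.333) -> removed
  # row 3: fully observed -> kept
  m <- rbind(
    c(20, 21, 22, 23, NA, NA, NA, NA, NA),
    c(20, 21, 22, NA, NA, NA, 20, NA, NA),
    rep(20, 9)
  )
  tbl <- toy_protein_table(m, stage = "log2", samples = design$sample)
  out <- valid_value_filter(tbl, design)
  expect_equal(out$group_id, c("grp1", "grp3"))
  expect_equal(out$n_valid_bait, c(4, 6))
  expect_equal(out$n_valid_control, c(0, 3))
})

test_that("imputation is deterministic, bounded and leaves observed data", {
  design <- toy_protein_design(6, 3)
  set.seed(101)
  m <- matrix(rnorm(200 * 9, 25, 2), 200)
  m[sample(length(m), 300)] <- NA
  tbl <- toy_protein_table(m, stage = "valid", samples = design$sample)
  tbl$n_valid_bait <- rowSums(!is.na(m[, 1:6]))
  tbl$n_valid_control <- rowSums(!is.na(m[, 7:9]))
  a <- impute_downshift(tbl, design, seed = 7)
  b <- impute_downshift(tbl, design, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(anyNA(as.matrix(a[design$sample])))
  mask <- attr(a, "imputation_mask")
  expect_equal(unname(colSums(mask)),
               unname(colSums(is.na(m))))
  # observed cells untouched
  expect_equal(as.matrix(a[design$sample])[!mask], m[!mask])

  # no missing values: identity with an empty mask
  full <- toy_protein_table(matrix(rnorm(45, 25, 2), 5), stage = "valid",
                            samples = design$sample)
  out <- impute_downshift(full, design, seed = 1)
  expect_equal(as.data.frame(out[design$sample]),
               as.data.frame(full[design$sample]), ignore_attr = TRUE)
  expect_false(any(attr(out, "imputation_mask")))
})

test_that("imputed values sit at the stated down-shifted distribution", {
  design <- toy_protein_design(2, 2)
  n <- 100000
  set.seed(102)
  # sample s1 observes Normal(25, 2) on half the rows, missing elsewhere
  base <- rnorm(n, 25, 2)
  m <- cbind(base, base, base, base)
  m[seq(1, n, by = 2), 1] <- NA
  colnames(m) <- design$sample
  tbl <- toy_protein_table(m, stage = "valid", samples = design$sample)
  out <- impute_downshift(tbl, design, seed = 11)
  obs <- m[, 1][!is.na(m[, 1])]
  m1 <- mean(obs)
  s1 <- sd(obs)
  imputed <- out[[design$sample[1]]][is.na(m[, 1])]
  # moments of Normal(m - 1.8 s, (0.3 s)^2); with (m, s) near (25, 2) the
  # targets are 21.4 and 0.6, tolerances ~3 standard errors
  expect_equal(mean(imputed), m1 - 1.8 * s1, tolerance = 0.06 / 21.4)
  expect_equal(sd(imputed), 0.3 * s1, tolerance = 0.02 / 0.6)
  # left-censoring contract: imputed values below the observed mean
  expect_equal(sum(imputed > m1), 0)
})

test_that("pipeline stages refuse out-of-order input", {
  design <- toy_protein_design(6, 3)
  raw <- toy_protein_table(matrix(100, 3, 9), samples = design$sample)
  expect_error(valid_value_filter(raw, design), "expects a table at stage")
  expect_error(impute_downshift(raw, design, seed = 1),
               "expects a table at stage")
  expect_error(call_interactors(raw, design), "expects a table at stage")
  logd <- log2_lfq(filter_protein_groups(raw), design)
  expect_error(log2_lfq(logd, design), "expects a table at stage")
})

test_that("the two-sample t-test matches hand and reference computations", {
  # identical groups
  same <- two_sample_t(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # hand-computed pooled t for (5,6,7) vs (1,2,3):
  # pooled variance 1, se = sqrt(2/3), t = 4 / se = 4.898979, df = 4
  got <- two_sample_t(c(5, 6, 7), c(1, 2, 3))
  expect_equal(got$t, 4 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(-4 / sqrt(2 / 3), 4), tolerance = 1e-12)

  # equals stats::t.test with var.equal = TRUE on random data
  set.seed(103)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(4)
    want <- t.test(a, b, var.equal = TRUE)
    got <- two_sample_t(a, b)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    ww <- t.test(a, b)
    gw <- two_sample_t(a, b, kind = "welch")
    expect_equal(gw$p, ww$p.value, tolerance = 1e-12)
  }

  # zero variance, unequal means: degenerate flag
  deg <- two_sample_t(c(5, 5, 5), c(1, 1, 1))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
})

test_that("null t-test p-values are approximately uniform", {
  set.seed(104)
  m <- matrix(rnorm(5000 * 9, 25, 1), 5000)
  res <- ripscore:::row_t_stats(m, 1:6, s0 = 0)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("the s0 statistic follows its definition", {
  expect_equal(s0_statistic(2, 0.4, 0.1), 4)
  expect_equal(s0_statistic(0, 0.7, 0.3), 0)
  # s0 = 0 reduces to the plain t statistic
  expect_equal(s0_statistic(1.5, 0.5, 0), 3)
  expect_error(s0_statistic(1, 0, 0.1), "`se` must be > 0")
  expect_error(s0_statistic(1, 1, -1), "`s0` must be >= 0")
})

test_that("doubling raw intensities shifts log2 values but not the calls", {
  sim <- simulate_proteome(n_groups = 300, seed = 31)
  run <- function(tbl) {
    tbl |>
      filter_protein_groups() |>
      log2_lfq(sim$design) |>
      valid_value_filter(sim$design) |>
      impute_downshift(sim$design, seed = 5) |>
      call_interactors(sim$design, seed = 5)
  }
  r1 <- run(sim$table)
  doubled <- sim$table
  for (s in sim$design$sample) doubled[[s]] <- 2 * doubled[[s]]
  attr(doubled, "lfq_stage") <- "raw"
  r2 <- run(doubled)
  # differences, statistics and the significant set are location-invariant
  expect_equal(r2$log2_enrichment, r1$log2_enrichment, tolerance = 1e-9)
  expect_equal(r2$d_stat, r1$d_stat, tolerance = 1e-9)
  expect_equal(r2$significant, r1$significant)
})

test_that("degenerate FDR bound declares everything significant", {
  design <- toy_protein_design(3, 3)
  set.seed(105)
  m <- matrix(rnorm(50 * 6, 25, 1), 50)
  tbl <- toy_protein_table(m, stage = "valid", samples = design$sample)
  res <- call_interactors(tbl, design, s0 = 0, fdr = 1.0, seed = 1)
  expect_true(all(res$class != "ns"))
})

test_that("the volcano report round-trips through TSV", {
  sim <- simulate_proteome(n_groups = 100, seed = 32)
  res <- interactome_pipeline(sim$table, sim$design, seed = 2)
  rep1 <- enrichment_report(res)
  expect_equal(rep1$neg_log10_p, -log10(res$p))
  toy <- tibble::tibble(group_id = "g", log2_enrichment = 1, p = 0.01,
                        d_stat = 2, class = "ns", significant = FALSE)
  expect_equal(enrichment_report(toy)$neg_log10_p, 2)
  path <- tempfile(fileext = ".tsv")
  write_result_table(rep1, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(rep1))
})

test_that("identification/quantification bookkeeping counts correctly", {
  design <- toy_protein_design(2, 2)
  m <- rbind(
    c(10, 0, 0, 0),   # identified, bait only
    c(0, 0, 5, 0),    # identified, control only
    c(10, 0, 5, 0),   # both
    c(0, 0, 0, 0)     # never seen
  )
  tbl <- toy_protein_table(m, samples = design$sample)
  qs <- quantification_summary(tbl, design)
  expect_equal(qs$n_identified_either, 3)
  expect_equal(qs$n_quantified_both, 1)
})
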