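# Partition fractions, recovery, depletion, viability and gating.

test_that("single-replicate fractions are the plain percentages", {
  ct <- tibble::tibble(replicate = 1, size_class = "large_cluster",
                       stage1_product = 90, stage2_product = 7,
                       waste = 3)
  pf <- partition_fractions(ct)
  expect_equal(pf$mean_pct[pf$stream == "stage1_product"], 90)
  expect_equal(pf$mean_pct[pf$stream == "stage2_product"], 7)
  expect_equal(pf$mean_pct[pf$stream == "waste"], 3)
  expect_equal(sum(pf$mean_pct), 100)
})

test_that("fractions always sum to 100 percent per class", {
  ct <- make_count_table(list(large_cluster = c(0.918, 0.075, 0.007),
                              small_cluster = c(0.302, 0.489, 0.210)),
                         400, 5, seed = 3)
  pf <- partition_fractions(ct)
  sums <- tapply(pf$mean_pct, pf$size_class, sum)
  expect_equal(as.vector(sums), rep(100, 2), tolerance = 1e-9)
})

test_that("multinomial generator probabilities are recovered", {
  p <- c(0.778, 0.209, 0.013) # blood large-cluster stream fractions
  ct <- make_count_table(list(large_cluster = p), 500, 5, seed = 11)
  pf <- partition_fractions(ct)
  for (k in 1:3) {
    stream <- c("stage1_product", "stage2_product", "waste")[k]
    row <- pf[pf$stream == stream, ]
    expect_lt(abs(row$mean_pct - 100 * p[k]), 2 * max(row$sd_pct, 0.5))
  }
})

test_that("recovery equals one hundred minus the waste fraction", {
  ct <- make_count_table(list(large_cluster = c(0.918, 0.075, 0.007)),
                         300, 4, seed = 9)
  pf <- partition_fractions(ct)
  tr <- total_recovery(ct)
  expect_equal(tr$recovery_pct,
               100 - pf$mean_pct[pf$stream == "waste"],
               tolerance = 1e-9)
})

test_that("published per-stream fractions sum to the printed recoveries", {
  expect_equal(combine_fractions(c(91.8, 7.5))$recovery_pct, 99.3)
  expect_equal(combine_fractions(c(77.8, 20.9))$recovery_pct, 98.7)
  expect_equal(combine_fractions(c(0, 0))$recovery_pct, 0)
  withsd <- combine_fractions(c(91.8, 7.5), c(9.5, 8.8))
  expect_equal(withsd$sd_pct, sqrt(9.5^2 + 8.8^2))
})

test_that("log10 depletion follows count ratios", {
  expect_equal(log10_depletion(1e6, 10)$log10_depletion, 5)
  expect_equal(log10_depletion(500, 500)$log10_depletion, 0)
  # doubling volumes at fixed concentrations leaves depletion unchanged
  expect_equal(log10_depletion(2e6, 20)$log10_depletion,
               log10_depletion(1e6, 10)$log10_depletion)
  cens <- log10_depletion(1e6, 0)
  expect_true(cens$censored)
  expect_equal(cens$log10_depletion, 6)
  # additive over serially composed stages
  d1 <- log10_depletion(1e6, 1e3)$log10_depletion
  d2 <- log10_depletion(1e3, 10)$log10_depletion
  expect_equal(d1 + d2, log10_depletion(1e6, 10)$log10_depletion)
})

test_that("viability records enforce the 200-cell floor", {
  v <- viability_record(188, 200)
  expect_equal(v$viability_pct, 94)
  expect_error(viability_record(150, 180), "200")
})

test_that("viability comparison flags only real differences", {
  # near-identical groups: non-significant, CI straddles zero
  same <- viability_compare(c(93, 94), c(93.2, 93.8))
  expect_false(same$significant)
  expect_lt(same$conf_low, 0)
  expect_gt(same$conf_high, 0)
  # low-rate conditions near control: not significant
  low <- viability_compare(c(93.8, 93.9), c(91.5, 93.0, 94.5))
  expect_false(low$significant)
  # high-rate condition far below control: significant
  high <- viability_compare(c(71.4, 76.2), c(91.5, 93.0, 94.5))
  expect_true(high$significant)
  expect_lt(high$estimate, 0)
})

test_that("cytometry gating partitions every event exactly once", {
  ev <- tibble::tibble(
    nuclear = c(2, 2, 2, 0, 2, 2),
    viability = c(2, 2, 0, 2, 2, 0),
    apoptosis = c(0, 2, 0, 0, 0, 2),
    epithelial = c(2, 2, 2, 2, 0, 0),
    leukocyte = c(0, 0, 0, 0, 2, 2))
  out <- cytometry_classify(ev)
  expect_equal(out$gate,
               c("viable_cancer", "nonviable_cancer", "nonviable_cancer",
                 "excluded", "leukocyte", "leukocyte"))
  expect_true(all(out$gate %in% c("excluded", "viable_cancer",
                                  "nonviable_cancer", "leukocyte")))
  # property: every combination lands in exactly one category
  grid <- tidyr::expand_grid(nuclear = c(0, 2), viability = c(0, 2),
                             apoptosis = c(0, 2), epithelial = c(0, 2),
                             leukocyte = c(0, 2))
  gates <- cytometry_classify(grid)$gate
  expect_equal(length(gates), 32)
  expect_false(any(is.na(gates)))
})

test_that("leukocyte counts subtract reporter nuclei from totals", {
  w <- wbc_counts(c(120, 80), c(20, 5))
  expect_equal(w$wbc, c(100, 75))
  expect_error(wbc_counts(10, 20))
})
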