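test_that("qc_filter applies the >1 razor+unique rule with OR semantics", {
  tab <- toy_table(matrix(1000, 3, 8),
                   razor_wt = c(1L, 0L, 2L), razor_ko = c(1L, 5L, 0L))
  kept <- qc_filter(tab)
  expect_equal(kept$protein_ids, c("P02", "P03"))
  expect_equal(attr(kept, "dropped"), "P01")
})

test_that("log transform centers each sample over present values", {
  # one sample pair (2, 8): log2 -> (1, 3), mean 2 -> (-1, +1)
  v <- matrix(1000, 2, 8)
  v[, 3] <- c(2, 8)
  tab <- toy_table(v)
  nt <- log_transform_normalize(tab)
  expect_equal(unname(nt$values[, 3]), c(-1, 1))
  expect_equal(unname(nt$values[, 1]), c(0, 0))  # all-equal sample

  # missing cell excluded from the mean: hand-computed 3x2 fixture
  v <- matrix(c(4, 16, NA, 8, 8, 8), nrow = 3)
  mu1 <- mean(log2(c(4, 16)))         # = 3
  expect_equal(unname(log2(c(4, 16)) - mu1), c(-1, 1))
  design <- sample_design(c("WT_input", "KO_input"), c("WT", "KO"),
                          c("", ""), c("input", "input"))
  colnames(v) <- design$sample
  tab <- intensity_table(v, paste0("P", 1:3), paste0("G", 1:3),
                         cbind(WT = rep(5L, 3), KO = rep(5L, 3)), design)
  nt <- log_transform_normalize(tab)
  expect_equal(unname(nt$values[, 1]), c(-1, 1, NA))
  expect_equal(unname(nt$values[, 2]), c(0, 0, 0))

  # idempotence: columns already centered, re-centering changes nothing
  expect_equal(colMeans(nt$values, na.rm = TRUE),
               setNames(rep(0, 2), design$sample), tolerance = 1e-12)
})

test_that("imputation draws in [-shift*sd, jitter - shift*sd] per sample", {
  # sample with present normalized values {-1, 0, 1}: sd = 1 (n-1 form)
  v <- matrix(2^c(24, 25, 26, NA), nrow = 4, ncol = 8)
  tab <- toy_table(v)
  nt <- log_transform_normalize(tab)
  present_sd <- sd(nt$values[1:3, 1])
  expect_equal(present_sd, 1)
  imp <- impute_missing(nt, seed = 1)
  expect_true(all(imp$imputed[4, ]))
  expect_true(all(imp$values[4, ] >= -2.5 & imp$values[4, ] <= -2.2))

  # no missing cells: identity for any seed
  full <- toy_table(matrix(2^c(24, 25, 26), 3, 8))
  ntf <- log_transform_normalize(full)
  expect_identical(impute_missing(ntf, seed = 99)$values, ntf$values)

  # <2 present values is an error naming the sample
  v2 <- matrix(2^25, 3, 8); v2[2:3, 5] <- NA
  colnames(v2) <- default_design(3)$sample
  nt2 <- log_transform_normalize(toy_table(v2))
  expect_error(impute_missing(nt2, seed = 1), colnames(v2)[5])
})

test_that("fold change vs input follows the delta definition", {
  # all equal -> delta 0, avg FC 1
  nt <- impute_missing(log_transform_normalize(shifted_table(n = 2)),
                       seed = 1)
  fc <- fold_change_vs_input(nt)
  expect_equal(unname(fc$delta), matrix(0, 2, 3))
  expect_equal(unname(fc$avg_fold_change), c(1, 1))

  # delta (1,2,3) -> avg (2+4+8)/3 ; set per-protein values directly on a
  # normalized table so the arithmetic oracle is exact
  nt$values["P01", c("WT_eluate_c1", "WT_eluate_c2", "WT_eluate_c3")] <-
    c(1, 2, 3)
  fc <- fold_change_vs_input(nt)
  expect_equal(unname(fc$delta["P01", ]), c(1, 2, 3))
  expect_equal(unname(fc$avg_fold_change["P01"]), (2 + 4 + 8) / 3)
  expect_equal(unname(fc$avg_fold_change["P02"]), 1)
  fcg <- fold_change_vs_input(nt, fc_average = "geometric")
  expect_equal(unname(fcg$avg_fold_change["P01"]), 2^2)

  # delta (1,1,1) -> avg 2; inputs shift the other way
  nt$values["P01", c("WT_eluate_c1", "WT_eluate_c2", "WT_eluate_c3")] <- 0.5
  nt$values["P01", "WT_input"] <- -0.5
  expect_equal(unname(fold_change_vs_input(nt)$avg_fold_change["P01"]), 2)
})

test_that("paired t-test matches the formula and degenerate contract", {
  r <- paired_t_test(c(1, -1, 0), c(0, 0, 0))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(2 / (1 / sqrt(3)), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(paired_t_test(c(2, 5, 9), c(2, 5, 9))$p, 1)  # wt == ko
  expect_equal(paired_t_test(c(3, 4, 5), c(2, 3, 4))$p, 0)  # constant shift
})

test_that("paired t-test agrees with stats::t.test on random inputs", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    wt <- rnorm(n); ko <- rnorm(n)
    mine <- paired_t_test(wt, ko)
    ref <- t.test(wt, ko, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("enrichment call enforces all three criteria and sorts", {
  delta <- matrix(c(11, 11, 11, 0.5, 0.5, 0.4, 3, 3, 3.5), 3,
                  byrow = TRUE, dimnames = list(NULL, c("c1", "c2", "c3")))
  rec <- call_enrichment(
    protein_id = c("A", "B", "C"), gene = c("Sh3bgrl3", "gB", "gC"),
    delta = delta,
    avg_fold_change = c(2206.8, 1.4, 10),
    p_value = c(2.4e-4, 0.001, 0.001),
    n_wt_detected = c(3L, 3L, 1L),
    passes_qc = c(TRUE, TRUE, TRUE))
  expect_equal(rec$protein_id, c("A", "C", "B"))  # sorted by FC desc
  expect_equal(rec$enriched[rec$protein_id == "A"], TRUE)
  expect_equal(rec$enriched[rec$protein_id == "B"], FALSE)  # FC <= 1.5
  expect_equal(rec$enriched[rec$protein_id == "C"], FALSE)  # detected 1/3
  # BH column is informational only
  expect_true(all(rec$p_adj >= rec$p_value))
})

test_that("enrichment pipeline is invariant to per-sample scaling", {
  w <- simulate_experiment(sim_config(n_proteins = 80, seed = 21))
  tab <- w$intensities
  rec1 <- enrich_proteins(tab, seed = 5)
  tab2 <- tab
  tab2$values[, "WT_eluate_c2"] <- tab2$values[, "WT_eluate_c2"] * 37.5
  tab2$values[, "KO_input"] <- tab2$values[, "KO_input"] * 0.004
  rec2 <- enrich_proteins(tab2, seed = 5)
  expect_equal(rec1$avg_fold_change, rec2$avg_fold_change,
               tolerance = 1e-9)
  expect_equal(rec1$p_value, rec2$p_value, tolerance = 1e-9)
  expect_identical(rec1$enriched, rec2$enriched)
})

test_that("detection count uses non-imputed WT eluate cells", {
  v <- matrix(1000, 4, 8)
  design <- default_design(3)
  colnames(v) <- design$sample
  v[1, c("WT_eluate_c1", "WT_eluate_c2")] <- NA  # detected once
  v[2, c("WT_eluate_c1", "WT_eluate_c2", "WT_eluate_c3")] <- NA
  tab <- toy_table(v)
  rec <- enrich_proteins(tab, seed = 2)
  expect_equal(rec$n_wt_detected[match(c("P01", "P02", "P03"),
                                       rec$protein_id)], c(1L, 0L, 3L))
  expect_false(any(rec$enriched[match(c("P01", "P02"), rec$protein_id)]))
})
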