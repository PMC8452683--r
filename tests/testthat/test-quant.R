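test_that("standard curves recover slope, efficiency and fit quality", {
  amt <- 10^seq(0, -4)
  ct <- 18 - log2(amt)                       # perfect doubling chemistry
  cv <- fit_standard_curve(amount = amt, ct = ct)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(cv$efficiency, 2, tolerance = 1e-10)
  expect_equal(cv$r_squared, 1)
  expect_length(cv$flags, 0)

  expect_error(fit_standard_curve(amount = c(1, 0.1), ct = c(18, 21.3)),
               "at least 3 distinct")
  noisy <- fit_standard_curve(amount = amt, ct = c(10, 30, 12, 35, 11))
  expect_true("poor_fit" %in% noisy$flags)
})

test_that("Efficiency^dCt quantification matches the closed form", {
  cv <- fit_standard_curve(amount = 10^seq(0, -4), ct = 20 - log2(10^seq(0, -4)))
  expect_equal(quantify(cv$intercept, cv), 1)
  # 3.3219 cycles earlier at E=2 is 10x the reference amount
  expect_equal(quantify(20 - log2(10), cv, reference = c(20, 1)), 10,
               tolerance = 1e-9)
  expect_equal(quantify(NA_real_, cv), 0)

  degenerate <- cv
  degenerate$efficiency <- 1
  expect_error(quantify(20, degenerate), "degenerate curve")
})

test_that("noiseless plates round-trip true amounts to 1e-6 relative error", {
  cfg <- synth_config(seed = 11, qpcr = list(noise_sd = 0))
  truth <- tibble::tibble(
    sample = rep(sprintf("s%d", 1:3), each = 4),
    tissue = "gills",
    target = rep(c("cytbF", "cytbM", "18S", "28S"), 3),
    amount = c(0.2, 0.004, 0.05, 0.02,
               0.001, 0.3, 0.06, 0.025,
               0.07, 0.07, 0.04, 0.018)
  )
  res <- analyze_plate(simulate_qpcr(truth, cfg))
  merged <- merge(res$quantities, truth, by = c("sample", "tissue", "target"))
  expect_true(all(abs(merged$amount.x - merged$amount.y) <=
                    1e-6 * pmax(merged$amount.y, 1e-12)))
  for (cvname in names(res$curves)) {
    expect_equal(res$curves[[cvname]]$efficiency,
                 cfg$qpcr$efficiencies[[cvname]], tolerance = 1e-6)
  }
})

test_that("normalization is a geometric-mean ratio with scale invariance", {
  expect_equal(normalize_to_housekeeping(4, 2, 8), 1)
  expect_equal(normalize_to_housekeeping(3, 3, 3), 1)
  base <- normalize_to_housekeeping(0.3, 0.07, 0.11)
  expect_equal(normalize_to_housekeeping(0.3 * 17, 0.07 * 17, 0.11 * 17), base)
  expect_equal(normalize_to_housekeeping(0.3, 0.11, 0.07), base)
  expect_error(normalize_to_housekeeping(1, 0, 2), "positive")
})

test_that("tissue mitotype calls follow the detection-limit rule", {
  homF <- call_tissue_mitotype(0.5, 0, detection_limit = 1e-4)
  expect_identical(homF$call, "homoplasmic_F")
  het <- call_tissue_mitotype(1.0, 0.01, detection_limit = 1e-4)
  expect_identical(het$call, "heteroplasmic")
  expect_equal(het$log10_imbalance, 2)
  expect_identical(het$imbalance_bucket, "1-2 orders")
  expect_identical(call_tissue_mitotype(1, 0.3, 1e-4)$imbalance_bucket, "<1 order")
  expect_identical(call_tissue_mitotype(1, 1e-3, 1e-4)$imbalance_bucket, ">2 orders")
  expect_identical(call_tissue_mitotype(0, 0, 1e-4)$call, "FAIL")
})

test_that("homoplasmic samples are called correctly under default plate noise", {
  cfg <- synth_config(seed = 13)
  n <- 250
  withr::with_seed(14, {
    truth <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mito <- if (i %% 2 == 0) "M" else "F"
      amt <- stats::rlnorm(1, log(0.1), 0.5)
      tibble::tibble(
        sample = sprintf("s%03d", i), tissue = "gills",
        target = c("cytbF", "cytbM", "18S", "28S"),
        amount = c(if (mito == "F") amt else 0,
                   if (mito == "M") amt else 0,
                   stats::rlnorm(1, log(0.05), 0.3),
                   stats::rlnorm(1, log(0.02), 0.3))
      )
    }))
  })
  res <- analyze_plate(simulate_qpcr(truth, cfg))
  expected <- ifelse(as.integer(substr(res$calls$sample, 2, 4)) %% 2 == 0,
                     "homoplasmic_M", "homoplasmic_F")
  expect_gte(mean(res$calls$call == expected), 0.99)
})

test_that("copy-number fold reports a bootstrap CI around the median ratio", {
  withr::with_seed(15, {
    a <- stats::rlnorm(60, log(150), 0.3)
    b <- stats::rlnorm(60, log(50), 0.3)
  })
  cnf <- copy_number_fold(a, b, reps = 500, seed = 1)
  expect_gt(cnf$fold, 2); expect_lt(cnf$fold, 5)
  expect_true(cnf$ci[1] <= cnf$fold && cnf$fold <= cnf$ci[2])
  expect_equal(copy_number_fold(b, b, reps = 10, seed = 1)$fold, 1)
  expect_error(copy_number_fold(c(1, 2), b), "at least 3")
  expect_error(copy_number_fold(rep(0, 5), b), "degenerate")
})
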