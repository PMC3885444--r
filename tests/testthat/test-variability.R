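test_that("variance F-test matches hand computation and null symmetries", {
  r <- variance_f_test(c(1, 2, 3, 4), c(10, 10.1, 9.9, 10.2), "greater")
  expect_equal(r$f, 100.0, tolerance = 1e-12)
  expect_equal(r$df1, 3L)
  expect_equal(r$df2, 3L)

  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- variance_f_test(x, x, "greater")
  expect_equal(same$f, 1)
  expect_equal(same$p, 0.5, tolerance = 1e-12)

  set.seed(7)
  y <- rnorm(6)
  expect_equal(variance_f_test(x, y, "greater")$p +
                 variance_f_test(y, x, "greater")$p, 1, tolerance = 1e-12)
})

test_that("F-test p-values agree with an incomplete-beta CDF to 1e-10", {
  set.seed(8)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x <- rnorm(n1, 0, runif(1, 0.5, 3)); y <- rnorm(n2, 0, runif(1, 0.5, 3))
    r <- variance_f_test(x, y, "greater")
    # independent route: upper F tail via the regularised incomplete beta
    p_beta <- pbeta((n2 - 1) / ((n2 - 1) + (n1 - 1) * r$f),
                    (n2 - 1) / 2, (n1 - 1) / 2)
    expect_equal(r$p, p_beta, tolerance = 1e-10)
  }
})

test_that("degenerate variances are flagged with the documented p-values", {
  r0 <- variance_f_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(r0$degenerate)
  expect_equal(r0$p, 1)
  r1 <- variance_f_test(c(1, 2, 3), c(2, 2, 2))
  expect_true(r1$degenerate)
  expect_equal(r1$p, 0)
})

test_that("activation filter recovers variance-inflated probes at alpha rate", {
  # 100 probes inflated in GA, 100 in generic, 9800 null
  set.seed(21)
  st <- null_study(10000, n_ga = 34, n_generic = 11, n_medium = 8, seed = 21)
  st$m[1:100, st$meta$treatment == "GA"] <-
    7 + 2 * (st$m[1:100, st$meta$treatment == "GA"] - 7)
  st$m[101:200, st$meta$treatment == "GENERIC"] <-
    7 + 2 * (st$m[101:200, st$meta$treatment == "GENERIC"] - 7)
  got <- activation_variable_probes(st$m, st$meta, alpha = 0.05)
  planted <- rownames(st$m)[1:200]
  # most planted probes recovered; false positives near the union alpha level
  expect_gt(mean(planted %in% got), 0.5)
  # the two filter arms share the medium variance estimate (7 df), so the
  # union false-positive rate sits between alpha and the independence rate
  n_fp <- sum(!got %in% planted)
  expect_gt(n_fp / 9800, 0.04)
  expect_lt(n_fp / 9800, 0.0975)
  keep <- st$meta$treatment != "MEDIUM"
  expect_error(activation_variable_probes(st$m[, keep], st$meta[keep, ],
                                          alpha = 0.05), "MEDIUM")
})

test_that("directional variability counts behave under null and planted data", {
  # planted: generic variance x4 on 300 probes
  st <- null_study(3000, seed = 31)
  gen <- st$meta$treatment == "GENERIC"
  st$m[1:300, gen] <- 7 + 2 * (st$m[1:300, gen] - 7)
  # probe set as the pipeline would supply it: planted plus some null probes
  cmp <- compare_group_variability(st$m, st$meta, rownames(st$m)[1:600])
  expect_gt(cmp$n_generic_more_variable, 3 * cmp$n_ga_more_variable)
  expect_gt(cmp$fold, 3)

  # exchangeable groups, all probes tested: close-to-symmetric counts
  null <- null_study(10000, seed = 32)
  c0 <- compare_group_variability(null$m, null$meta, rownames(null$m))
  expect_gt(c0$fold, 0.7)
  expect_lt(c0$fold, 1.4)
  expect_error(compare_group_variability(null$m, null$meta, character()),
               "empty")
})

test_that("tolerance probe selection applies fold ranking and expression floors", {
  m <- toy_matrix(rbind(c(9, 9, 3, 3),    # up, |FC| 6, passes RS floor
                        c(5.9, 5.9, 2, 2),# up, |FC| 3.9, fails RS floor
                        c(4, 4, 8, 8),    # down, |FC| 4, passes medium floor
                        c(6.5, 6.5, 6, 6)))  # up, |FC| 0.5, passes
  meta <- toy_meta(c("REFERENCE_STANDARD", "REFERENCE_STANDARD",
                     "MEDIUM", "MEDIUM"), colnames(m))
  expect_warning(sel <- select_tolerance_probes(m, meta, n_top = 10),
                 "survive")
  expect_false("P002" %in% sel)  # mean RS 5.9 < 6.00: excluded despite FC
  expect_identical(sel, c("P001", "P003", "P004"))
  expect_identical(select_tolerance_probes(m, meta, n_top = 2),
                   c("P001", "P003"))
  perm <- sample(nrow(m))
  expect_identical(select_tolerance_probes(m[perm, ], meta, n_top = 2),
                   c("P001", "P003"))
})

test_that("tolerance ranges are the inclusive reference-standard min/max", {
  m <- toy_matrix(rbind(c(5, 6, 7), c(4, 4, 9)))
  meta <- toy_meta(c("REFERENCE_STANDARD", "REFERENCE_STANDARD", "GA"),
                   colnames(m))
  rg <- tolerance_ranges(m, meta, rownames(m))
  expect_equal(rg$range_low, c(5, 4))
  expect_equal(rg$range_high, c(6, 4))  # zero-width range is valid
  # every RS sample lies inside its own ranges
  tol_rs <- tolerance_percentages(m, meta, rg, "REFERENCE_STANDARD")
  expect_true(all(tol_rs$table$pct_within == 100))
})

test_that("tolerance percentages count inclusively and stay monotone", {
  m <- toy_matrix(matrix(c(5.5, 4.9, 6.1, 5.0), 1))
  meta <- toy_meta(rep("GA", 4), colnames(m))
  rg <- data.frame(probe_id = "P001", range_low = 5, range_high = 6)
  tol <- tolerance_percentages(m, meta, rg, "GA")
  expect_equal(tol$table$pct_within, 50)

  all_in <- tolerance_percentages(
    toy_matrix(matrix(c(5, 5.5, 6, 6), 1)), meta, rg, "GA")
  expect_equal(all_in$table$pct_within, 100)

  # widening the range never decreases the percentage
  wider <- tolerance_percentages(m, meta,
    data.frame(probe_id = "P001", range_low = 4.9, range_high = 6), "GA")
  expect_gte(wider$table$pct_within, tol$table$pct_within)

  # adding an in-range sample never decreases it
  m5 <- toy_matrix(matrix(c(5.5, 4.9, 6.1, 5.0, 5.2), 1))
  meta5 <- toy_meta(rep("GA", 5), colnames(m5))
  more <- tolerance_percentages(m5, meta5, rg, "GA")
  expect_gte(more$table$pct_within, tol$table$pct_within)
  expect_true(all(diff(tol$curve) >= 0))
})

test_that("failing-probe counts follow the threshold definition", {
  fake <- structure(list(table = data.frame(
    probe_id = c("A", "B", "C"), range_low = 0, range_high = 1,
    pct_within = c(50, 80, 100)), curve = c(50, 80, 100)),
    class = "tolerance_result")
  expect_equal(count_failing(fake, 75), 1L)
  expect_equal(count_failing(fake, 0), 0L)
  expect_equal(count_failing(fake, 100), 2L)
})

test_that("variance-ratio ranking orders, scales and flags degenerates", {
  m <- toy_matrix(rbind(c(1, 3, 5, 1, 2, 3, 4, 2),
                        c(2, 2, 2, 1, 2, 1, 2, 1.5)))
  meta <- toy_meta(c(rep("GENERIC", 3), rep("GA", 5)), colnames(m))
  vr <- variance_ratio_ranking(m, meta)
  expect_equal(vr$ratio[vr$probe_id == "P001"],
               var(c(1, 3, 5)) / var(c(1, 2, 3, 4, 2)))

  st <- null_study(50, seed = 41)
  vr1 <- variance_ratio_ranking(st$m, st$meta)
  m2 <- st$m
  m2[, st$meta$treatment == "GENERIC"] <-
    3 * m2[, st$meta$treatment == "GENERIC"]
  vr2 <- variance_ratio_ranking(m2, st$meta)
  expect_equal(vr2$ratio[order(vr2$probe_id)],
               9 * vr1$ratio[order(vr1$probe_id)], tolerance = 1e-12)

  eq <- toy_matrix(rbind(c(1, 2, 3, 1, 2, 3), c(4, 6, 8, 4, 6, 8),
                         c(0, 5, 1, 0, 5, 1)))
  meta_eq <- toy_meta(c(rep("GENERIC", 3), rep("GA", 3)), colnames(eq))
  expect_true(all(variance_ratio_ranking(eq, meta_eq)$ratio == 1))

  degen <- toy_matrix(rbind(c(1, 2, 3, 5, 5, 5), c(1, 2, 3, 4, 5, 6)))
  meta_d <- toy_meta(c(rep("GENERIC", 3), rep("GA", 3)), colnames(degen))
  vd <- variance_ratio_ranking(degen, meta_d)
  expect_identical(vd$probe_id[1], "P001")
  expect_true(is.infinite(vd$ratio[1]) && vd$degenerate[1])
})

test_that("variance-ratio ties break lexicographically by probe ID", {
  m <- toy_matrix(rbind(c(1, 2, 3, 1, 2, 3), c(1, 2, 3, 1, 2, 3)))
  meta <- toy_meta(c(rep("GENERIC", 3), rep("GA", 3)), colnames(m))
  expect_identical(variance_ratio_ranking(m, meta)$probe_id, c("P001", "P002"))
})

test_that("coefficient of variation matches hand values and is order-invariant", {
  m <- toy_matrix(rbind(c(4, 4, 4), c(2, 4, 6)))
  meta <- toy_meta(rep("GA", 3), colnames(m))
  cv <- coefficient_of_variation(m, meta, "GA")
  expect_equal(cv$cv, c(0, 0.5))
  expect_equal(cv$mean_log2[2], 4)
  perm <- c(3, 1, 2)
  cv2 <- coefficient_of_variation(m[, perm], meta[perm, ], "GA")
  expect_equal(cv2$cv, cv$cv)

  neg <- toy_matrix(matrix(c(-1, -2, -3), 1))
  cvn <- coefficient_of_variation(neg, toy_meta(rep("GA", 3), colnames(neg)), "GA")
  expect_true(cvn$degenerate)
  expect_true(is.na(cvn$cv))
})

test_that("paired-difference t matches the closed form and degenerates safely", {
  r <- glatcomp:::paired_diff_test(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(r$p, 0.07417990, tolerance = 1e-6)
  z <- glatcomp:::paired_diff_test(c(0, 0, 0))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
})

test_that("subsampling sensitivity is seeded, deterministic and powered", {
  sim <- simulate_study(simulation_config(
    n_probes = 1500, batch_sd = 0, activation_fraction = 0.02,
    n_inflated = 75, n_generic_only_up = 0, n_generic_only_down = 0,
    n_ga_rs_only_up = 0, n_ga_rs_only_down = 0, seed = 51))
  a <- subsample_sensitivity(sim$matrix, sim$meta, n_repeats = 10, seed = 5)
  b <- subsample_sensitivity(sim$matrix, sim$meta, n_repeats = 10, seed = 5)
  expect_identical(a$repeats, b$repeats)
  # inflated generic variance: significantly more generic-variable probes
  expect_lt(a$p, 0.05)
  expect_true(all(a$repeats$diff > 0))
})
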