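test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order invariance
  p <- runif(25)
  ord <- sample(25)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
})

test_that("per-probe ANOVA equals lm/aov and the pooled t on two groups", {
  # frozen from the stats::anova(lm(...)) oracle: F = 27, p = 0.001000500
  m <- toy_matrix(matrix(1:9, 1))
  meta <- toy_meta(rep(c("GA", "GENERIC", "MEDIUM"), each = 3), colnames(m))
  res <- anova_per_probe(m, meta, c("GA", "GENERIC", "MEDIUM"))
  expect_equal(res$f, 27, tolerance = 1e-12)
  expect_equal(res$p, 0.001, tolerance = 1e-9)  # (1 + F/3)^-3 exactly

  set.seed(62)
  st <- null_study(30, n_ga = 5, n_generic = 7, n_medium = 4)
  two <- anova_per_probe(st$m, st$meta, c("GA", "GENERIC"))
  for (i in c(1, 9, 30)) {
    x <- st$m[i, st$meta$treatment == "GA"]
    y <- st$m[i, st$meta$treatment == "GENERIC"]
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(two$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(two$f[i], unname(tt$statistic)^2, tolerance = 1e-10)
  }
  g <- anova_per_probe(st$m, st$meta, c("GA", "GENERIC", "MEDIUM"))
  df <- data.frame(y = st$m[17, ], g = factor(st$meta$treatment))
  expect_equal(g$p[17], anova(lm(y ~ g, df))$`Pr(>F)`[1], tolerance = 1e-10)

  meta_small <- st$meta
  meta_small$treatment[meta_small$treatment == "MEDIUM"][-1] <- "OTHER"
  expect_error(anova_per_probe(st$m, meta_small, c("GA", "MEDIUM")), "< 2")
})

test_that("moderated fit limits recover the ordinary and fully shrunk t", {
  set.seed(63)
  st <- null_study(200, n_ga = 4, n_generic = 4, n_medium = 0)
  grp <- factor(st$meta$treatment, c("GA", "GENERIC"))
  design <- model.matrix(~ 0 + grp)
  fit0 <- moderated_linear_fit(st$m, design, c(1, -1), prior_df = 0)
  pooled <- anova_per_probe(st$m, st$meta, c("GA", "GENERIC"))
  expect_equal(fit0$p, pooled$p, tolerance = 1e-10)  # d0 = 0: plain pooled t

  fitI <- moderated_linear_fit(st$m, design, c(1, -1), prior_df = Inf)
  s02 <- attr(fitI, "s02")
  ga <- st$m[, grp == "GA"]; gen <- st$m[, grp == "GENERIC"]
  s2 <- (3 * apply(ga, 1, var) + 3 * apply(gen, 1, var)) / 6  # pooled
  expect_equal(fitI$t, unname(fit0$t * sqrt(s2 / s02)), tolerance = 1e-8)
})

test_that("moderated fit rejects rank-deficient designs naming the alias", {
  st <- null_study(10, n_ga = 3, n_generic = 3, n_medium = 0)
  design <- cbind(a = 1, b = rep(c(1, 0), each = 3), c = rep(c(0, 1), each = 3))
  expect_error(moderated_linear_fit(st$m, design, c(1, 0, 0)), "c")
})

test_that("prior-df estimation recovers the generating d0 within 25%", {
  set.seed(64)
  n <- 8
  for (d0 in c(4, 10, 50)) {
    s2 <- 0.25 * d0 / rchisq(20000, d0)
    m <- toy_matrix(matrix(rnorm(20000 * n, 0, sqrt(s2)), 20000, n))
    fit <- moderated_linear_fit(m, matrix(1, n, 1), 1)
    expect_lt(abs(attr(fit, "d0") - d0) / d0, 0.25)
  }
})

test_that("moderated statistics agree with the limma cross-check", {
  set.seed(65)
  st <- null_study(500, n_ga = 4, n_generic = 5, n_medium = 0)
  grp <- factor(st$meta$treatment, c("GA", "GENERIC"))
  design <- model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  fit <- moderated_linear_fit(st$m, design, c(1, -1))
  lfit <- limma::lmFit(st$m, design)
  lfit <- limma::contrasts.fit(lfit, c(1, -1))
  eb <- limma::eBayes(lfit)
  expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(fit$t, unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(fit$p, unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("variance shrinkage improves ranking at tiny sample sizes", {
  set.seed(66)
  n_probes <- 5000; n_de <- 250
  m <- toy_matrix(matrix(rnorm(n_probes * 6, 7,
                               sqrt(0.3 * 4 / rchisq(n_probes, 4))),
                         n_probes, 6))
  m[1:n_de, 1:3] <- m[1:n_de, 1:3] + 1
  meta <- toy_meta(rep(c("GA", "GENERIC"), each = 3), colnames(m))
  grp <- factor(meta$treatment, c("GA", "GENERIC"))
  design <- model.matrix(~ 0 + grp)
  mod <- moderated_linear_fit(m, design, c(1, -1))
  ord <- moderated_linear_fit(m, design, c(1, -1), prior_df = 0)
  truth <- seq_len(n_probes) <= n_de
  auc <- function(score) {
    r <- rank(score)
    (sum(r[truth]) - n_de * (n_de + 1) / 2) / (n_de * (n_probes - n_de))
  }
  expect_gte(auc(abs(mod$t)), auc(abs(ord$t)))
})

test_that("SNR scores use the sd floor and exhaustive permutations when small", {
  m <- toy_matrix(matrix(c(2, 4, 0, 2), 1))
  r <- snr_test(m, c("S001", "S002"), c("S003", "S004"))
  expect_equal(r$score, 1 / sqrt(2), tolerance = 1e-10)

  # symmetric relabeling: score 0
  m2 <- toy_matrix(matrix(c(1, 2, 2, 1), 1))
  expect_equal(snr_test(m2, c("S001", "S002"), c("S003", "S004"))$score, 0)

  # 3v3: exhaustive enumeration matches a brute-force oracle
  set.seed(67)
  m3 <- toy_matrix(matrix(rnorm(5 * 6, 7, 1), 5, 6))
  got <- snr_test(m3, colnames(m3)[1:3], colnames(m3)[4:6])
  expect_true(attr(got, "exhaustive"))
  splits <- utils::combn(6, 3)
  for (i in seq_len(nrow(m3))) {
    x <- m3[i, ]
    snr1 <- function(ia) {
      a <- x[ia]; b <- x[-ia]
      fl <- function(v) max(sd(v), 0.2 * abs(mean(v)), 0.2)
      (mean(a) - mean(b)) / (fl(a) + fl(b))
    }
    obs <- snr1(1:3)
    perms <- apply(splits, 2, snr1)
    expect_equal(got$p[i], mean(abs(perms) >= abs(obs)), tolerance = 1e-12)
  }
})

test_that("SNR sd floor engages for low-variance classes", {
  m <- toy_matrix(matrix(c(10, 10.001, 8, 8.001), 1))
  r <- snr_test(m, c("S001", "S002"), c("S003", "S004"))
  # floors engage: 0.2*mean(10, 10.001) and 0.2*mean(8, 8.001)
  expect_equal(r$score, 2 / (0.2 * 10.0005 + 0.2 * 8.0005), tolerance = 1e-10)
})

test_that("Welch t matches hand values and is antisymmetric", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1))
  a <- colnames(m)[1:3]; b <- colnames(m)[4:6]
  r <- two_sample_t(m, a, b)
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4, tolerance = 1e-10)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)
  swap <- two_sample_t(m, b, a)
  expect_equal(swap$t, -r$t)
  expect_equal(swap$p, r$p)

  eq <- toy_matrix(matrix(c(1, 2, 1, 2), 1))
  re <- two_sample_t(eq, c("S001", "S002"), c("S003", "S004"))
  expect_equal(re$t, 0)
  expect_equal(re$p, 1)
})

test_that("Wilcoxon p-values are exact when small and approximate when large", {
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1))
  r <- wilcoxon_rank_sum(m, colnames(m)[1:3], colnames(m)[4:6])
  expect_equal(r$p, 0.1, tolerance = 1e-12)

  eqm <- toy_matrix(matrix(c(1, 2, 3, 1, 2, 3), 1))
  re <- wilcoxon_rank_sum(eqm, colnames(eqm)[1:3], colnames(eqm)[4:6])
  expect_equal(re$p, 1)

  set.seed(68)
  big <- toy_matrix(matrix(rnorm(20 * 20), 20, 20))
  appr <- wilcoxon_rank_sum(big, colnames(big)[1:10], colnames(big)[11:20])
  for (i in 1:20) {
    ex <- wilcox.test(big[i, 1:10], big[i, 11:20], exact = TRUE)$p.value
    expect_lt(abs(appr$p[i] - ex), 0.01)
  }
})

test_that("fold-change ranking is ordered, stable and antisymmetric", {
  m <- toy_matrix(rbind(c(9, 9, 3, 3), c(5, 5, 6, 6), c(1, 1, 9, 9)))
  meta <- toy_meta(c("GA", "GA", "GENERIC", "GENERIC"), colnames(m))
  fc <- fold_change_ranking(m, meta, "GA", "GENERIC")
  expect_identical(fc$probe_id, c("P003", "P001", "P002"))
  expect_equal(fc$log2_fc, c(-8, 6, -1))

  perm <- c(2, 4, 1, 3)
  fc2 <- fold_change_ranking(m[, perm], meta[perm, ], "GA", "GENERIC")
  expect_identical(fc2, fc)

  swap <- fold_change_ranking(m, meta, "GENERIC", "GA")
  expect_identical(swap$probe_id, fc$probe_id)
  expect_equal(swap$log2_fc, -fc$log2_fc)
})

test_that("consensus requires all four parametric tests with one direction", {
  tab <- data.frame(
    probe_id = c("A", "B", "C"),
    log2_fc = c(1, 1, -1), t_stat = c(2, 2, -2), snr_score = c(1, 1, -1),
    limma_effect = c(1, 1, -1),
    anova_q = c(0.01, 0.01, 0.02), limma_q = c(0.02, 0.02, 0.01),
    t_q = c(0.04, 0.30, 0.03), snr_q = c(0.049, 0.01, 0.04),
    wilcoxon_q = c(0.01, 0.2, 0.01))
  cons <- consensus_significant(tab)
  expect_identical(cons$probes_higher_ga, "A")        # B: 3 of 4 only
  expect_identical(cons$probes_higher_generic, "C")
  expect_identical(cons$wilcoxon_higher_ga, "A")
  expect_identical(cons$wilcoxon_higher_generic, "C")
  expect_error(consensus_significant(tab[, -6]), "anova_q")
})

test_that("the differential table flags planted group differences", {
  sim <- simulate_study(simulation_config(
    n_probes = 600, batch_sd = 0, activation_fraction = 0,
    n_inflated = 0, n_generic_only_up = 20, n_generic_only_down = 20,
    n_ga_rs_only_up = 0, n_ga_rs_only_down = 0,
    generic_only_effect = 1.5, seed = 69))
  dt <- differential_table(sim$matrix, sim$meta, n_perm = 1000, seed = 7)
  expect_true(all(dt$anova_q >= dt$anova_p))
  expect_true(all(dt$wilcoxon_q >= dt$wilcoxon_p - 1e-12))
  up_in_generic <- sim$truth$probe_sets$generic_only_up
  # planted generic-up probes are detected as higher-in-generic
  expect_gt(mean(up_in_generic %in% dt$probe_id[dt$consensus_higher_generic]),
            0.5)
  # consensus is a subset of every individual significant set
  cons <- dt$probe_id[dt$consensus_higher_ga | dt$consensus_higher_generic]
  for (qc in c("anova_q", "limma_q", "t_q", "snr_q")) {
    expect_true(all(cons %in% dt$probe_id[dt[[qc]] <= 0.05]))
  }
})
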