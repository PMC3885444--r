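# Differential-expression procedures: per-probe one-way ANOVA, an
# empirical-Bayes moderated linear fit, Welch/pooled t, signal-to-noise
# ratio with permutation p-values, Wilcoxon rank-sum, BH-FDR adjustment,
# fold-change ranking and the four-parametric-method consensus.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1; input
#' order preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted values (q-values).
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Group index list from metadata, preserving matrix column order.
group_index <- function(m, meta, groups) {
  meta <- meta[match(colnames(m), meta$sample_id), ]
  idx <- lapply(groups, function(g) which(meta$treatment == g))
  names(idx) <- groups
  bad <- groups[vapply(idx, length, 1L) < 2L]
  if (length(bad)) stop("group(s) with < 2 samples: ", paste(bad, collapse = ", "))
  idx
}

#' Per-probe one-way ANOVA
#'
#' Fixed-effects F-test across the specified treatment groups, computed
#' row-wise from the between/within sums of squares (identical to
#' `anova(lm(...))` per probe; cross-checked in the test suite).
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param groups Treatment labels (>= 2 groups, each with >= 2 samples).
#' @return Data frame `probe_id`, `f`, `p`.
#' @export
anova_per_probe <- function(m, meta, groups) {
  validate_pairing(m, meta)
  if (length(groups) < 2L) stop("need >= 2 groups")
  idx <- group_index(m, meta, groups)
  sub <- m[, unlist(idx), drop = FALSE]
  sizes <- vapply(idx, length, 1L)
  n <- sum(sizes); k <- length(idx)
  gmeans <- vapply(idx, function(i) rowMeans(m[, i, drop = FALSE]),
                   numeric(nrow(m)))
  if (nrow(m) == 1L) gmeans <- matrix(gmeans, nrow = 1L)
  grand <- rowMeans(sub)
  ssb <- as.vector((gmeans - grand)^2 %*% sizes)
  sst <- rowSums((sub - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  # zero within-group variance: F infinite if any between-group spread
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb == 0] <- 1
  data.frame(probe_id = rownames(m), f = unname(f), p = unname(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function (for the prior-df estimator).
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# Method-of-moments fit of a scaled F distribution to residual variances:
# s^2 ~ s0^2 F(df_resid, d0). Returns prior df d0 and prior variance s0^2.
fit_variance_prior <- function(s2, df_resid) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  evar <- stats::var(e) - trigamma(df_resid / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated linear model fit with empirical-Bayes variance shrinkage
#'
#' Per-probe least squares against a shared design matrix; residual
#' variances are shrunk toward a common prior estimated by method of
#' moments on the log residual variances (s~^2 = (d0 s0^2 + d s^2)/(d0 + d)),
#' and the contrast is tested with a moderated t on d0 + d degrees of
#' freedom.
#'
#' @param m Probe x sample matrix.
#' @param design Sample x coefficient design matrix (full rank).
#' @param contrast Numeric coefficient weights (length = ncol(design)).
#' @param prior_df Optional override of the estimated prior df d0: `0`
#'   reproduces the ordinary per-probe t-test, `Inf` uses the common prior
#'   variance for every probe.
#' @return Data frame `probe_id`, `effect`, `t`, `p`, plus attributes
#'   `d0` and `s02`.
#' @export
moderated_linear_fit <- function(m, design, contrast, prior_df = NULL) {
  check_expression_matrix(m)
  design <- as.matrix(design)
  if (nrow(design) != ncol(m)) stop("design rows must match samples")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("design is rank deficient; aliased coefficient(s): ",
         paste(aliased, collapse = ", "))
  }
  df_resid <- ncol(m) - ncol(design)
  if (df_resid < 1L) stop("no residual degrees of freedom")
  if (length(contrast) != ncol(design)) stop("contrast length must match design columns")
  xtx_inv <- chol2inv(chol(crossprod(design)))
  beta <- m %*% design %*% xtx_inv          # probes x coefficients
  fitted <- beta %*% t(design)
  s2 <- rowSums((m - fitted)^2) / df_resid
  prior <- fit_variance_prior(s2, df_resid)
  d0 <- if (is.null(prior_df)) prior$d0 else prior_df
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, nrow(m)) else
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  cvar <- as.numeric(t(contrast) %*% xtx_inv %*% contrast)
  effect <- as.vector(beta %*% contrast)
  tstat <- effect / sqrt(s2_post * cvar)
  df_total <- if (is.infinite(d0)) Inf else d0 + df_resid
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(probe_id = rownames(m), effect = effect, t = tstat,
                    p = p, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_resid") <- df_resid
  out
}

#' Moderated fit for the three-arm drug comparison
#'
#' Convenience wrapper building a group-means design on (GA, GENERIC,
#' MEDIUM). The default contrast reproduces the medium-adjusted effect
#' (GA - generic) - (generic - Medium) = GA - 2*generic + Medium; note this
#' weights the generic arm twice. `contrast = "conventional"` uses the
#' ordinary (GA - Medium) - (generic - Medium) = GA - generic instead.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param contrast `"medium_adjusted"` (default), `"conventional"`, or a
#'   numeric weight vector on (GA, GENERIC, MEDIUM).
#' @param prior_df See [moderated_linear_fit()].
#' @return As [moderated_linear_fit()].
#' @export
moderated_fit_treatment <- function(m, meta,
                                    contrast = c("medium_adjusted", "conventional"),
                                    prior_df = NULL) {
  validate_pairing(m, meta)
  if (is.character(contrast)) {
    contrast <- switch(match.arg(contrast),
                       medium_adjusted = c(1, -2, 1),
                       conventional = c(1, -1, 0))
  }
  idx <- group_index(m, meta, c("GA", "GENERIC", "MEDIUM"))
  keep <- unlist(idx)
  sub <- m[, keep, drop = FALSE]
  grp <- factor(rep(names(idx), vapply(idx, length, 1L)),
                levels = c("GA", "GENERIC", "MEDIUM"))
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- levels(grp)
  moderated_linear_fit(sub, design, contrast, prior_df = prior_df)
}

# Signal-to-noise scores per probe with the GenePattern sd floor:
# each class sd is floored at max(0.2 * |class mean|, 0.2).
row_snr_scores <- function(m, idxA, idxB) {
  a <- m[, idxA, drop = FALSE]; b <- m[, idxB, drop = FALSE]
  muA <- rowMeans(a); muB <- rowMeans(b)
  sdA <- pmax(sqrt(row_vars(a)), pmax(0.2 * abs(muA), 0.2))
  sdB <- pmax(sqrt(row_vars(b)), pmax(0.2 * abs(muB), 0.2))
  (muA - muB) / (sdA + sdB)
}

#' Signal-to-noise ratio test with permutation p-values
#'
#' Score = (mu_A - mu_B) / (sd_A + sd_B) with each class sd floored at
#' max(0.2 |mu|, 0.2). Two-sided significance by class-label permutation of
#' the per-probe score. When the number of distinct label splits is at most
#' 10,000 the permutation null is enumerated exhaustively (p = b / n_splits,
#' observed split included); otherwise `n_perm` random permutations with
#' add-one smoothing p = (b + 1) / (n_perm + 1).
#'
#' @param m Probe x sample matrix.
#' @param classA,classB Sample IDs of the two classes (>= 2 each).
#' @param n_perm Random permutation count (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation draw.
#' @return Data frame `probe_id`, `score`, `p`, with attribute `exhaustive`.
#' @export
snr_test <- function(m, classA, classB, n_perm = 1000, seed = 1) {
  check_expression_matrix(m)
  idxA <- match(classA, colnames(m)); idxB <- match(classB, colnames(m))
  if (anyNA(idxA) || anyNA(idxB)) stop("class sample(s) not in matrix")
  if (length(idxA) < 2L || length(idxB) < 2L) stop("each class needs >= 2 samples")
  if (n_perm < 100) warning("n_perm < 100 gives coarse permutation p-values")
  obs <- row_snr_scores(m, idxA, idxB)
  pool <- c(idxA, idxB)
  nA <- length(idxA); n <- length(pool)
  n_splits <- choose(n, nA)
  exhaustive <- n_splits <= 10000
  if (exhaustive) {
    combos <- utils::combn(n, nA)
    ge <- integer(nrow(m))
    for (j in seq_len(ncol(combos))) {
      pa <- pool[combos[, j]]; pb <- pool[-combos[, j]]
      ge <- ge + (abs(row_snr_scores(m, pa, pb)) >= abs(obs))
    }
    p <- ge / ncol(combos)
  } else {
    set.seed(seed)
    ge <- integer(nrow(m))
    for (j in seq_len(n_perm)) {
      perm <- sample(pool)
      ge <- ge + (abs(row_snr_scores(m, perm[seq_len(nA)], perm[-seq_len(nA)])) >= abs(obs))
    }
    p <- (ge + 1) / (n_perm + 1)
  }
  out <- data.frame(probe_id = rownames(m), score = unname(obs),
                    p = unname(pmin(p, 1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Per-probe two-sample t-test
#'
#' Welch (unequal-variance) by default; `var_equal = TRUE` gives the pooled
#' test. Two-sided p-values.
#'
#' @param m Probe x sample matrix.
#' @param classA,classB Sample IDs (>= 2 each).
#' @param var_equal Pooled-variance test instead of Welch.
#' @return Data frame `probe_id`, `t`, `df`, `p`.
#' @export
two_sample_t <- function(m, classA, classB, var_equal = FALSE) {
  check_expression_matrix(m)
  a <- m[, classA, drop = FALSE]; b <- m[, classB, drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  if (nA < 2L || nB < 2L) stop("each class needs >= 2 samples")
  vA <- row_vars(a); vB <- row_vars(b)
  delta <- rowMeans(a) - rowMeans(b)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- rep(nA + nB - 2, nrow(m))
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  t <- delta / se
  t[se == 0 & delta == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df = df)
  p[se == 0 & delta == 0] <- 1
  data.frame(probe_id = rownames(m), t = unname(t), df = unname(df),
             p = unname(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-probe Wilcoxon rank-sum test
#'
#' Exact two-sided p-values when the combined sample size is at most 20 and
#' the data carry no ties; otherwise the normal approximation with
#' continuity correction.
#'
#' @param m Probe x sample matrix.
#' @param classA,classB Sample IDs (>= 1 each).
#' @return Data frame `probe_id`, `w`, `p`.
#' @export
wilcoxon_rank_sum <- function(m, classA, classB) {
  check_expression_matrix(m)
  a <- m[, classA, drop = FALSE]; b <- m[, classB, drop = FALSE]
  small <- (ncol(a) + ncol(b)) <= 20L
  res <- vapply(seq_len(nrow(m)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    exact <- small && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2L))
  data.frame(probe_id = rownames(m), w = res[1L, ], p = pmin(res[2L, ], 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change ranking
#'
#' Top-k probes by absolute mean difference (log2 fold change) between two
#' treatment groups, with the signed fold change reported and probe-ID
#' tie-break.
#'
#' @param m Probe x sample matrix (log2 scale).
#' @param meta Sample metadata.
#' @param groupA,groupB Treatment labels; fold change is mean(A) - mean(B).
#' @param k Number of probes to return (default all).
#' @return Data frame `probe_id`, `log2_fc`, `rank`.
#' @export
fold_change_ranking <- function(m, meta, groupA, groupB, k = nrow(m)) {
  validate_pairing(m, meta)
  fa <- rowMeans(group_matrix(m, meta, groupA, min_n = 1L))
  fb <- rowMeans(group_matrix(m, meta, groupB, min_n = 1L))
  fc <- fa - fb
  ord <- order(-abs(fc), rownames(m))
  out <- data.frame(probe_id = rownames(m)[ord], log2_fc = unname(fc[ord]),
                    rank = seq_along(fc),
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Build the full differential table for GA vs generic
#'
#' Runs the five tests (ANOVA, moderated linear fit, Welch t, SNR with
#' permutations, Wilcoxon), BH-adjusts each, and adds fold change and the
#' four-parametric-method consensus flags.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with GA, GENERIC and MEDIUM samples.
#' @param alpha Consensus significance threshold on adjusted values.
#' @param n_perm,seed Passed to [snr_test()].
#' @param contrast Passed to [moderated_fit_treatment()].
#' @return Data frame, one row per probe, with all statistics, q-values and
#'   logical `consensus_higher_ga` / `consensus_higher_generic` columns.
#' @export
differential_table <- function(m, meta, alpha = 0.05, n_perm = 1000,
                               seed = 1, contrast = "medium_adjusted") {
  validate_pairing(m, meta)
  ga_ids <- intersect(colnames(m), group_samples(meta, "GA"))
  gen_ids <- intersect(colnames(m), group_samples(meta, "GENERIC"))
  an <- anova_per_probe(m, meta, c("GA", "GENERIC"))
  lf <- moderated_fit_treatment(m, meta, contrast = contrast)
  tt <- two_sample_t(m, ga_ids, gen_ids)
  sn <- snr_test(m, ga_ids, gen_ids, n_perm = n_perm, seed = seed)
  wx <- wilcoxon_rank_sum(m, ga_ids, gen_ids)
  fc <- rowMeans(m[, ga_ids, drop = FALSE]) - rowMeans(m[, gen_ids, drop = FALSE])
  tab <- data.frame(
    probe_id = rownames(m),
    mean_ga = rowMeans(m[, ga_ids, drop = FALSE]),
    mean_generic = rowMeans(m[, gen_ids, drop = FALSE]),
    log2_fc = unname(fc),
    anova_f = an$f, anova_p = an$p, anova_q = bh_adjust(an$p),
    limma_effect = lf$effect, limma_t = lf$t, limma_p = lf$p,
    limma_q = bh_adjust(lf$p),
    t_stat = tt$t, t_p = tt$p, t_q = bh_adjust(tt$p),
    snr_score = sn$score, snr_p = sn$p, snr_q = bh_adjust(sn$p),
    wilcoxon_w = wx$w, wilcoxon_p = wx$p, wilcoxon_q = bh_adjust(wx$p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  cons <- consensus_significant(tab, alpha = alpha)
  tab$consensus_higher_ga <- tab$probe_id %in% cons$probes_higher_ga
  tab$consensus_higher_generic <- tab$probe_id %in% cons$probes_higher_generic
  tab
}

#' Four-method consensus sets
#'
#' A probe enters a consensus set iff all four parametric adjusted values
#' (ANOVA, moderated fit, t, SNR) are at or below `alpha` and every signed
#' statistic (fold change, t, SNR score, moderated effect) points the same
#' way. Wilcoxon-only significant sets are reported separately (they feed
#' the pathway enrichment).
#'
#' @param table Output of [differential_table()] (or any data frame with the
#'   same q and sign columns).
#' @param alpha Threshold on adjusted values (default 0.05).
#' @return List `probes_higher_ga`, `probes_higher_generic`,
#'   `wilcoxon_higher_ga`, `wilcoxon_higher_generic`.
#' @export
consensus_significant <- function(table, alpha = 0.05) {
  qcols <- c("anova_q", "limma_q", "t_q", "snr_q")
  if (!all(qcols %in% colnames(table))) {
    stop("table lacks the four parametric q columns: ",
         paste(setdiff(qcols, colnames(table)), collapse = ", "))
  }
  all_sig <- Reduce(`&`, lapply(table[qcols], function(q) q <= alpha))
  signs <- sign(cbind(table$log2_fc, table$t_stat, table$snr_score,
                      table$limma_effect))
  agree_up <- rowSums(signs > 0) == ncol(signs)
  agree_dn <- rowSums(signs < 0) == ncol(signs)
  wil_sig <- table$wilcoxon_q <= alpha
  list(
    probes_higher_ga = table$probe_id[all_sig & agree_up],
    probes_higher_generic = table$probe_id[all_sig & agree_dn],
    wilcoxon_higher_ga = table$probe_id[wil_sig & table$log2_fc > 0],
    wilcoxon_higher_generic = table$probe_id[wil_sig & table$log2_fc < 0]
  )
}
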