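# Batch-consistency analyses: variance F-tests with an activation filter,
# the reference-standard tolerance-range method, variance-ratio ranking,
# coefficient-of-variation analysis and the subsampling sensitivity check.

#' Two-sample variance F-test
#'
#' F = s_x^2 / s_y^2 with (n_x - 1, n_y - 1) degrees of freedom; variances
#' use denominator n - 1. `alternative = "greater"` tests var(x) > var(y).
#'
#' @param x,y Numeric sample vectors, each of length >= 2.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return List with `f`, `df1`, `df2`, `p`, `direction` (which group has
#'   the larger sample variance) and `degenerate` (zero-variance input).
#' @export
variance_f_test <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  if (vy == 0) {
    # undefined ratio: both degenerate -> p = 1; only y degenerate -> p = 0
    p <- if (vx == 0) 1 else 0
    return(list(f = NA_real_, df1 = df1, df2 = df2, p = p,
                direction = if (vx > 0) "x" else "none", degenerate = TRUE))
  }
  f <- vx / vy
  pg <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p <- if (alternative == "greater") pg else 2 * min(pg, 1 - pg)
  list(f = f, df1 = df1, df2 = df2, p = min(p, 1),
       direction = if (vx > vy) "x" else if (vy > vx) "y" else "none",
       degenerate = FALSE)
}

# Vectorised one-sided F-test p-values for var(row of mx) > var(row of my).
row_f_pvalues <- function(mx, my) {
  f <- row_vars(mx) / row_vars(my)
  stats::pf(f, ncol(mx) - 1L, ncol(my) - 1L, lower.tail = FALSE)
}

#' Probes with activation-induced variability
#'
#' A probe qualifies when it is significantly more variable under either
#' drug arm than under vehicle (one-sided F-test vs MEDIUM, union over the
#' two arms), separating biologically induced variability from assay noise.
#' P-values are used raw at `alpha` (no multiplicity correction), matching
#' the descriptive use of the filter.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata; must contain GA, GENERIC and MEDIUM samples.
#' @param alpha Per-test significance level (default 0.05).
#' @return Character vector of qualifying probe IDs.
#' @export
activation_variable_probes <- function(m, meta, alpha = 0.05) {
  validate_pairing(m, meta)
  ga <- group_matrix(m, meta, "GA", min_n = 2L)
  gen <- group_matrix(m, meta, "GENERIC", min_n = 2L)
  med <- group_matrix(m, meta, "MEDIUM", min_n = 2L)
  p_ga <- row_f_pvalues(ga, med)
  p_gen <- row_f_pvalues(gen, med)
  rownames(m)[p_ga < alpha | p_gen < alpha]
}

#' Directional variability comparison between generic and GA
#'
#' For each probe in `probes`, one-sided F-tests in both directions between
#' the generic and GA groups at `alpha`; returns the per-direction counts of
#' significant probes and their ratio (the "fold" difference in variability).
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param probes Probe IDs to test (typically [activation_variable_probes()]).
#' @param alpha Per-test level.
#' @return List with `n_generic_more_variable`, `n_ga_more_variable`, `fold`.
#' @export
compare_group_variability <- function(m, meta, probes, alpha = 0.05) {
  validate_pairing(m, meta)
  if (!length(probes)) stop("empty probe set")
  missing <- setdiff(probes, rownames(m))
  if (length(missing)) stop("probes not in matrix: ", paste(utils::head(missing), collapse = ", "))
  sub <- m[probes, , drop = FALSE]
  ga <- group_matrix(sub, meta, "GA", min_n = 2L)
  gen <- group_matrix(sub, meta, "GENERIC", min_n = 2L)
  n_gen <- sum(row_f_pvalues(gen, ga) < alpha)
  n_ga <- sum(row_f_pvalues(ga, gen) < alpha)
  list(n_generic_more_variable = n_gen, n_ga_more_variable = n_ga,
       fold = n_gen / n_ga)
}

#' Select probes for the tolerance analysis
#'
#' Ranks probes by absolute fold change of reference standard vs medium and
#' keeps the top `n_top` after an expression floor: probes up in RS need a
#' mean RS expression of at least `expr_floor`; probes down in RS need a
#' mean medium expression of at least `expr_floor` (both on the log2 scale).
#' The floor keeps noisy low-intensity probes out of the tolerance panel.
#'
#' @param m Probe x sample matrix (log2 scale).
#' @param meta Sample metadata with REFERENCE_STANDARD and MEDIUM samples.
#' @param n_top Number of probes to keep (default 1000).
#' @param expr_floor Expression floor in log2 units (default 6.00).
#' @return Character vector of probe IDs, by descending |fold change| with
#'   probe-ID tie-break.
#' @export
select_tolerance_probes <- function(m, meta, n_top = 1000, expr_floor = 6.00) {
  validate_pairing(m, meta)
  rs <- group_matrix(m, meta, "REFERENCE_STANDARD", min_n = 1L)
  med <- group_matrix(m, meta, "MEDIUM", min_n = 1L)
  mean_rs <- rowMeans(rs); mean_med <- rowMeans(med)
  fc <- mean_rs - mean_med
  pass <- ifelse(fc >= 0, mean_rs >= expr_floor, mean_med >= expr_floor)
  ids <- rownames(m)[pass]
  ids <- ids[order(-abs(fc[pass]), ids)]
  if (length(ids) < n_top) {
    warning("only ", length(ids), " probes survive the expression floor; ",
            "returning all of them")
    return(ids)
  }
  ids[seq_len(n_top)]
}

#' Reference-standard tolerance ranges
#'
#' The acceptable window per probe is the inclusive interval between the
#' minimum and maximum expression observed across reference-standard
#' samples.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with >= 2 REFERENCE_STANDARD samples.
#' @param probes Probe IDs (typically [select_tolerance_probes()]).
#' @return Data frame `probe_id`, `range_low`, `range_high`.
#' @export
tolerance_ranges <- function(m, meta, probes) {
  validate_pairing(m, meta)
  rs <- group_matrix(m[probes, , drop = FALSE], meta, "REFERENCE_STANDARD",
                     min_n = 2L)
  data.frame(probe_id = probes,
             range_low = apply(rs, 1L, min),
             range_high = apply(rs, 1L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of product samples within tolerance
#'
#' Per probe, the percentage of the product group's samples falling inside
#' the inclusive tolerance range, plus the ascending sorted curve over
#' probes used for the process-specification plot.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param ranges Output of [tolerance_ranges()].
#' @param product_group Treatment label of the product under assessment
#'   (e.g. `"GA"` or `"GENERIC"`).
#' @return Object of class `tolerance_result`: list with `table` (probe_id,
#'   range_low, range_high, pct_within), `curve` (ascending percentages,
#'   probe-ID tie-break), `product_group`, `n_samples`.
#' @export
tolerance_percentages <- function(m, meta, ranges, product_group) {
  validate_pairing(m, meta)
  prod <- group_matrix(m[ranges$probe_id, , drop = FALSE], meta,
                       product_group, min_n = 1L)
  inside <- prod >= ranges$range_low & prod <= ranges$range_high
  pct <- 100 * rowSums(inside) / ncol(prod)
  tab <- cbind(ranges, pct_within = unname(pct))
  ord <- order(tab$pct_within, tab$probe_id)
  structure(list(table = tab, curve = tab$pct_within[ord],
                 product_group = product_group, n_samples = ncol(prod)),
            class = "tolerance_result")
}

#' Count probes failing a tolerance specification
#'
#' @param tol A `tolerance_result`.
#' @param threshold_pct Processing specification: required percentage of
#'   samples within range, in `[0, 100]`.
#' @return Number of probes with `pct_within < threshold_pct`.
#' @export
count_failing <- function(tol, threshold_pct) {
  stopifnot(inherits(tol, "tolerance_result"),
            threshold_pct >= 0, threshold_pct <= 100)
  sum(tol$table$pct_within < threshold_pct)
}

#' Variance-ratio ranking
#'
#' Per probe r = var(generic) / var(GA), sorted descending with probe-ID
#' tie-break. A zero GA variance yields an `Inf` sentinel, sorted first and
#' flagged.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with >= 2 samples in each of GENERIC and GA.
#' @return Data frame `probe_id`, `ratio`, `rank`, `degenerate`.
#' @export
variance_ratio_ranking <- function(m, meta) {
  validate_pairing(m, meta)
  gen <- group_matrix(m, meta, "GENERIC", min_n = 2L)
  ga <- group_matrix(m, meta, "GA", min_n = 2L)
  v_ga <- row_vars(ga)
  ratio <- ifelse(v_ga == 0, Inf, row_vars(gen) / v_ga)
  ord <- order(-ratio, rownames(m))
  data.frame(probe_id = rownames(m)[ord], ratio = unname(ratio[ord]),
             rank = seq_along(ratio),
             degenerate = unname(v_ga[ord] == 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-probe coefficient of variation
#'
#' CV = sd(log2 x) / mean(log2 x) within the given treatment group, paired
#' with the mean intensity for CV-vs-intensity plots. Merge technical
#' replicates first ([merge_technical_replicates()]) so the CV reflects
#' biological rather than technical variability.
#'
#' @param m Probe x sample matrix (log2 scale).
#' @param meta Sample metadata.
#' @param group Treatment label.
#' @return Data frame `probe_id`, `mean_log2`, `cv`, `degenerate` (mean <= 0,
#'   CV undefined).
#' @export
coefficient_of_variation <- function(m, meta, group) {
  validate_pairing(m, meta)
  g <- group_matrix(m, meta, group, min_n = 2L)
  mu <- rowMeans(g)
  sdv <- sqrt(row_vars(g))
  data.frame(probe_id = rownames(m), mean_log2 = unname(mu),
             cv = unname(ifelse(mu > 0, sdv / mu, NA_real_)),
             degenerate = unname(mu <= 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subsampling sensitivity analysis for the variability comparison
#'
#' Equalises group sizes: repeatedly draws `subset_size` GA samples without
#' replacement (after technical-replicate merging), re-runs the activation
#' filter and the directional variability counts against the full generic
#' group, and tests the per-repeat count differences with a two-sided
#' paired t-test.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param subset_size GA samples per draw (default 11, matching the generic
#'   group).
#' @param n_repeats Number of random draws (default 10).
#' @param seed Integer seed; per-repeat substream seeds are derived from it
#'   and recorded in the output.
#' @param alpha F-test level.
#' @return List with `repeats` (data frame: repeat, seed, n_generic, n_ga,
#'   diff), `t`, `p`, `degenerate` (all differences zero; t undefined,
#'   p reported as 1).
#' @export
subsample_sensitivity <- function(m, meta, subset_size = 11, n_repeats = 10,
                                  seed = 1, alpha = 0.05) {
  validate_pairing(m, meta)
  merged <- merge_technical_replicates(m, meta)
  m2 <- merged$matrix; meta2 <- merged$meta
  ga_ids <- group_samples(meta2, "GA")
  if (length(ga_ids) < subset_size) {
    stop("GA group has ", length(ga_ids), " samples after merging; need >= ",
         subset_size)
  }
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  rows <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    set.seed(repeat_seeds[[i]])
    keep_ga <- sample(ga_ids, subset_size)
    keep <- meta2$sample_id %in% keep_ga | meta2$treatment != "GA"
    meta_i <- meta2[keep, ]
    m_i <- m2[, meta_i$sample_id, drop = FALSE]
    probes <- activation_variable_probes(m_i, meta_i, alpha = alpha)
    cmp <- if (length(probes)) {
      compare_group_variability(m_i, meta_i, probes, alpha = alpha)
    } else list(n_generic_more_variable = 0L, n_ga_more_variable = 0L)
    rows[[i]] <- data.frame(repeat_idx = i, seed = repeat_seeds[[i]],
                            n_generic = cmp$n_generic_more_variable,
                            n_ga = cmp$n_ga_more_variable)
  }
  rep_df <- do.call(rbind, rows)
  rep_df$diff <- rep_df$n_generic - rep_df$n_ga
  c(list(repeats = rep_df), paired_diff_test(rep_df$diff))
}

# Two-sided one-sample t-test on paired differences; constant input is
# degenerate (t undefined): p = 1 when all differences are zero, 0 otherwise.
paired_diff_test <- function(d) {
  if (stats::sd(d) == 0) {
    return(list(t = if (d[[1L]] == 0) NA_real_ else Inf * sign(d[[1L]]),
                p = if (d[[1L]] == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}
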