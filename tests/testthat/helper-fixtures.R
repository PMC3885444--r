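# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive (direct enumeration / step-by-step computation) and
# never reuse package code paths.

# Minimal matrix with probe/sample names.
toy_matrix <- function(values, n_probes = nrow(values)) {
  m <- as.matrix(values)
  dimnames(m) <- list(sprintf("P%03d", seq_len(nrow(m))),
                      sprintf("S%03d", seq_len(ncol(m))))
  m
}

# Metadata for a vector of treatments, one sample each unless ids given.
toy_meta <- function(treatments, sample_ids = sprintf("S%03d", seq_along(treatments)),
                     chip = "C1", replicate_group = sample_ids) {
  data.frame(sample_id = sample_ids, treatment = treatments,
             chip_batch = rep_len(chip, length(treatments)),
             product_batch = "B1", replicate_group = replicate_group,
             stringsAsFactors = FALSE)
}

# Null study: iid Gaussian groups GA / GENERIC / MEDIUM (+ optional RS).
null_study <- function(n_probes, n_ga = 34, n_generic = 11, n_medium = 8,
                       n_rs = 0, sd = 1, seed = 1) {
  set.seed(seed)
  n <- n_ga + n_generic + n_medium + n_rs
  m <- toy_matrix(matrix(rnorm(n_probes * n, 7, sd), n_probes, n))
  trt <- c(rep("GA", n_ga), rep("GENERIC", n_generic),
           rep("MEDIUM", n_medium), rep("REFERENCE_STANDARD", n_rs))
  list(m = m, meta = toy_meta(trt, colnames(m)))
}

# --- independent oracles -------------------------------------------------

# BH step-up by the direct formula with an explicit sort.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by direct summation of the pmf.
hyper_oracle <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all label splits.
wilcox_exact_oracle <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  splits <- utils::combn(length(pool), nx)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ws <- apply(splits, 2L, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Weighted-KS enrichment score by an explicit step-by-step walk.
es_oracle <- function(scores, hit, p = 1) {
  n <- length(scores)
  w <- abs(scores)^p
  denom_hit <- sum(w[hit])
  denom_miss <- n - sum(hit)
  run <- 0; hi <- -Inf; lo <- Inf
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / denom_hit else -1 / denom_miss
    hi <- max(hi, run); lo <- min(lo, run)
  }
  unname(if (hi >= -lo) hi else lo)  # positive wins an exact tie
}
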