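# Pre-analysis processing: quantile normalisation, chip-batch adjustment,
# technical-replicate merging and PCA-based outlier screening.

#' Quantile normalisation across samples
#'
#' Forces every sample (column) to the same distribution: the across-column
#' mean of order statistics. Ties receive the mean of the implicated
#' order-statistic means (average-rank convention).
#'
#' @param m Probe x sample matrix, >= 2 samples.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2L) stop("quantile normalisation needs at least 2 samples")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Remove chip-batch effects
#'
#' Adjusts additive/multiplicative batch effects while protecting
#' treatment-associated differences (treatment is supplied as covariate).
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with `chip_batch` and `treatment`.
#' @param method `"combat"` (parametric empirical-Bayes location/scale
#'   adjustment via [sva::ComBat()]), `"simple"` (per-batch mean-centering of
#'   treatment-adjusted residuals; exactly preserves each probe's grand mean)
#'   or `"none"`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_batch <- function(m, meta, method = c("combat", "simple", "none")) {
  method <- match.arg(method)
  check_expression_matrix(m)
  validate_pairing(m, meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (any(is.na(meta$chip_batch) | !nzchar(meta$chip_batch))) {
    stop("every sample needs a chip_batch label")
  }
  if (method == "none") return(m)
  batch <- factor(meta$chip_batch)
  if (nlevels(batch) == 1L) return(m)  # single batch: nothing to adjust
  singletons <- names(which(table(batch) < 2L))
  if (length(singletons)) {
    stop("chip batch(es) with a single sample: ",
         paste(singletons, collapse = ", "),
         "; merge with a neighbouring batch or exclude the sample")
  }
  trt <- factor(meta$treatment)
  if (method == "combat") {
    mod <- if (nlevels(trt) > 1L) stats::model.matrix(~trt) else NULL
    out <- sva::ComBat(dat = m, batch = batch, mod = mod,
                       par.prior = TRUE, prior.plots = FALSE)
    dimnames(out) <- dimnames(m)
    return(out)
  }
  # simple: remove per-batch means from treatment-adjusted residuals
  design <- if (nlevels(trt) > 1L) stats::model.matrix(~trt) else
    matrix(1, ncol(m), 1L)
  fit <- t(stats::lm.fit(design, t(m))$fitted.values)
  resid <- m - fit
  for (b in levels(batch)) {
    idx <- which(batch == b)
    resid[, idx] <- resid[, idx] - rowMeans(resid[, idx, drop = FALSE])
  }
  out <- fit + resid
  dimnames(out) <- dimnames(m)
  out
}

#' Average technical replicates
#'
#' Collapses samples sharing a `replicate_group` to their arithmetic mean
#' column, isolating biological from technical variability. Members of a
#' group must agree on treatment.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with `replicate_group` defined for all samples.
#' @return List with `matrix` (one column per replicate group, named by the
#'   group) and `meta` (collapsed metadata).
#' @export
merge_technical_replicates <- function(m, meta) {
  check_expression_matrix(m)
  validate_pairing(m, meta)
  meta <- meta[match(colnames(m), meta$sample_id), ]
  if (any(is.na(meta$replicate_group) | !nzchar(meta$replicate_group))) {
    stop("replicate_group must be defined for all samples")
  }
  groups <- unique(meta$replicate_group)
  vals <- matrix(NA_real_, nrow(m), length(groups),
                 dimnames = list(rownames(m), groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- which(meta$replicate_group == groups[[i]])
    trts <- unique(meta$treatment[idx])
    if (length(trts) > 1L) {
      stop("replicate group '", groups[[i]], "' spans treatments: ",
           paste(trts, collapse = ", "))
    }
    vals[, i] <- rowMeans(m[, idx, drop = FALSE])
    rows[[i]] <- data.frame(
      sample_id = groups[[i]],
      treatment = trts,
      chip_batch = paste(unique(meta$chip_batch[idx]), collapse = ";"),
      product_batch = paste(unique(meta$product_batch[idx]), collapse = ";"),
      replicate_group = groups[[i]],
      stringsAsFactors = FALSE
    )
  }
  list(matrix = vals, meta = do.call(rbind, rows))
}

#' PCA outlier screen
#'
#' Projects samples onto the first two principal components of the
#' probe-centred data (no per-probe scaling) and flags samples whose
#' standardised distance from the sample centroid exceeds `k_sd`. Each PC
#' axis is centred on its median and scaled by the median absolute
#' deviation (consistent for the Gaussian sd): with the plain mean/sd an
#' extreme sample drags the centre and inflates its own scale, so a lone
#' outlier can never exceed sqrt(n) standardised units and the screen would
#' miss exactly what it exists for. Flagged samples are reported, never
#' removed.
#'
#' @param m Probe x sample matrix, >= 3 samples.
#' @param k_sd Flagging radius in (robust) standard-deviation units
#'   (default 4).
#' @return Data frame with `sample_id`, `pc1`, `pc2`, `dist_sd`, `outlier`.
#' @export
pca_outlier_check <- function(m, k_sd = 4) {
  check_expression_matrix(m)
  if (ncol(m) < 3L) stop("PCA outlier check needs at least 3 samples")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(scores) < 2L) scores <- cbind(scores, 0)
  centers <- apply(scores, 2L, stats::median)
  sds <- apply(scores, 2L, function(v) {
    s <- stats::mad(v)
    if (s == 0) stats::sd(v) else s
  })
  std <- sweep(sweep(scores, 2L, centers), 2L, ifelse(sds > 0, sds, 1), "/")
  std[, sds == 0] <- 0
  dist_sd <- sqrt(rowSums(std^2))
  data.frame(sample_id = colnames(m),
             pc1 = scores[, 1L], pc2 = scores[, 2L],
             dist_sd = dist_sd,
             outlier = dist_sd > k_sd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full pre-processing stage
#'
#' Optional log2 transform, quantile normalisation, batch adjustment and
#' (optionally) technical-replicate merging, with a PCA outlier report.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param log2_input See [read_expression_matrix()].
#' @param batch_method See [adjust_batch()].
#' @param merge_replicates Merge technical replicates (default `FALSE`; the
#'   variability analyses run unmerged except where noted).
#' @param k_sd PCA flagging radius.
#' @return List with `matrix`, `meta`, `pca` (outlier report).
#' @export
preprocess_study <- function(m, meta, log2_input = "no",
                             batch_method = "combat",
                             merge_replicates = FALSE, k_sd = 4) {
  validate_pairing(m, meta)
  m <- maybe_log2(m, log2_input)
  m <- quantile_normalize(m)
  m <- adjust_batch(m, meta, method = batch_method)
  if (merge_replicates) {
    merged <- merge_technical_replicates(m, meta)
    m <- merged$matrix
    meta <- merged$meta
  }
  list(matrix = m, meta = meta, pca = pca_outlier_check(m, k_sd = k_sd))
}
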