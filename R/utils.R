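#' @keywords internal
"_PACKAGE"

#' Recognised treatment levels
#'
#' The four study arms plus a catch-all for additional activators
#' (other glatiramoids, degraded drug, mannitol, ...).
#'
#' @return Character vector of the canonical treatment labels.
#' @export
treatment_levels <- function() {
  c("GA", "REFERENCE_STANDARD", "GENERIC", "MEDIUM", "OTHER")
}

# Map free-text treatment labels onto the canonical enum. Unknown labels
# become OTHER (callers decide whether to warn).
normalize_treatment <- function(x) {
  key <- gsub("[^a-z0-9]+", "_", tolower(trimws(as.character(x))))
  out <- rep("OTHER", length(x))
  out[key %in% c("ga", "copaxone", "branded")] <- "GA"
  out[key %in% c("reference_standard", "rs", "reference", "ga_reference_standard")] <- "REFERENCE_STANDARD"
  out[key %in% c("generic", "glatimer")] <- "GENERIC"
  out[key %in% c("medium", "vehicle", "untreated")] <- "MEDIUM"
  out
}

# Row variance with denominator n - 1, matching stats::var per row.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("row_vars() needs at least 2 columns")
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

# Sample columns belonging to a treatment group, in matrix column order.
group_samples <- function(meta, group) {
  meta$sample_id[meta$treatment %in% group]
}

# Subset matrix columns by treatment group with a clear error when absent.
group_matrix <- function(m, meta, group, min_n = 1L) {
  ids <- intersect(colnames(m), group_samples(meta, group))
  if (length(ids) < min_n) {
    stop("treatment group '", paste(group, collapse = ","), "' has ",
         length(ids), " sample(s); need at least ", min_n)
  }
  m[, ids, drop = FALSE]
}

#' Validate an expression matrix against its sample metadata
#'
#' Rejects any sample present in exactly one of the two objects, so every
#' downstream stage can assume a one-to-one pairing.
#'
#' @param m Numeric probe x sample matrix with probe row names and sample
#'   column names.
#' @param meta Data frame with at least a `sample_id` column (see
#'   [read_sample_sheet()]).
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_pairing <- function(m, meta) {
  stopifnot(is.matrix(m), is.data.frame(meta))
  only_m <- setdiff(colnames(m), meta$sample_id)
  only_s <- setdiff(meta$sample_id, colnames(m))
  if (length(only_m) || length(only_s)) {
    stop("matrix/metadata mismatch; only in matrix: [",
         paste(only_m, collapse = ", "), "]; only in sample sheet: [",
         paste(only_s, collapse = ", "), "]")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  invisible(TRUE)
}

check_expression_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry probe row names and sample column names")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated probe IDs: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample IDs: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (!all(is.finite(m))) stop("expression matrix contains non-finite values")
  invisible(TRUE)
}
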