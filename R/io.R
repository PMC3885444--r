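# Readers and writers for the external formats shared by all stages:
# tab-delimited expression matrices, sample sheets, GMT gene-set files and
# two-column orthology maps. All outputs are plain TSV with an optional
# header comment recording tool version and parameters.

#' Read a probe x sample expression matrix from TSV
#'
#' First column holds probe identifiers, header row holds sample identifiers.
#' Values must parse as finite numbers; duplicate identifiers are rejected.
#'
#' @param path Path to a tab-delimited file.
#' @param log2_input One of `"auto"`, `"yes"`, `"no"`. `"yes"` log2-transforms
#'   the values (flooring intensities at 1 so the transform stays finite);
#'   `"auto"` transforms if and only if the matrix maximum exceeds 50, the
#'   heuristic separating linear-scale intensities from already-logged data.
#' @return Numeric matrix with probe row names and sample column names, in
#'   file order.
#' @export
read_expression_matrix <- function(path, log2_input = c("no", "auto", "yes")) {
  log2_input <- match.arg(log2_input)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", colClasses = "character")
  if (ncol(df) < 2L) stop("expression matrix needs a probe column and >=1 sample column")
  probes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(probes)) {
    stop("duplicated probe IDs in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample IDs in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(probes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite value at probe '", probes[bad[1L, 1L]],
         "', sample '", samples[bad[1L, 2L]], "' in ", path)
  }
  m <- maybe_log2(vals, log2_input)
  check_expression_matrix(m)
  m
}

# Linear -> log2 handling shared by readers and the CLI. Intensities are
# floored at 1 before the transform so background-level signals map to 0.
maybe_log2 <- function(m, log2_input = c("no", "auto", "yes")) {
  log2_input <- match.arg(log2_input)
  do_it <- switch(log2_input, no = FALSE, yes = TRUE, auto = max(m) > 50)
  if (do_it) log2(pmax(m, 1)) else m
}

#' Write an expression matrix as TSV
#'
#' @param m Probe x sample matrix.
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines
#'   (tool version, parameters).
#' @export
write_expression_matrix <- function(m, path, comment = NULL) {
  check_expression_matrix(m)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  body <- cbind(rownames(m), format(m, trim = TRUE, digits = 15, scientific = FALSE))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns `sample_id`, `treatment`, `chip_batch`, `product_batch`
#' and `replicate_group`. Treatments are normalised onto the canonical enum
#' ([treatment_levels()]); unrecognised labels map to `OTHER` with a warning.
#'
#' @param path CSV or TSV file; the delimiter is taken from the extension
#'   (`.csv` means comma, anything else tab).
#' @return Data frame with the five columns, `treatment` enum-valued, plus
#'   `treatment_original` preserving the file's spelling.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#", colClasses = "character",
                          quote = "\"")
  required <- c("sample_id", "treatment", "chip_batch", "product_batch",
                "replicate_group")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("sample sheet ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  out <- df[required]
  out$treatment_original <- df$treatment
  out$treatment <- normalize_treatment(df$treatment)
  unknown <- unique(out$treatment_original[out$treatment == "OTHER"])
  if (length(unknown)) {
    warning("treatment label(s) mapped to OTHER: ", paste(unknown, collapse = ", "))
  }
  out
}

#' Write a sample sheet as TSV
#' @param meta Sample metadata data frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(meta, path) {
  cols <- c("sample_id", "treatment", "chip_batch", "product_batch", "replicate_group")
  utils::write.table(meta[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#'
#' @param path GMT file.
#' @param case One of `"upper"`, `"asis"`: symbol case normalisation policy
#'   applied to members (human and mouse symbol conventions differ in case;
#'   upper-casing makes set operations case-insensitive).
#' @return Named list of gene sets; each element is a character vector of
#'   members with a `description` attribute.
#' @export
read_gmt <- function(path, case = c("upper", "asis")) {
  case <- match.arg(case)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line ", i, " in ", path,
                             " (fewer than 3 fields)")
    members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (!length(members)) stop("empty gene set at GMT line ", i, " in ", path)
    if (case == "upper") members <- toupper(members)
    nms[i] <- f[[1L]]
    sets[[i]] <- structure(members, description = f[[2L]])
  }
  if (anyDuplicated(nms)) {
    stop("duplicated gene set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column orthology map
#'
#' @param path TSV with source symbols in column 1, target symbols in
#'   column 2; no header. Duplicate pairs are collapsed.
#' @return Data frame with columns `source`, `target`.
#' @export
read_orthology_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) stop("orthology map must have two tab-separated columns")
  out <- data.frame(source = trimws(df[[1L]]), target = trimws(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$source)) || any(!nzchar(out$target))) {
    stop("orthology map contains empty symbols")
  }
  unique(out)
}

#' Read a probe annotation table
#'
#' @param path TSV with header columns `probe_id` and `gene_symbol`.
#'   Many probes may map to one gene; unannotated probes may be absent.
#' @return Data frame with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          comment.char = "#")
  if (!all(c("probe_id", "gene_symbol") %in% colnames(df))) {
    stop("probe annotation needs columns probe_id, gene_symbol")
  }
  df[c("probe_id", "gene_symbol")]
}

#' Read a cell-type reference matrix
#'
#' @param path TSV: first column gene symbols, remaining columns mean log2
#'   expression per cell type.
#' @return Numeric gene x cell-type matrix.
#' @export
read_celltype_reference <- function(path) {
  m <- read_expression_matrix(path, log2_input = "no")
  if (ncol(m) < 2L) stop("cell-type reference needs at least 2 cell types")
  m
}

# Shared writer for result tables: TSV with '#' comment header.
write_result_table <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("glatcomp"))
  writeLines(paste0("# glatcomp ", version), con)
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
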