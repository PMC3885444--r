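# Condition-pattern identification: classify probes by which of the six
# pairwise comparisons among the four conditions (GA, generic, reference
# standard, medium) are significant and which are not.

# Fixed pair order used throughout; constraints and outputs follow it.
condition_pairs <- function() {
  rbind(c("GA", "GENERIC"),
        c("GA", "REFERENCE_STANDARD"),
        c("GA", "MEDIUM"),
        c("GENERIC", "REFERENCE_STANDARD"),
        c("GENERIC", "MEDIUM"),
        c("REFERENCE_STANDARD", "MEDIUM"))
}

pair_names <- function() {
  apply(condition_pairs(), 1L, paste, collapse = "-")
}

#' Pairwise condition p-values
#'
#' For every probe, the six two-group one-way ANOVA p-values between all
#' pairs of the four conditions (equivalent to pooled two-sided t-tests,
#' F = t^2). Column order is fixed: GA-GENERIC, GA-REFERENCE_STANDARD,
#' GA-MEDIUM, GENERIC-REFERENCE_STANDARD, GENERIC-MEDIUM,
#' REFERENCE_STANDARD-MEDIUM.
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata; all four conditions need >= 2 samples.
#' @return Numeric probe x 6 matrix of p-values.
#' @export
pairwise_condition_pvalues <- function(m, meta) {
  validate_pairing(m, meta)
  conds <- c("GA", "GENERIC", "REFERENCE_STANDARD", "MEDIUM")
  missing <- conds[!conds %in% meta$treatment]
  if (length(missing)) stop("missing condition(s): ", paste(missing, collapse = ", "))
  prs <- condition_pairs()
  out <- matrix(NA_real_, nrow(m), nrow(prs),
                dimnames = list(rownames(m), pair_names()))
  for (i in seq_len(nrow(prs))) {
    out[, i] <- anova_per_probe(m, meta, prs[i, ])$p
  }
  out
}

#' Construct a pattern template
#'
#' @param name Template name.
#' @param sig Pair names (see [pairwise_condition_pvalues()] column names)
#'   required significant (p < alpha).
#' @param ns Pair names required non-significant (p > alpha). Pairs in
#'   neither list are unconstrained.
#' @param direction Optional named list: affected condition -> `"up"` or
#'   `"down"` relative to MEDIUM group means.
#' @return Object of class `pattern_template`.
#' @export
pattern_template <- function(name, sig, ns, direction = NULL) {
  known <- pair_names()
  bad <- setdiff(c(sig, ns), known)
  if (length(bad)) stop("unknown pair name(s): ", paste(bad, collapse = ", "))
  if (length(intersect(sig, ns))) stop("a pair cannot be both SIG and NS")
  if (!length(c(sig, ns))) stop("template needs at least one constraint")
  structure(list(name = name, sig = sig, ns = ns, direction = direction),
            class = "pattern_template")
}

#' Built-in condition-pattern templates
#'
#' Four templates describing probes moved by exactly one product family:
#' \describe{
#'   \item{UP_ONLY_GENERIC / DOWN_ONLY_GENERIC}{all three generic-containing
#'     pairs significant, the remaining three non-significant; generic mean
#'     above / below the medium mean.}
#'   \item{UP_GA_AND_RS_ONLY / DOWN_GA_AND_RS_ONLY}{GA and reference
#'     standard each differ from generic and medium, while agreeing with
#'     each other and generic agrees with medium; GA and RS means above /
#'     below medium.}
#' }
#' Direction is enforced via group means versus MEDIUM even though the
#' significance mask alone is direction-blind.
#'
#' @return Named list of `pattern_template` objects.
#' @export
builtin_templates <- function() {
  gen_sig <- c("GA-GENERIC", "GENERIC-REFERENCE_STANDARD", "GENERIC-MEDIUM")
  gen_ns <- c("GA-REFERENCE_STANDARD", "GA-MEDIUM", "REFERENCE_STANDARD-MEDIUM")
  gars_sig <- c("GA-GENERIC", "GA-MEDIUM", "GENERIC-REFERENCE_STANDARD",
                "REFERENCE_STANDARD-MEDIUM")
  gars_ns <- c("GA-REFERENCE_STANDARD", "GENERIC-MEDIUM")
  list(
    UP_ONLY_GENERIC = pattern_template("UP_ONLY_GENERIC", gen_sig, gen_ns,
                                       direction = list(GENERIC = "up")),
    DOWN_ONLY_GENERIC = pattern_template("DOWN_ONLY_GENERIC", gen_sig, gen_ns,
                                         direction = list(GENERIC = "down")),
    UP_GA_AND_RS_ONLY = pattern_template(
      "UP_GA_AND_RS_ONLY", gars_sig, gars_ns,
      direction = list(GA = "up", REFERENCE_STANDARD = "up")),
    DOWN_GA_AND_RS_ONLY = pattern_template(
      "DOWN_GA_AND_RS_ONLY", gars_sig, gars_ns,
      direction = list(GA = "down", REFERENCE_STANDARD = "down"))
  )
}

#' Match probes against a pattern template
#'
#' A probe matches when every SIG pair has p < alpha, every NS pair has
#' p > alpha (p equal to alpha matches neither), and, if the template
#' carries direction predicates and `m`/`meta` are supplied, each affected
#' condition's mean sits on the required side of the MEDIUM mean.
#'
#' @param pvals Probe x 6 p-value matrix from [pairwise_condition_pvalues()].
#' @param template A `pattern_template`.
#' @param alpha Significance threshold in (0, 1).
#' @param m,meta Optional matrix/metadata for the direction check.
#' @param adjust Apply BH adjustment to each p-value column before matching
#'   (off by default; the pattern method uses raw pairwise p-values).
#' @return Character vector of matching probe IDs.
#' @export
match_pattern <- function(pvals, template, alpha = 0.05, m = NULL,
                          meta = NULL, adjust = FALSE) {
  stopifnot(inherits(template, "pattern_template"), alpha > 0, alpha < 1)
  if (adjust) pvals <- apply(pvals, 2L, bh_adjust)
  ok <- rep(TRUE, nrow(pvals))
  for (pr in template$sig) ok <- ok & (pvals[, pr] < alpha)
  for (pr in template$ns) ok <- ok & (pvals[, pr] > alpha)
  ids <- rownames(pvals)[ok]
  if (!is.null(template$direction) && !is.null(m) && !is.null(meta) &&
      length(ids)) {
    med_mean <- rowMeans(group_matrix(m[ids, , drop = FALSE], meta, "MEDIUM"))
    keep <- rep(TRUE, length(ids))
    for (cond in names(template$direction)) {
      cm <- rowMeans(group_matrix(m[ids, , drop = FALSE], meta, cond))
      keep <- keep & if (template$direction[[cond]] == "up")
        cm > med_mean else cm < med_mean
    }
    ids <- ids[keep]
  }
  ids
}

#' Run all built-in templates
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata with all four conditions.
#' @param alpha Significance threshold.
#' @param adjust See [match_pattern()].
#' @return Named list of probe-ID vectors, one per built-in template.
#' @export
identify_patterns <- function(m, meta, alpha = 0.05, adjust = FALSE) {
  pvals <- pairwise_condition_pvalues(m, meta)
  lapply(builtin_templates(), match_pattern, pvals = pvals, alpha = alpha,
         m = m, meta = meta, adjust = adjust)
}
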