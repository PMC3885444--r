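# Gene-set and cell-type enrichment: weighted Kolmogorov-Smirnov GSEA with
# a permutation null, hypergeometric over-representation with a minimum
# overlap rule, orthology mapping, and immune cell-type specificity
# scoring/enrichment against a reference compendium.

#' Map gene symbols through an orthology table
#'
#' @param genes Character vector of source symbols.
#' @param map Data frame from [read_orthology_map()] (`source`, `target`).
#' @param policy `"one_to_one"` drops entries whose source or target appears
#'   in more than one pair (ambiguous orthology); `"all"` keeps every
#'   target.
#' @return Character vector of mapped symbols (unique, input order), with
#'   attribute `unmapped` listing genes without an accepted mapping.
#' @export
map_orthologs <- function(genes, map, policy = c("one_to_one", "all")) {
  policy <- match.arg(policy)
  if (policy == "one_to_one") {
    keep <- !(map$source %in% map$source[duplicated(map$source)]) &
      !(map$target %in% map$target[duplicated(map$target)])
    map <- map[keep, , drop = FALSE]
  }
  hit <- map$source %in% genes
  mapped <- unique(map$target[hit][order(match(map$source[hit], genes))])
  structure(mapped, unmapped = setdiff(genes, map$source))
}

#' Gene-level signal-to-noise ranking
#'
#' Per-probe SNR scores between two classes (see [snr_test()] for the sd
#' floor), collapsed to gene level by the probe with the maximum absolute
#' score, sorted descending.
#'
#' @param m Probe x sample matrix.
#' @param annotation Data frame `probe_id`, `gene_symbol`.
#' @param classA,classB Sample IDs (>= 2 each).
#' @return Named numeric vector: gene symbol -> score, descending.
#' @export
rank_genes_snr <- function(m, annotation, classA, classB) {
  check_expression_matrix(m)
  idxA <- match(classA, colnames(m)); idxB <- match(classB, colnames(m))
  if (anyNA(idxA) || anyNA(idxB)) stop("class sample(s) not in matrix")
  if (length(idxA) < 2L || length(idxB) < 2L) stop("each class needs >= 2 samples")
  scores <- row_snr_scores(m, idxA, idxB)
  names(scores) <- rownames(m)
  ann <- annotation[annotation$probe_id %in% rownames(m) &
                      nzchar(annotation$gene_symbol), ]
  s <- scores[ann$probe_id]
  best <- tapply(s, ann$gene_symbol, function(v) v[which.max(abs(v))])
  out <- as.numeric(best)
  names(out) <- names(best)
  sort(out, decreasing = TRUE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: member genes ("hits") increment the running sum
#' by |score|^p normalised by the sum over hits; non-members decrement by
#' 1/(N - N_hit). ES is the signed maximum deviation from zero.
#'
#' @param ranked Named numeric vector of gene scores, sorted descending.
#' @param geneset Character vector of member symbols.
#' @param weight_p Score weight exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return List with `es` and `running` (length = length(ranked)).
#' @export
gsea_enrichment_score <- function(ranked, geneset, weight_p = 1) {
  genes <- names(ranked)
  hit <- genes %in% geneset
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no overlap with the ranked list")
  n <- length(ranked)
  w <- abs(ranked)^weight_p
  w_hit <- sum(w[hit])
  inc <- if (w_hit > 0) w * hit / w_hit else hit / n_hit
  dec <- if (n > n_hit) (!hit) / (n - n_hit) else rep(0, n)
  running <- unname(cumsum(inc - dec))
  hi <- max(running); lo <- min(running)
  es <- if (hi >= -lo) hi else lo  # equal-magnitude tie resolves positive
  list(es = es, running = running)
}

#' GSEA with a permutation null
#'
#' Computes the weighted-KS enrichment score per set, normalises against
#' same-sign permutation scores (NES), and derives nominal p-values and
#' FDR q-values the GSEA way (ratio of same-sign tail fractions of the
#' pooled permutation NES versus the observed NES, capped at 1).
#'
#' @param ranked Named numeric vector of gene scores, sorted descending.
#' @param genesets Named list of gene sets.
#' @param n_perm Permutations per set (default 1000; < 100 warns).
#' @param perm_type `"gene_set"` (random member sets of equal size drawn
#'   from the ranked universe; default, robust for small or unbalanced
#'   designs) or `"phenotype"` (requires `m`, `classA`, `classB`,
#'   `annotation`: class labels are permuted and the ranking recomputed).
#' @param seed Integer seed.
#' @param weight_p Score weight exponent.
#' @param m,annotation,classA,classB Needed for phenotype permutation only.
#' @return Data frame per set: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-separated genes up to/at the ES extremum).
#'   Sets without overlap are skipped with a warning.
#' @export
gsea <- function(ranked, genesets, n_perm = 1000,
                 perm_type = c("gene_set", "phenotype"), seed = 1,
                 weight_p = 1, m = NULL, annotation = NULL,
                 classA = NULL, classB = NULL) {
  perm_type <- match.arg(perm_type)
  if (n_perm < 100) warning("n_perm < 100 gives coarse permutation p-values")
  keep <- vapply(genesets, function(s) any(names(ranked) %in% s), logical(1L))
  if (any(!keep)) {
    warning("skipping set(s) with no overlap: ",
            paste(names(genesets)[!keep], collapse = ", "))
    genesets <- genesets[keep]
  }
  if (!length(genesets)) stop("no gene set overlaps the ranked list")
  obs <- lapply(genesets, function(s) gsea_enrichment_score(ranked, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1L), "es")
  sizes <- vapply(genesets, function(s) sum(names(ranked) %in% s), integer(1L))

  set.seed(seed)
  perm_es <- matrix(NA_real_, n_perm, length(genesets))
  if (perm_type == "gene_set") {
    universe <- names(ranked)
    for (b in seq_len(n_perm)) {
      for (j in seq_along(genesets)) {
        rnd <- sample(universe, sizes[[j]])
        perm_es[b, j] <- gsea_enrichment_score(ranked, rnd, weight_p)$es
      }
    }
  } else {
    if (is.null(m) || is.null(annotation) || is.null(classA) || is.null(classB)) {
      stop("phenotype permutation needs m, annotation, classA, classB")
    }
    pool <- c(classA, classB); nA <- length(classA)
    for (b in seq_len(n_perm)) {
      perm <- sample(pool)
      rk <- rank_genes_snr(m, annotation, perm[seq_len(nA)], perm[-seq_len(nA)])
      for (j in seq_along(genesets)) {
        perm_es[b, j] <- gsea_enrichment_score(rk, genesets[[j]], weight_p)$es
      }
    }
  }

  nes <- numeric(length(es)); pval <- numeric(length(es))
  nes_perm <- perm_es
  for (j in seq_along(es)) {
    same <- perm_es[, j][sign(perm_es[, j]) == sign(es[[j]])]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(perm_es[, j]))
    if (denom == 0) denom <- 1
    nes[[j]] <- es[[j]] / denom
    pval[[j]] <- if (length(same))
      (sum(abs(same) >= abs(es[[j]])) + 1) / (length(same) + 1) else
      1 / (n_perm + 1)
    # normalise each column's permutation scores sign-wise for the FDR pool
    pos <- perm_es[, j] > 0; neg <- perm_es[, j] < 0
    mp <- if (any(pos)) mean(perm_es[pos, j]) else 1
    mn <- if (any(neg)) mean(abs(perm_es[neg, j])) else 1
    nes_perm[pos, j] <- perm_es[pos, j] / mp
    nes_perm[neg, j] <- perm_es[neg, j] / mn
  }
  qval <- vapply(seq_along(es), function(j) {
    s <- sign(nes[[j]]); if (s == 0) return(1)
    pool <- nes_perm[sign(nes_perm) == s]
    obs_pool <- nes[sign(nes) == s]
    num <- if (length(pool)) mean(abs(pool) >= abs(nes[[j]])) else 0
    den <- mean(abs(obs_pool) >= abs(nes[[j]]))
    min(1, if (den > 0) num / den else 1)
  }, numeric(1L))

  le <- vapply(seq_along(genesets), function(j) {
    run <- obs[[j]]$running
    peak <- if (es[[j]] >= 0) which.max(run) else which.min(run)
    genes <- names(ranked)
    members <- genes %in% genesets[[j]]
    idx <- if (es[[j]] >= 0) seq_len(peak) else seq(peak, length(genes))
    paste(genes[idx][members[idx]], collapse = ",")
  }, character(1L))

  data.frame(set = names(genesets), size = unname(sizes), es = unname(es),
             nes = unname(nes), p = unname(pval), q = unname(qval),
             leading_edge = le, row.names = NULL, stringsAsFactors = FALSE)
}

#' Upper-tail hypergeometric enrichment test
#'
#' p = P(X >= k) for an overlap of k between a query of size n and a
#' reference set of size K drawn from a universe of size N.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param reference_set Character vector of reference genes.
#' @param universe Character vector defining the background.
#' @param min_overlap Minimum overlap for the row to be reported
#'   (default 3); smaller overlaps return `NULL` so collections can drop
#'   them before BH adjustment.
#' @return One-row data frame `overlap`, `overlap_genes`, `p`, `size_query`,
#'   `size_reference`, `size_universe`, or `NULL` when below `min_overlap`.
#' @export
hypergeometric_test <- function(query, reference_set, universe,
                                min_overlap = 3) {
  offenders <- setdiff(query, universe)
  if (length(offenders)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(offenders), collapse = ", "))
  }
  reference_set <- intersect(reference_set, universe)
  ov <- intersect(query, reference_set)
  k <- length(ov)
  if (k < min_overlap) return(NULL)
  N <- length(unique(universe)); K <- length(reference_set)
  n <- length(unique(query))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(overlap = k, overlap_genes = paste(sort(ov), collapse = ","),
             p = p, size_query = n, size_reference = K, size_universe = N,
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment over a gene-set collection
#'
#' Applies [hypergeometric_test()] per set, drops rows below the overlap
#' minimum before adjustment, then BH-adjusts across the surviving rows.
#'
#' @param query,universe As in [hypergeometric_test()].
#' @param collection Named list of gene sets.
#' @param min_overlap Minimum overlap (default 3).
#' @return Data frame, one row per surviving set, with a `q` column, sorted
#'   by p.
#' @export
hypergeometric_enrichment <- function(query, collection, universe,
                                      min_overlap = 3) {
  rows <- lapply(names(collection), function(nm) {
    r <- hypergeometric_test(query, collection[[nm]], universe, min_overlap)
    if (is.null(r)) return(NULL)
    cbind(set = nm, r, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(set = character(), overlap = integer(),
                      overlap_genes = character(), p = numeric(),
                      size_query = integer(), size_reference = integer(),
                      size_universe = integer(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Cell-type specificity scores
#'
#' Margin score: spec(g, c) = mean expression of gene g in cell type c minus
#' the maximum mean over all other cell types. Positive iff c is the
#' (strict) top cell type for g; at most one positive entry per gene.
#'
#' @param ref Gene x cell-type matrix of mean log2 expression (>= 2 types).
#' @return Matrix of the same shape.
#' @export
celltype_specificity_scores <- function(ref) {
  stopifnot(is.matrix(ref), ncol(ref) >= 2L)
  out <- ref
  for (j in seq_len(ncol(ref))) {
    other_max <- apply(ref[, -j, drop = FALSE], 1L, max)
    out[, j] <- ref[, j] - other_max
  }
  out
}

#' Cell-type enrichment of a gene list
#'
#' For each cell type, the reference set is the genes with specificity
#' score above `tau`; enrichment of the query is assessed with the
#' upper-tail hypergeometric test and BH-adjusted across cell types. The
#' summed specificity of the query genes is reported as a descriptive
#' column, with an optional permutation test on that sum for users wanting
#' the score-based reading (`n_sum_perm > 0`).
#'
#' @param query Character vector of gene symbols (within `universe`).
#' @param spec Specificity matrix from [celltype_specificity_scores()].
#' @param tau Specificity threshold in log2 units (default 1.0).
#' @param universe Background genes (default: rownames of `spec`).
#' @param min_overlap Minimum overlap (default 1 here; cell-type panels are
#'   small).
#' @param n_sum_perm Optional permutation count for the summed-score test.
#' @param seed Seed for the permutation test.
#' @return Data frame per cell type: `cell_type`, `n_specific`, `overlap`,
#'   `summed_spec`, `p`, `q` (and `sum_p` if requested), sorted by p. Cell
#'   types with an empty reference set are skipped with a note attribute.
#' @export
celltype_enrichment <- function(query, spec, tau = 1.0,
                                universe = rownames(spec), min_overlap = 1,
                                n_sum_perm = 0, seed = 1) {
  stopifnot(tau >= 0)
  offenders <- setdiff(query, universe)
  if (length(offenders)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(offenders), collapse = ", "))
  }
  skipped <- character()
  rows <- lapply(colnames(spec), function(ct) {
    ref_set <- rownames(spec)[spec[, ct] > tau]
    ref_set <- intersect(ref_set, universe)
    if (!length(ref_set)) {
      skipped <<- c(skipped, ct)
      return(NULL)
    }
    ov <- intersect(query, ref_set)
    N <- length(unique(universe)); K <- length(ref_set); n <- length(unique(query))
    k <- length(ov)
    if (k < min_overlap) return(NULL)
    qin <- intersect(query, rownames(spec))
    data.frame(cell_type = ct, n_specific = K, overlap = k,
               summed_spec = sum(spec[qin, ct]),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(), n_specific = integer(),
               overlap = integer(), summed_spec = numeric(), p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(out)) out$q <- bh_adjust(out$p) else out$q <- numeric()
  if (n_sum_perm > 0 && nrow(out)) {
    set.seed(seed)
    qin_n <- length(intersect(query, rownames(spec)))
    sum_p <- vapply(out$cell_type, function(ct) {
      perms <- vapply(seq_len(n_sum_perm), function(b) {
        sum(spec[sample(rownames(spec), qin_n), ct])
      }, numeric(1L))
      obs <- out$summed_spec[out$cell_type == ct][[1L]]
      (sum(perms >= obs) + 1) / (n_sum_perm + 1)
    }, numeric(1L))
    out$sum_p <- unname(sum_p)
  }
  out <- out[order(out$p, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
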