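# Orchestration: run every stage on a study, write TSV tables, basic plots
# and a run manifest with content hashes.

open_plot_device <- function(path_base) {
  # cairo png when available, pdf otherwise; returns the file written
  if (capabilities("png")) {
    path <- paste0(path_base, ".png")
    grDevices::png(path, width = 900, height = 700, res = 110,
                   type = if (capabilities("cairo")) "cairo" else NULL)
  } else {
    path <- paste0(path_base, ".pdf")
    grDevices::pdf(path, width = 8, height = 6)
  }
  path
}

#' Run the full comparability analysis
#'
#' Executes preprocessing, the variability suite (activation filter,
#' directional F-test counts, tolerance method, variance-ratio ranking,
#' CV analysis, subsampling sensitivity), the differential-expression
#' consensus, condition-pattern identification and (when gene sets /
#' cell-type reference are supplied) enrichment, writing all tables, plots
#' and a manifest under `out_dir`.
#'
#' @param m Probe x sample matrix (raw or log2; see `log2_input`).
#' @param meta Sample metadata.
#' @param out_dir Output directory (created if needed).
#' @param annotation Optional probe annotation (probe_id, gene_symbol);
#'   required for enrichment stages.
#' @param genesets Optional named list of gene sets (GSEA + hypergeometric).
#' @param celltype_ref Optional gene x cell-type reference matrix.
#' @param log2_input,batch_method,merge_replicates Passed to
#'   [preprocess_study()].
#' @param n_top,expr_floor,tolerance_threshold Tolerance-method parameters.
#' @param alpha Significance level used throughout.
#' @param n_perm Permutation count (SNR, GSEA).
#' @param subset_size,n_repeats Sensitivity-analysis parameters.
#' @param seed Integer seed for all randomised stages.
#' @param skip Character vector of stage names to skip (any of
#'   `"variability"`, `"differential"`, `"patterns"`, `"enrichment"`).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_comparison <- function(m, meta, out_dir, annotation = NULL,
                                genesets = NULL, celltype_ref = NULL,
                                log2_input = "no", batch_method = "combat",
                                merge_replicates = FALSE,
                                n_top = 1000, expr_floor = 6.0,
                                tolerance_threshold = 75, alpha = 0.05,
                                n_perm = 1000, subset_size = 11,
                                n_repeats = 10, seed = 1, skip = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  params <- list(log2_input = log2_input, batch_method = batch_method,
                 merge_replicates = merge_replicates, n_top = n_top,
                 expr_floor = expr_floor,
                 tolerance_threshold = tolerance_threshold, alpha = alpha,
                 n_perm = n_perm, subset_size = subset_size,
                 n_repeats = n_repeats, seed = seed, skip = skip)

  message("[prep] normalising and adjusting ", ncol(m), " samples")
  prep <- preprocess_study(m, meta, log2_input = log2_input,
                           batch_method = batch_method,
                           merge_replicates = merge_replicates)
  m <- prep$matrix; meta <- prep$meta
  results$prep <- prep
  write_expression_matrix(m, file.path(out_dir, "expression_processed.tsv"))
  write_result_table(prep$pca, file.path(out_dir, "pca_outliers.tsv"))

  if (!"variability" %in% skip) {
    message("[variability] F-test filter, tolerance, variance ratios, CV")
    probes <- activation_variable_probes(m, meta, alpha = alpha)
    cmp <- if (length(probes))
      compare_group_variability(m, meta, probes, alpha = alpha) else
      list(n_generic_more_variable = 0L, n_ga_more_variable = 0L, fold = NA)
    tol_probes <- select_tolerance_probes(m, meta, n_top = n_top,
                                          expr_floor = expr_floor)
    ranges <- tolerance_ranges(m, meta, tol_probes)
    tol_ga <- tolerance_percentages(m, meta, ranges, "GA")
    tol_gen <- tolerance_percentages(m, meta, ranges, "GENERIC")
    vr <- variance_ratio_ranking(m, meta)
    merged <- merge_technical_replicates(m, meta)
    cv_ga <- coefficient_of_variation(merged$matrix, merged$meta, "GA")
    cv_gen <- coefficient_of_variation(merged$matrix, merged$meta, "GENERIC")
    sens <- subsample_sensitivity(m, meta, subset_size = subset_size,
                                  n_repeats = n_repeats, seed = seed,
                                  alpha = alpha)
    results$variability <- list(
      activation_probes = probes, comparison = cmp,
      tolerance = list(ga = tol_ga, generic = tol_gen,
                       failing_ga = count_failing(tol_ga, tolerance_threshold),
                       failing_generic = count_failing(tol_gen, tolerance_threshold)),
      variance_ratio = vr, cv = list(ga = cv_ga, generic = cv_gen),
      sensitivity = sens)
    write_result_table(data.frame(probe_id = probes),
                       file.path(out_dir, "activation_variable_probes.tsv"))
    write_result_table(tol_ga$table, file.path(out_dir, "tolerance_ga.tsv"))
    write_result_table(tol_gen$table, file.path(out_dir, "tolerance_generic.tsv"))
    write_result_table(vr, file.path(out_dir, "variance_ratio.tsv"))
    write_result_table(sens$repeats, file.path(out_dir, "sensitivity_repeats.tsv"))
    p1 <- open_plot_device(file.path(out_dir, "tolerance_curves"))
    plot_tolerance_curves(tol_ga, tol_gen)
    grDevices::dev.off()
    p2 <- open_plot_device(file.path(out_dir, "cv_vs_intensity"))
    plot_cv_intensity(cv_ga, cv_gen)
    grDevices::dev.off()
  }

  if (!"differential" %in% skip) {
    message("[differential] five-test table and consensus")
    dt <- differential_table(m, meta, alpha = alpha, n_perm = n_perm,
                             seed = seed)
    results$differential <- dt
    write_result_table(dt, file.path(out_dir, "differential.tsv"))
  }

  if (!"patterns" %in% skip) {
    message("[patterns] pairwise condition patterns")
    pats <- identify_patterns(m, meta, alpha = alpha)
    results$patterns <- pats
    pat_df <- data.frame(
      template = rep(names(pats), vapply(pats, length, 1L)),
      probe_id = unlist(pats, use.names = FALSE))
    write_result_table(pat_df, file.path(out_dir, "patterns.tsv"))
  }

  if (!"enrichment" %in% skip && !is.null(annotation)) {
    message("[enrichment] GSEA / hypergeometric / cell types")
    enr <- list()
    ga_ids <- intersect(colnames(m), group_samples(meta, "GA"))
    med_ids <- intersect(colnames(m), group_samples(meta, "MEDIUM"))
    if (!is.null(genesets) && length(ga_ids) >= 2 && length(med_ids) >= 2) {
      ranked <- rank_genes_snr(m, annotation, ga_ids, med_ids)
      enr$gsea <- gsea(ranked, genesets, n_perm = n_perm, seed = seed)
      write_result_table(enr$gsea, file.path(out_dir, "gsea_ga_vs_medium.tsv"))
    }
    if (!is.null(results$differential) && !is.null(genesets)) {
      universe <- unique(annotation$gene_symbol)
      cons <- consensus_significant(results$differential, alpha = alpha)
      query <- unique(annotation$gene_symbol[
        annotation$probe_id %in% cons$wilcoxon_higher_ga])
      if (length(query) >= 3) {
        enr$msigdb_like <- hypergeometric_enrichment(query, genesets, universe)
        write_result_table(enr$msigdb_like,
                           file.path(out_dir, "hypergeometric_wilcoxon_ga.tsv"))
      }
    }
    if (!is.null(celltype_ref) && !is.null(results$differential)) {
      spec <- celltype_specificity_scores(celltype_ref)
      cons <- consensus_significant(results$differential, alpha = alpha)
      for (side in c("probes_higher_ga", "probes_higher_generic")) {
        query <- unique(annotation$gene_symbol[
          annotation$probe_id %in% cons[[side]]])
        query <- intersect(query, rownames(spec))
        if (length(query)) {
          ct <- celltype_enrichment(query, spec)
          enr[[paste0("celltype_", side)]] <- ct
          write_result_table(ct, file.path(out_dir, paste0("celltype_", side, ".tsv")))
        }
      }
    }
    results$enrichment <- enr
  }

  # manifest: parameters + content hash of every output file
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.yaml"))
  manifest <- list(
    package = "glatcomp",
    version = as.character(utils::packageVersion("glatcomp")),
    parameters = params,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  results$manifest <- manifest
  invisible(results)
}

#' Tolerance-curve plot
#'
#' Ascending per-probe within-tolerance percentages for GA and generic
#' against probe index; the flatter and higher the curve, the more
#' consistent the product.
#'
#' @param tol_ga,tol_generic `tolerance_result` objects.
#' @export
plot_tolerance_curves <- function(tol_ga, tol_generic) {
  n <- length(tol_ga$curve)
  graphics::plot(seq_len(n), tol_ga$curve, type = "l", col = "firebrick",
                 lwd = 2, ylim = c(0, 100), xlab = "probe (sorted)",
                 ylab = "% samples within tolerance",
                 main = "Tolerance curves")
  graphics::lines(seq_along(tol_generic$curve), tol_generic$curve,
                  col = "black", lwd = 2)
  graphics::legend("bottomright", legend = c("GA", "generic"),
                   col = c("firebrick", "black"), lwd = 2, bty = "n")
}

#' CV versus intensity plot
#' @param cv_ga,cv_generic Outputs of [coefficient_of_variation()].
#' @export
plot_cv_intensity <- function(cv_ga, cv_generic) {
  graphics::plot(cv_generic$mean_log2, cv_generic$cv, pch = ".",
                 col = "black", xlab = "mean log2 intensity", ylab = "CV",
                 main = "Coefficient of variation vs intensity")
  graphics::points(cv_ga$mean_log2, cv_ga$cv, pch = ".", col = "firebrick")
  graphics::legend("topright", legend = c("GA", "generic"),
                   col = c("firebrick", "black"), pch = 15, bty = "n")
}

#' Per-gene panels: boxplots, kernel densities, scatter pairs
#'
#' @param m Probe x sample matrix.
#' @param meta Sample metadata.
#' @param annotation Probe annotation.
#' @param genes Gene symbols to plot (error if absent from the annotation).
#' @param kinds Any of `"box"`, `"density"`, `"scatter_pair"`
#'   (`scatter_pair` uses the first two genes and draws the
#'   reference-standard tolerance rectangle).
#' @param ranges Optional [tolerance_ranges()] output for the rectangle.
#' @return Invisibly, the probe IDs plotted per gene.
#' @export
plot_gene_panels <- function(m, meta, annotation, genes,
                             kinds = c("box", "density"), ranges = NULL) {
  missing <- setdiff(genes, annotation$gene_symbol)
  if (length(missing)) {
    stop("gene(s) not in annotation: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(m), meta$sample_id), ]
  trt <- factor(meta$treatment, levels = treatment_levels())
  probe_of <- vapply(genes, function(g) {
    annotation$probe_id[annotation$gene_symbol == g][[1L]]
  }, character(1L))
  for (g in genes) {
    x <- m[probe_of[[g]], ]
    if ("box" %in% kinds) {
      graphics::boxplot(x ~ droplevels(trt), main = g, xlab = "",
                        ylab = "log2 expression")
    }
    if ("density" %in% kinds) {
      first <- TRUE
      cols <- c(GA = "firebrick", REFERENCE_STANDARD = "orange",
                GENERIC = "black", MEDIUM = "grey50", OTHER = "blue")
      for (lev in levels(droplevels(trt))) {
        v <- x[trt == lev]
        if (length(v) < 2) next
        bw <- max(stats::bw.nrd0(v), 1e-3)  # bandwidth floor for constants
        d <- stats::density(v, bw = bw)
        if (first) {
          graphics::plot(d, main = paste(g, "kernel density"),
                         col = cols[[lev]], xlab = "log2 expression")
          first <- FALSE
        } else graphics::lines(d, col = cols[[lev]])
      }
    }
  }
  if ("scatter_pair" %in% kinds) {
    if (length(genes) < 2) stop("scatter_pair needs two genes")
    g1 <- probe_of[[1L]]; g2 <- probe_of[[2L]]
    cols <- ifelse(trt == "GA", "firebrick",
                   ifelse(trt == "GENERIC", "black", "grey70"))
    graphics::plot(m[g1, ], m[g2, ], col = cols, pch = 16,
                   xlab = genes[[1L]], ylab = genes[[2L]],
                   main = paste(genes[[1L]], "vs", genes[[2L]]))
    if (!is.null(ranges)) {
      r1 <- ranges[ranges$probe_id == g1, ]
      r2 <- ranges[ranges$probe_id == g2, ]
      if (nrow(r1) && nrow(r2)) {
        graphics::rect(r1$range_low, r2$range_low, r1$range_high,
                       r2$range_high, border = "red", lwd = 2)
      }
    }
  }
  invisible(probe_of)
}
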