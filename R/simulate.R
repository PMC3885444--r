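# Seeded generator of synthetic comparability studies with the statistical
# structure the pipeline assumes: four treatment arms with the study's
# sample counts, chip-batch effects, shared activation effects for the
# branded arms, a variance-inflated probe subset for the generic arm,
# product-specific shift sets, and planted cell-type signatures/gene sets.
# Ground truth is emitted for recovery tests.

#' Simulation configuration
#'
#' Defaults mirror the study design: 22 reference-standard, 34 GA, 11
#' generic and 8 medium samples over 18 chip batches, with 30 GA and 5
#' generic product batches. Expression is Gaussian on the log2 scale:
#' baseline + chip-batch effect + treatment effects + noise. Activation
#' effects (mean shift plus extra per-sample variability) are shared by the
#' GA, reference-standard and generic arms; the generic arm's noise sd is
#' multiplied by `var_inflation` on `n_inflated` planted probes; the
#' generic-only and GA-and-RS-only sets receive their own mean shifts.
#'
#' @param n_probes Probe count (default 10000).
#' @param n_rs,n_ga,n_generic,n_medium Group sizes (defaults 22/34/11/8).
#' @param n_chip_batches Chip batches (default 18).
#' @param n_ga_batches,n_generic_batches Product batches (defaults 30/5).
#' @param batch_sd Chip-batch effect sd, log2 units (default 0.3).
#' @param baseline_mean,baseline_sd Per-probe baseline distribution
#'   (defaults 7 / 1.5 log2 units, Illumina-like).
#' @param noise_sd Residual sd, log2 units (default 0.5).
#' @param noise_df Residual distribution df; `Inf` = Gaussian (default),
#'   finite values give scaled t noise for robustness experiments.
#' @param activation_fraction,activation_effect Fraction of probes shifted
#'   by activation and the shift size (defaults 0.05, 1.0; random sign).
#' @param activation_var_sd Extra per-sample sd on activation probes in the
#'   activated arms (default 0.3), the "activation-induced variability"
#'   that the F-test filter targets.
#' @param var_inflation Generic-arm noise-sd multiplier gamma on inflated
#'   probes (default 2, i.e. a 4-fold variance ratio).
#' @param n_inflated Number of variance-inflated probes (default 100).
#' @param n_generic_only_up,n_generic_only_down,generic_only_effect
#'   Generic-only shift sets and effect size (defaults 50/50, 1.0 = two
#'   noise sd).
#' @param n_ga_rs_only_up,n_ga_rs_only_down,ga_rs_only_effect Same for the
#'   GA-and-reference-standard-only sets.
#' @param tech_replicates Technical replicates per biological sample
#'   (default 1), with `tech_sd` extra technical noise when > 1.
#' @param tech_sd Technical noise sd (default 0.2).
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 10000, n_rs = 22, n_ga = 34,
                              n_generic = 11, n_medium = 8,
                              n_chip_batches = 18, n_ga_batches = 30,
                              n_generic_batches = 5, batch_sd = 0.3,
                              baseline_mean = 7, baseline_sd = 1.5,
                              noise_sd = 0.5, noise_df = Inf,
                              activation_fraction = 0.05,
                              activation_effect = 1.0,
                              activation_var_sd = 0.3,
                              var_inflation = 2, n_inflated = 100,
                              n_generic_only_up = 50,
                              n_generic_only_down = 50,
                              generic_only_effect = 1.0,
                              n_ga_rs_only_up = 50, n_ga_rs_only_down = 50,
                              ga_rs_only_effect = 1.0,
                              tech_replicates = 1, tech_sd = 0.2,
                              seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_probes, cfg$n_rs, cfg$n_ga, cfg$n_generic, cfg$n_medium,
              cfg$n_chip_batches, cfg$tech_replicates)
  if (any(counts < 1)) stop("all counts must be positive")
  if (cfg$var_inflation < 1) stop("var_inflation must be >= 1")
  if (cfg$activation_fraction < 0 || cfg$activation_fraction > 1) {
    stop("activation_fraction must lie in [0, 1]")
  }
  n_planted <- round(cfg$activation_fraction * cfg$n_probes) + cfg$n_inflated +
    cfg$n_generic_only_up + cfg$n_generic_only_down +
    cfg$n_ga_rs_only_up + cfg$n_ga_rs_only_down
  if (n_planted > cfg$n_probes) {
    stop("planted categories (", n_planted, " probes) exceed n_probes")
  }
  structure(cfg, class = "simulation_config")
}

rnoise <- function(n, sd, df) {
  if (is.infinite(df)) stats::rnorm(n, 0, sd) else
    sd * stats::rt(n, df) / sqrt(df / (df - 2))
}

#' Simulate a full synthetic comparability study
#'
#' @param cfg A [simulation_config()].
#' @return List with `matrix` (probe x sample log2 expression), `meta`
#'   (sample metadata), `annotation` (probe -> gene, one gene per probe),
#'   `truth` (planted probe sets by category plus the configured effects)
#'   and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  probes <- sprintf("P%05d", seq_len(cfg$n_probes))
  genes <- sprintf("G%05d", seq_len(cfg$n_probes))

  # disjoint planted categories
  n_act <- round(cfg$activation_fraction * cfg$n_probes)
  shuffled <- sample(cfg$n_probes)
  take <- function(n) {
    if (n == 0L) return(integer())
    out <- shuffled[seq_len(n)]
    shuffled <<- shuffled[-seq_len(n)]
    out
  }
  idx <- list(activation = take(n_act), inflated = take(cfg$n_inflated),
              generic_only_up = take(cfg$n_generic_only_up),
              generic_only_down = take(cfg$n_generic_only_down),
              ga_rs_only_up = take(cfg$n_ga_rs_only_up),
              ga_rs_only_down = take(cfg$n_ga_rs_only_down))

  arms <- c(rep("REFERENCE_STANDARD", cfg$n_rs), rep("GA", cfg$n_ga),
            rep("GENERIC", cfg$n_generic), rep("MEDIUM", cfg$n_medium))
  n_bio <- length(arms)
  bio_id <- sprintf("S%03d", seq_len(n_bio))
  product_batch <- c(rep("RS_STD", cfg$n_rs),
                     sprintf("GA_B%02d", rep_len(seq_len(cfg$n_ga_batches), cfg$n_ga)),
                     sprintf("GEN_B%02d", rep_len(seq_len(cfg$n_generic_batches), cfg$n_generic)),
                     rep("NONE", cfg$n_medium))

  baseline <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
  act_sign <- sample(c(-1, 1), n_act, replace = TRUE)
  effect <- matrix(0, cfg$n_probes, n_bio)
  activated <- arms != "MEDIUM"
  effect[idx$activation, activated] <- cfg$activation_effect * act_sign
  effect[idx$generic_only_up, arms == "GENERIC"] <- cfg$generic_only_effect
  effect[idx$generic_only_down, arms == "GENERIC"] <- -cfg$generic_only_effect
  gars <- arms %in% c("GA", "REFERENCE_STANDARD")
  effect[idx$ga_rs_only_up, gars] <- cfg$ga_rs_only_effect
  effect[idx$ga_rs_only_down, gars] <- -cfg$ga_rs_only_effect

  # per-sample noise, with generic-arm inflation on the planted subset and
  # activation-induced variability on activation probes in activated arms
  sd_mat <- matrix(cfg$noise_sd, cfg$n_probes, n_bio)
  sd_mat[idx$inflated, arms == "GENERIC"] <-
    cfg$noise_sd * cfg$var_inflation
  if (n_act && cfg$activation_var_sd > 0) {
    sd_mat[idx$activation, activated] <-
      sqrt(sd_mat[idx$activation, activated]^2 + cfg$activation_var_sd^2)
  }
  noise <- matrix(rnoise(cfg$n_probes * n_bio, 1, cfg$noise_df),
                  cfg$n_probes, n_bio) * sd_mat

  # chip-batch structure: samples randomised across chips
  chip <- sprintf("CHIP%02d", rep_len(seq_len(cfg$n_chip_batches),
                                      n_bio))[sample(n_bio)]
  batch_eff <- matrix(stats::rnorm(cfg$n_probes * cfg$n_chip_batches, 0,
                                   cfg$batch_sd),
                      cfg$n_probes, cfg$n_chip_batches,
                      dimnames = list(NULL, sprintf("CHIP%02d", seq_len(cfg$n_chip_batches))))

  bio <- baseline + effect + noise + batch_eff[, chip]

  if (cfg$tech_replicates > 1L) {
    reps <- rep(seq_len(n_bio), each = cfg$tech_replicates)
    vals <- bio[, reps] + matrix(stats::rnorm(cfg$n_probes * length(reps), 0,
                                              cfg$tech_sd),
                                 cfg$n_probes, length(reps))
    sample_id <- sprintf("%s_r%d", bio_id[reps],
                         rep(seq_len(cfg$tech_replicates), times = n_bio))
    meta <- data.frame(sample_id = sample_id, treatment = arms[reps],
                       chip_batch = chip[reps],
                       product_batch = product_batch[reps],
                       replicate_group = bio_id[reps],
                       stringsAsFactors = FALSE)
  } else {
    vals <- bio
    sample_id <- bio_id
    meta <- data.frame(sample_id = bio_id, treatment = arms,
                       chip_batch = chip, product_batch = product_batch,
                       replicate_group = bio_id, stringsAsFactors = FALSE)
  }
  dimnames(vals) <- list(probes, sample_id)

  truth <- list(
    probe_sets = lapply(idx, function(i) probes[sort(i)]),
    gene_sets = lapply(idx, function(i) genes[sort(i)]),
    activation_signs = stats::setNames(act_sign, probes[idx$activation]),
    effects = list(activation = cfg$activation_effect,
                   generic_only = cfg$generic_only_effect,
                   ga_rs_only = cfg$ga_rs_only_effect,
                   var_inflation = cfg$var_inflation)
  )
  list(matrix = vals,
       meta = meta,
       annotation = data.frame(probe_id = probes, gene_symbol = genes,
                               stringsAsFactors = FALSE),
       truth = truth,
       config = cfg)
}

#' Simulate a cell-type reference compendium
#'
#' Disjoint cell-type signatures on a flat background: a signature gene's
#' mean expression in its own cell type exceeds every other cell type by
#' approximately `margin` log2 units (Gaussian noise `noise_sd` on every
#' entry).
#'
#' @param n_genes Total genes (ignored if `genes` given).
#' @param n_celltypes Number of cell types (>= 2).
#' @param signature_size Genes per signature (used for cell types without
#'   an explicit entry in `signatures`).
#' @param margin Expression margin of signature genes, log2 units.
#' @param seed Integer seed.
#' @param noise_sd Entry-level noise sd (default 0.3).
#' @param genes Optional explicit gene universe.
#' @param signatures Optional named list: cell type -> signature genes
#'   (must be disjoint; remaining cell types receive random disjoint
#'   signatures from the leftover genes).
#' @return List with `reference` (gene x cell-type matrix) and `truth`
#'   (named list of signature gene vectors).
#' @export
simulate_celltype_reference <- function(n_genes = 5000, n_celltypes = 20,
                                        signature_size = 10, margin = 3,
                                        seed = 1, noise_sd = 0.3,
                                        genes = NULL, signatures = NULL) {
  if (n_celltypes < 2L) stop("need >= 2 cell types")
  set.seed(seed)
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  n_genes <- length(genes)
  cts <- sprintf("CT%02d", seq_len(n_celltypes))
  if (!is.null(signatures)) {
    if (any(!names(signatures) %in% cts)) {
      cts <- unique(c(names(signatures), cts))[seq_len(max(n_celltypes, length(signatures)))]
    }
    all_sig <- unlist(signatures)
    if (anyDuplicated(all_sig)) stop("requested signatures overlap")
    if (any(!all_sig %in% genes)) stop("signature gene(s) outside the universe")
  }
  sig <- if (is.null(signatures)) list() else signatures
  free <- setdiff(genes, unlist(sig))
  todo <- setdiff(cts, names(sig))
  if (length(todo) * signature_size > length(free)) {
    stop("signature_size x n_celltypes exceeds available genes")
  }
  for (ct in todo) {
    if (signature_size > 0) {
      pick <- sample(free, signature_size)
      free <- setdiff(free, pick)
      sig[[ct]] <- pick
    } else sig[[ct]] <- character()
  }
  ref <- matrix(stats::rnorm(n_genes * length(cts), 5, noise_sd),
                n_genes, length(cts), dimnames = list(genes, cts))
  for (ct in names(sig)) {
    if (length(sig[[ct]])) ref[sig[[ct]], ct] <- ref[sig[[ct]], ct] + margin
  }
  list(reference = ref, truth = sig[cts[cts %in% names(sig)]])
}

#' Simulate gene-set collections with planted and decoy sets
#'
#' One set per planted category in the study truth, plus random decoy sets
#' drawn from genes outside every planted category.
#'
#' @param truth `truth` element of [simulate_study()] output.
#' @param universe Gene universe to draw decoys from (e.g. the study
#'   annotation's `gene_symbol` column).
#' @param n_decoy_sets Number of decoys (default 10).
#' @param set_size Decoy size (default 20).
#' @param seed Integer seed.
#' @return Named list of gene sets (GMT-compatible; see [write_gmt()]).
#' @export
simulate_gene_sets <- function(truth, universe, n_decoy_sets = 10,
                               set_size = 20, seed = 1) {
  set.seed(seed)
  planted <- truth$gene_sets[vapply(truth$gene_sets, length, 1L) > 0]
  names(planted) <- paste0("planted_", names(planted))
  free <- setdiff(universe, unlist(truth$gene_sets))
  decoys <- lapply(seq_len(n_decoy_sets), function(i) sample(free, set_size))
  names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoy_sets))
  c(planted, decoys)
}
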