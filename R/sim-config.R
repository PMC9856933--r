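#' Configuration for the synthetic cohort generators
#'
#' Bundles every tunable of the synthetic-data module in one validated
#' object. Defaults encode the study conditions the generators emulate: two
#' expression subtypes of unequal size ("h" homogeneous, "o" other) with
#' larger within-group variance in "o", a cross-platform microarray pair
#' with per-gene additive shifts, negative-binomial mature-miRNA counts with
#' anti-correlated target genes, band-structured copy-number segments on a
#' toy two-chromosome genome, and trinucleotide-context mutations drawn from
#' a mixture of catalog signatures.
#'
#' @param seed integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_genes number of genes in expression cohorts.
#' @param n_samples_per_group named count vector \code{c(h=, o=)}.
#' @param de_fraction fraction of genes differentially expressed between the
#'   groups, in (0, 1).
#' @param effect_size absolute between-group shift for DE genes (log2 units).
#' @param variance_ratio_o_vs_h ratio (>= 1) of per-gene noise variance in
#'   group "o" relative to group "h".
#' @param noise_sd per-gene residual standard deviation in group "h" (log2).
#' @param platform_shift_sd standard deviation of the per-gene additive
#'   platform shift in the dual-platform generator (log2 units).
#' @param tech_sd technical replicate noise added independently on each
#'   platform (log2 units).
#' @param concordant_fraction fraction of genes measured concordantly on
#'   both platforms; the complement is scrambled (independent values).
#' @param n_shared_samples samples hybridized on both platforms.
#' @param n_modules,module_size,module_loading number, size and latent
#'   factor loading of implanted co-expression blocks.
#' @param hazard_ratio group-"h" vs group-"o" hazard ratio of the simulated
#'   survival endpoint (months).
#' @param clinical_probs named list of per-group probabilities for the
#'   categorical clinical fields (reference-level probability in h and o).
#' @param n_mirnas number of mature miRNAs.
#' @param n_de_mirnas mature miRNAs given a true group fold-change.
#' @param mirna_log2fc absolute group log2 fold-change of DE miRNAs (> 1).
#' @param n_true_interactions,n_decoy_interactions true and decoy
#'   miRNA-target pairs placed in the interaction database.
#' @param interaction_pcc target Pearson correlation of true pairs, in
#'   [-1, 0).
#' @param mirna_dispersion negative-binomial size parameter of counts.
#' @param n_genes_per_band genes placed in each cytoband of the toy genome.
#' @param enriched_band_ids cytoband(s) carrying a group-enriched event.
#' @param enriched_event "loss" or "gain" implanted in the enriched bands.
#' @param band_penetrance_h,band_penetrance_o fraction of patients of each
#'   group altered in the enriched bands.
#' @param background_alteration_rate per-band probability of a sporadic
#'   alteration.
#' @param n_signatures number of synthetic catalog signatures.
#' @param signature_mixture numeric vector (or patients x signatures matrix)
#'   of mixture weights; rows must sum to 1.
#' @param mutations_per_patient somatic SNVs drawn per patient.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_per_group = c(h = 40L, o = 20L),
                       de_fraction = 0.1,
                       effect_size = 2,
                       variance_ratio_o_vs_h = 10 / 7,
                       noise_sd = 1,
                       platform_shift_sd = 1,
                       tech_sd = 0.2,
                       concordant_fraction = 0.8,
                       n_shared_samples = 87L,
                       n_modules = 5L,
                       module_size = 20L,
                       module_loading = 3,
                       hazard_ratio = 3,
                       clinical_probs = list(
                         location = c(h = 0.60, o = 0.07),
                         sex = c(h = 0.76, o = 0.48),
                         grade = c(h = 0.58, o = 0.24),
                         differentiation = c(h = 0.88, o = 0.24)
                       ),
                       n_mirnas = 300L,
                       n_de_mirnas = 40L,
                       mirna_log2fc = 2,
                       n_true_interactions = 50L,
                       n_decoy_interactions = 200L,
                       interaction_pcc = -0.8,
                       mirna_dispersion = 50,
                       n_genes_per_band = 20L,
                       enriched_band_ids = "chr1:b02",
                       enriched_event = "loss",
                       band_penetrance_h = 0.8,
                       band_penetrance_o = 0.2,
                       background_alteration_rate = 0.05,
                       n_signatures = 3L,
                       signature_mixture = c(0.6, 0.3, 0.1),
                       mutations_per_patient = 100L) {
  cfg <- as.list(environment())
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  if (n_genes <= 0 || any(n_samples_per_group <= 0))
    stop("non-positive dimensions in configuration")
  if (!all(c("h", "o") %in% names(n_samples_per_group)))
    stop("n_samples_per_group must be named c(h=, o=)")
  if (de_fraction <= 0 || de_fraction >= 1)
    stop("de_fraction must lie in (0, 1)")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (variance_ratio_o_vs_h < 1)
    stop("variance_ratio_o_vs_h must be >= 1")
  if (concordant_fraction < 0 || concordant_fraction > 1)
    stop("concordant_fraction must lie in [0, 1]")
  if (interaction_pcc >= 0 || interaction_pcc < -1)
    stop("interaction_pcc must lie in [-1, 0)")
  if (mirna_log2fc <= 1)
    stop("mirna_log2fc must exceed 1 (the downstream filter threshold)")
  mix <- signature_mixture
  if (is.null(dim(mix))) mix <- matrix(mix, nrow = 1)
  if (ncol(mix) != n_signatures)
    stop("signature_mixture must have n_signatures columns")
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8))
    stop("signature_mixture rows must be non-negative and sum to 1")
  cfg$signature_mixture <- mix
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration (seed ", x$seed, ")\n", sep = "")
  cat("  expression: ", x$n_genes, " genes, h=", x$n_samples_per_group[["h"]],
      " / o=", x$n_samples_per_group[["o"]], " samples, ",
      round(100 * x$de_fraction), "% DE at effect ", x$effect_size,
      ", var ratio o/h ", x$variance_ratio_o_vs_h, "\n", sep = "")
  cat("  platforms : shift sd ", x$platform_shift_sd, ", ",
      round(100 * x$concordant_fraction), "% concordant genes, ",
      x$n_shared_samples, " shared samples\n", sep = "")
  cat("  miRNA     : ", x$n_mirnas, " mature, ", x$n_true_interactions,
      " true + ", x$n_decoy_interactions, " decoy interactions, target PCC ",
      x$interaction_pcc, "\n", sep = "")
  cat("  CNV       : enriched ", paste(x$enriched_band_ids, collapse = ","),
      " (", x$enriched_event, " ", x$band_penetrance_h, " vs ",
      x$band_penetrance_o, ")\n", sep = "")
  cat("  variants  : ", x$mutations_per_patient, " SNVs/patient from ",
      x$n_signatures, " signatures\n", sep = "")
  invisible(x)
}

# distinct sub-streams per generator, all derived from the one seed
sim_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset
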