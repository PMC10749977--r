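#' Simulation configuration for the pooled half-sib study design
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the pooled half-sib forage trial the package targets: 50 maternal family
#' pools genotyped by sequencing at a few thousand biallelic SNPs spread over
#' 9 chromosomes, 33 trait-clipping phenotypes with family-mean heritabilities
#' between 0.44 and 0.92 and a mean inter-trait correlation around 0.7, and an
#' 11-sample TPM expression matrix with planted coexpression modules.
#'
#' @param seed integer master seed; every stage derives its own stream from it
#'   by a fixed offset, so one seed fixes all outputs byte-for-byte.
#' @param n_families number of half-sib family pools.
#' @param n_markers number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param chromosome_length_bp length of each chromosome in bp.
#' @param founder_freq_range range of the uniform law founder alternative
#'   allele frequencies are drawn from.
#' @param family_concentration concentration of the Beta law family
#'   frequencies are drawn from around the founder frequency (larger =
#'   families more alike).
#' @param mean_depth expected sequencing depth (reads) per marker per family.
#' @param depth_dispersion negative-binomial size parameter for depth.
#' @param missing_rate fraction of (marker, family) cells forced to depth 0.
#' @param n_traits number of trait-clipping phenotypes.
#' @param n_individuals individuals phenotyped per family.
#' @param n_qtl QTLs per trait.
#' @param qtl_effect_sd standard deviation of QTL allele-substitution effects.
#' @param h2_targets per-trait family-mean heritability targets, recycled to
#'   \code{n_traits}; all in (0, 1].
#' @param trait_corr target mean correlation between trait genetic values,
#'   induced by sharing QTLs across traits (not by correlated noise).
#' @param within_family_frac fraction of the non-between-family variance that
#'   is within-family genetic rather than residual; the half-sib
#'   within-family variance structure for autotetraploids is left as a
#'   parameter rather than asserted.
#' @param n_expr_samples expression samples (genotypes), default 11.
#' @param n_genes annotated genes to simulate.
#' @param gene_length_bp mean gene length in bp.
#' @param fraction_genes_near_qtl fraction of genes placed so that they
#'   overlap a +/- 5 kb window of a planted QTL marker.
#' @param duplication_rate fraction of base genes emitted as multi-copy.
#' @param module_spec list of planted coexpression modules, each
#'   \code{list(size =, cor =)} giving module size and within-module
#'   correlation.
#' @param low_expr_frac fraction of background genes generated at low
#'   expression so they fail the TPM filter.
#' @param qtl_window_bp physical window used when placing genes near QTLs.
#' @return an object of class \code{sim_config} (validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_families = 50L,
                       n_markers = 2000L,
                       n_chromosomes = 9L,
                       chromosome_length_bp = 60e6,
                       founder_freq_range = c(0.05, 0.95),
                       family_concentration = 10,
                       mean_depth = 60,
                       depth_dispersion = 5,
                       missing_rate = 0.1,
                       n_traits = 33L,
                       n_individuals = 20L,
                       n_qtl = 5L,
                       qtl_effect_sd = 1,
                       h2_targets = NULL,
                       trait_corr = 0.7,
                       within_family_frac = 0.5,
                       n_expr_samples = 11L,
                       n_genes = 200L,
                       gene_length_bp = 2000,
                       fraction_genes_near_qtl = 0.2,
                       duplication_rate = 0.05,
                       module_spec = list(list(size = 10L, cor = 0.95),
                                          list(size = 8L, cor = 0.9)),
                       low_expr_frac = 0.1,
                       qtl_window_bp = 5000L) {
  if (is.null(h2_targets)) {
    # spread across the trial's reported heritability range
    h2_targets <- seq(0.44, 0.92, length.out = max(n_traits, 2L))[seq_len(n_traits)]
  }
  h2_targets <- rep_len(h2_targets, n_traits)
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              founder_freq_range = as.numeric(founder_freq_range),
              family_concentration = as.numeric(family_concentration),
              mean_depth = as.numeric(mean_depth),
              depth_dispersion = as.numeric(depth_dispersion),
              missing_rate = as.numeric(missing_rate),
              n_traits = as.integer(n_traits),
              n_individuals = as.integer(n_individuals),
              n_qtl = as.integer(n_qtl),
              qtl_effect_sd = as.numeric(qtl_effect_sd),
              h2_targets = as.numeric(h2_targets),
              trait_corr = as.numeric(trait_corr),
              within_family_frac = as.numeric(within_family_frac),
              n_expr_samples = as.integer(n_expr_samples),
              n_genes = as.integer(n_genes),
              gene_length_bp = as.numeric(gene_length_bp),
              fraction_genes_near_qtl = as.numeric(fraction_genes_near_qtl),
              duplication_rate = as.numeric(duplication_rate),
              module_spec = module_spec,
              low_expr_frac = as.numeric(low_expr_frac),
              qtl_window_bp = as.integer(qtl_window_bp))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, is.finite(cfg$seed))
  counts <- c("n_families", "n_markers", "n_chromosomes", "n_traits",
              "n_individuals", "n_qtl", "n_expr_samples", "n_genes")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("'", nm, "' must be >= 1", call. = FALSE)
  }
  fracs <- c("missing_rate", "fraction_genes_near_qtl", "duplication_rate",
             "low_expr_frac", "within_family_frac")
  for (nm in fracs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$h2_targets <= 0 | cfg$h2_targets > 1))
    stop("'h2_targets' must lie in (0, 1]", call. = FALSE)
  if (cfg$trait_corr < 0 || cfg$trait_corr > 1)
    stop("'trait_corr' must lie in [0, 1]", call. = FALSE)
  if (cfg$n_qtl > cfg$n_markers)
    stop("'n_qtl' cannot exceed 'n_markers'", call. = FALSE)
  if (diff(cfg$founder_freq_range) < 0 ||
      any(cfg$founder_freq_range < 0 | cfg$founder_freq_range > 1))
    stop("'founder_freq_range' must be an increasing pair in [0, 1]",
         call. = FALSE)
  szs <- vapply(cfg$module_spec, function(m) as.integer(m$size), integer(1))
  if (sum(szs) > cfg$n_genes)
    stop("planted module sizes exceed 'n_genes'", call. = FALSE)
  invisible(cfg)
}

# fixed per-stage seed offsets so each stage has its own reproducible stream
stage_seed <- function(cfg, stage) {
  offs <- c(genome = 101L, freqs = 211L, counts = 307L,
            pheno = 401L, expr = 503L)
  (cfg$seed + offs[[stage]]) %% .Machine$integer.max
}

#' Trait-clipping labels for the forage trial layout
#'
#' Returns the 33 trait-clipping labels of the study design (clippings 2-9
#' plus the total for green matter, dry matter and regrowth; clippings 2, 5
#' and total for leaf and stem dry matter), with season tags: wet = clippings
#' 2, 3, 7, 8, 9; dry = 4, 5, 6; totals are not season-specific.
#'
#' @param n_traits optionally truncate/recycle to a different trait count
#'   (used by small test configurations).
#' @return data.frame with columns label, trait, clipping, season.
#' @export
trait_layout <- function(n_traits = 33L) {
  full <- rbind(
    expand.grid(trait = c("GM", "DM", "RG"),
                clipping = c(as.character(2:9), "T"),
                stringsAsFactors = FALSE),
    expand.grid(trait = c("LDM", "SDM"), clipping = c("2", "5", "T"),
                stringsAsFactors = FALSE))
  full <- full[order(full$trait, full$clipping), ]
  season <- ifelse(full$clipping %in% c("2", "3", "7", "8", "9"), "wet",
                   ifelse(full$clipping %in% c("4", "5", "6"), "dry", "total"))
  out <- data.frame(label = paste(full$trait, full$clipping, sep = "-"),
                    trait = full$trait, clipping = full$clipping,
                    season = season, stringsAsFactors = FALSE)
  idx <- rep_len(seq_len(nrow(out)), n_traits)
  out <- out[idx, , drop = FALSE]
  if (n_traits > nrow(full))  # disambiguate recycled labels
    out$label <- make.unique(out$label, sep = ".")
  rownames(out) <- NULL
  out
}
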