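#' Bundled family-prediction benchmark tables
#'
#' Reference result tables from a published genome-wide family prediction
#' study of 50 pooled half-sib forage-grass families, shipped as plain TSVs:
#' \code{"model_comparison_fi2"} (per trait-clipping RKHS vs RF predictive
#' ability and MSE on the intersection marker sets),
#' \code{"marker_chromosomes"} (per-chromosome marker counts for the
#' complete, intersection and top-importance sets) and \code{"set_sizes"}
#' (mean selected-set sizes per selection stage). These are the inputs of
#' the report-aggregation arithmetic.
#'
#' @param name one of "model_comparison_fi2", "marker_chromosomes",
#'   "set_sizes".
#' @return data.frame.
#' @export
gwfp_benchmark <- function(name = c("model_comparison_fi2",
                                    "marker_chromosomes", "set_sizes")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("benchmark_", name, ".tsv"),
                      package = "gwfp", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Aggregate a two-model comparison table
#'
#' Given per trait-clipping PA and MSE of two models at table precision,
#' computes per-clipping differences and percent differences (from the
#' table-precision values), per-phenotype means of the unrounded percent
#' differences, and the overall mean as the mean of the per-phenotype means
#' (rounded only for display). This aggregation order — percentages from
#' printed precision, phenotype means unrounded, overall mean of the five
#' phenotype means — is the only one consistent with the benchmark table's
#' printed aggregates.
#'
#' @param tbl data.frame with phenotype, clipping, pa_rkhs, pa_rf,
#'   mse_rkhs, mse_rf (column pairs may name any two models).
#' @return list with \code{per_clipping}, \code{per_phenotype} and
#'   \code{overall} (pa_diff, pa_pct, mse_diff, mse_pct; \code{*_rounded}
#'   at one decimal).
#' @export
aggregate_model_comparison <- function(tbl) {
  need <- c("phenotype", "clipping", "pa_rkhs", "pa_rf", "mse_rkhs", "mse_rf")
  stopifnot(all(need %in% names(tbl)))
  pc <- tbl
  pc$pa_diff <- pc$pa_rf - pc$pa_rkhs
  pc$pa_pct <- 100 * pc$pa_diff / pc$pa_rkhs
  pc$mse_diff <- pc$mse_rf - pc$mse_rkhs
  pc$mse_pct <- 100 * pc$mse_diff / pc$mse_rkhs
  phenos <- unique(pc$phenotype)
  pp <- do.call(rbind, lapply(phenos, function(ph) {
    d <- pc[pc$phenotype == ph, ]
    data.frame(phenotype = ph,
               pa_diff = mean(d$pa_diff), pa_pct = mean(d$pa_pct),
               mse_diff = mean(d$mse_diff), mse_pct = mean(d$mse_pct),
               stringsAsFactors = FALSE)
  }))
  overall <- list(pa_diff = mean(pp$pa_diff), pa_pct = mean(pp$pa_pct),
                  mse_diff = mean(pp$mse_diff), mse_pct = mean(pp$mse_pct))
  overall$pa_pct_rounded <- round(overall$pa_pct, 1)
  overall$mse_pct_rounded <- round(overall$mse_pct, 1)
  list(per_clipping = pc, per_phenotype = pp, overall = overall)
}

#' Per-chromosome marker percentages
#'
#' @param counts integer vector of per-chromosome marker counts.
#' @return data.frame with count and percentage (one decimal; percentages
#'   sum to 100 up to rounding).
#' @export
chromosome_percentages <- function(counts) {
  data.frame(chromosome = names(counts), n = as.integer(counts),
             pct = round(100 * as.integer(counts) / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker-set sizes as percentages of the complete data
#'
#' @param sizes named numeric vector of set sizes.
#' @param cd_size complete-data marker count.
#' @param digits decimals (default 2).
#' @return data.frame with size and pct_of_cd.
#' @export
set_size_percentages <- function(sizes, cd_size, digits = 2L) {
  data.frame(set = names(sizes), size = as.numeric(sizes),
             pct_of_cd = round(100 * as.numeric(sizes) / cd_size, digits),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full family-prediction analysis
#'
#' Orchestrates the stages in order: genotypes (filter + impute + PCA),
#' phenotypes (family means, Min-Max scaling, correlations, heritability),
#' genomic prediction on the complete data, feature selection with
#' intersections and major-importance markers, genomic prediction on the
#' intersection sets, marker-gene linkage, and the coexpression network.
#' Every stage writes TSV outputs into \code{out_dir} and the run is
#' deterministic under a fixed config.
#'
#' @param sim a \code{\link{sim_config}}: the run generates its own inputs
#'   (fixture mode). Alternatively pass \code{study}, a prebuilt
#'   \code{\link{simulate_study}}-shaped list.
#' @param study optional prebuilt input bundle (overrides \code{sim}).
#' @param out_dir output directory; NULL skips file output.
#' @param models model names for cross-validation (default RKHS and RF, the
#'   benchmark pair; any of RKHS, BRR, SVM, RF, AB, MLP).
#' @param datasets any of "CD", "FI-1", "FI-2".
#' @param k,repetitions cross-validation folds and repeats.
#' @param mcmc list overriding MCMC settings of RKHS/BRR (n_iter, burn_in,
#'   thin).
#' @param window linkage half-window in bp.
#' @param hrr_limit HRR edge rank limit.
#' @param seed master seed for every stochastic stage.
#' @return list with all stage outputs (see Details in the vignette).
#' @export
run_pipeline <- function(sim = NULL, study = NULL, out_dir = NULL,
                         models = c("RKHS", "RF"),
                         datasets = c("CD", "FI-2"),
                         k = 5L, repetitions = 10L,
                         mcmc = list(), window = 5000L, hrr_limit = 30L,
                         seed = 1L) {
  if (is.null(study)) {
    if (is.null(sim)) stop("provide either 'sim' or 'study'")
    study <- simulate_study(sim)
  }
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ## genotypes
  filt <- filter_markers(study$counts, study$marker_map)
  Z <- impute_site_mean(filt$freqs)
  if (k > nrow(Z)) stop("gp_models: k = ", k, " folds exceed ", nrow(Z),
                        " families (partition impossible)")
  geno_pca <- pca_scores(Z, n_components = 2L)
  say("genotypes: %d markers in, %d retained",
      ncol(study$counts$ref), ncol(Z))

  ## phenotypes
  fm <- family_means(study$individuals)
  if (nrow(fm$missing_cells))
    stop("phenotypes: missing family x trait cells")
  Y <- minmax_scale(fm$means[rownames(Z), , drop = FALSE])
  tc <- trait_correlations(Y)
  herit <- do.call(rbind, lapply(colnames(Y), function(tr) {
    d <- study$individuals[study$individuals$trait == tr, ]
    fit <- reml_variance_components(d$value, d$family_id, d$block)
    data.frame(trait = tr, sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
               h2_family = fit$h2_family, h2_narrow = fit$h2_narrow,
               stringsAsFactors = FALSE)
  }))
  say("phenotypes: %d traits, mean correlation %.2f", ncol(Y),
      tc$mean_offdiag)

  traits <- colnames(Y)
  mk_spec <- function(name) {
    if (name %in% c("RKHS", "BRR")) do.call(model_spec, c(list(name), mcmc))
    else model_spec(name)
  }

  ## feature selection per trait
  fs_methods <- c("gbt", "extratrees", "rf")
  featsel <- lapply(seq_along(traits), function(ti) {
    y <- Y[, ti]
    fs <- lapply(seq_along(fs_methods), function(mi)
      fs_select(fs_methods[mi], Z, y,
                seed = (seed + 100L * ti + mi) %% .Machine$integer.max))
    names(fs) <- fs_methods
    sets <- lapply(fs, `[[`, "selected")
    fi1 <- feature_intersection(sets, 2L, colnames(Z))
    fi2 <- feature_intersection(sets, 3L, colnames(Z))
    gini <- if (length(fi2))
      gini_importance(Z[, fi2, drop = FALSE], y,
                      seed = (seed + 100L * ti + 9L) %% .Machine$integer.max)
    else numeric(0)
    major <- if (length(gini))
      major_importance_selection(gini, marker_order = colnames(Z))
    else data.frame(marker_id = character(0), importance = numeric(0))
    list(fs = fs, fi1 = fi1, fi2 = fi2, gini = gini, major = major)
  })
  names(featsel) <- traits
  say("featsel: mean FI-1 %.1f, FI-2 %.1f markers",
      mean(lengths(lapply(featsel, `[[`, "fi1"))),
      mean(lengths(lapply(featsel, `[[`, "fi2"))))

  ## cross-validation over datasets x models x traits
  cv_rows <- list()
  for (ds in datasets) {
    for (mname in models) {
      spec <- mk_spec(mname)
      for (ti in seq_along(traits)) {
        Zd <- switch(ds,
                     "CD" = Z,
                     "FI-1" = Z[, featsel[[ti]]$fi1, drop = FALSE],
                     "FI-2" = Z[, featsel[[ti]]$fi2, drop = FALSE],
                     stop("unknown dataset: ", ds))
        if (ncol(Zd) == 0L) next
        cv <- cross_validate(spec, Zd, Y[, ti], k = k,
                             repetitions = repetitions,
                             seed = (seed + 17L * ti) %% .Machine$integer.max)
        cv$model <- mname; cv$dataset <- ds; cv$trait <- traits[ti]
        cv_rows[[length(cv_rows) + 1L]] <- cv
      }
    }
  }
  cv_results <- do.call(rbind, cv_rows)
  say("gp_models: %d CV repetitions recorded", nrow(cv_results))

  ## linkage from major-importance markers
  major_tbl <- do.call(rbind, lapply(traits, function(tr) {
    m <- featsel[[tr]]$major
    if (!nrow(m)) return(NULL)
    lay <- study$trait_layout[match(tr, study$trait_layout$label), ]
    data.frame(trait = tr, marker_id = m$marker_id,
               importance = m$importance, season = lay$season,
               stringsAsFactors = FALSE)
  }))
  major_union <- unique(major_tbl$marker_id)
  fi2_union <- unique(unlist(lapply(featsel, `[[`, "fi2")))
  lk <- link_genes(major_union, study$marker_map, study$genes,
                   window = window)
  phys_map <- physical_map_export(lk$links, major_tbl, fi2_union,
                                  study$marker_map)
  say("linkage: %d major markers, %d gene links, %d unlinked markers",
      length(major_union), nrow(lk$links), length(lk$unlinked_markers))

  ## coexpression network
  expr <- tpm_filter(study$tpm)
  corr <- suppressWarnings(correlation_tests(expr))
  net <- hrr_network(corr, hrr_limit = hrr_limit)
  seed_genes <- intersect(unique(lk$links$gene_id), rownames(expr))
  coexpr <- NULL
  if (length(seed_genes)) {
    exp_res <- expand_seed_set(net, corr, seed_genes)
    trait_net <- gene_neighborhood(exp_res$network,
                                   union(seed_genes, exp_res$added), 2L)
    # clippings associated with each seed gene via its linked markers
    m2cl <- split(sub("^.*-", "", major_tbl$trait), major_tbl$marker_id)
    g2cl <- lapply(split(lk$links$marker_id, lk$links$gene_id),
                   function(ms) unique(unlist(m2cl[ms])))
    seasons <- seasonal_split(exp_res$network, g2cl, order = 2L)
    hubs <- degree_hubs(trait_net$graph)
    enr <- term_enrichment(igraph::V(trait_net$graph)$name,
                           rownames(expr), study$term_map)
    coexpr <- list(network = net, expanded = exp_res, trait_net = trait_net,
                   seasons = seasons, hubs = hubs, enrichment = enr)
    say("coexpr: %d nodes / %d edges in trait network; %d hubs",
        igraph::vcount(trait_net$graph), igraph::ecount(trait_net$graph),
        sum(hubs$degrees$hub))
  } else say("coexpr: no seed genes linked; network stage skipped")

  result <- list(study = study, Z = Z, filter_report = filt$report,
                 marker_map = filt$marker_map, geno_pca = geno_pca,
                 Y = Y, trait_correlations = tc, heritability = herit,
                 featsel = featsel, cv_results = cv_results,
                 major_markers = major_tbl, fi2_union = fi2_union,
                 linkage = lk, physical_map = phys_map, coexpr = coexpr,
                 log = log_lines)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
  w(result$filter_report, "filter_report.tsv")
  w(cbind(family = rownames(result$Z), as.data.frame(result$Z)),
    "genotype_matrix.tsv")
  w(cbind(family = rownames(result$Y), as.data.frame(result$Y)),
    "phenotype_matrix.tsv")
  w(result$heritability, "heritability.tsv")
  w(result$cv_results, "cv_results.tsv")
  sel_rows <- do.call(rbind, lapply(names(result$featsel), function(tr) {
    fs <- result$featsel[[tr]]
    rbind(
      if (length(fs$fi1)) data.frame(trait = tr, method = "FI-1",
                                     marker_id = fs$fi1),
      if (length(fs$fi2)) data.frame(trait = tr, method = "FI-2",
                                     marker_id = fs$fi2),
      if (nrow(fs$major)) data.frame(trait = tr, method = "MAJOR",
                                     marker_id = fs$major$marker_id))
  }))
  w(sel_rows, "selected_markers.tsv")
  w(result$linkage$links, "gene_links.tsv")
  w(result$physical_map, "physical_map.tsv")
  if (!is.null(result$coexpr)) {
    ed <- igraph::as_data_frame(result$coexpr$expanded$network, "edges")
    w(ed, "network_edges.tsv")
    w(result$coexpr$hubs$degrees, "network_degrees.tsv")
    if (nrow(result$coexpr$enrichment)) w(result$coexpr$enrichment,
                                          "term_enrichment.tsv")
  }
  writeLines(result$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(out_dir)
}

#' Summary report of a pipeline run
#'
#' Emits (a) a benchmark-style two-model comparison per trait (PA/MSE
#' means at table precision with absolute and percent differences and the
#' aggregation of \code{\link{aggregate_model_comparison}}), (b) the
#' chromosome distribution of the complete, intersection and
#' major-importance marker sets, and (c) marker/gene/network inventories.
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param model_a,model_b the two models to compare (defaults RKHS vs RF).
#' @param dataset dataset label for the comparison (default "FI-2").
#' @return list with \code{comparison}, \code{chromosomes},
#'   \code{inventory}.
#' @export
pipeline_report <- function(result, model_a = "RKHS", model_b = "RF",
                            dataset = "FI-2") {
  cvr <- result$cv_results
  layout <- result$study$trait_layout
  traits <- unique(cvr$trait)
  rows <- lapply(traits, function(tr) {
    a <- cvr[cvr$model == model_a & cvr$dataset == dataset & cvr$trait == tr, ]
    b <- cvr[cvr$model == model_b & cvr$dataset == dataset & cvr$trait == tr, ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    lay <- layout[match(tr, layout$label), ]
    data.frame(phenotype = lay$trait, clipping = lay$clipping,
               pa_rkhs = round(mean(a$pa), 3), pa_rf = round(mean(b$pa), 3),
               mse_rkhs = round(mean(a$mse), 3), mse_rf = round(mean(b$mse), 3),
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  comparison <- if (!is.null(tbl)) aggregate_model_comparison(tbl) else NULL

  chroms <- result$marker_map$chromosome
  mk_counts <- function(ids) table(factor(
    result$marker_map$chromosome[match(ids, result$marker_map$marker_id)],
    levels = unique(chroms)))
  chrom_tab <- list(
    CD = chromosome_percentages(table(factor(chroms, unique(chroms)))),
    FI2 = chromosome_percentages(mk_counts(result$fi2_union)),
    MAJOR = chromosome_percentages(mk_counts(unique(
      result$major_markers$marker_id))))

  inventory <- data.frame(
    quantity = c("markers_cd", "markers_fi2_union", "markers_major_union",
                 "genes_linked", "multicopy_genes", "network_nodes",
                 "network_edges", "hub_genes"),
    value = c(ncol(result$Z), length(result$fi2_union),
              length(unique(result$major_markers$marker_id)),
              length(unique(result$linkage$links$gene_id)),
              nrow(multicopy_genes(result$linkage$links)),
              if (is.null(result$coexpr)) 0
              else igraph::vcount(result$coexpr$trait_net$graph),
              if (is.null(result$coexpr)) 0
              else igraph::ecount(result$coexpr$trait_net$graph),
              if (is.null(result$coexpr)) 0
              else sum(result$coexpr$hubs$degrees$hub)))
  list(comparison = comparison, chromosomes = chrom_tab,
       inventory = inventory)
}
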