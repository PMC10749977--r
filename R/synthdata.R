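#' @useDynLib gwfp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rbinom rnbinom rnorm runif rchisq var cor sd
#'   median prcomp aov TukeyHSD pt phyper qnorm quantile setNames
#' @importFrom utils read.delim write.table head
NULL

#' Simulate a marker map and gene annotation
#'
#' Markers are spread over \code{n_chromosomes} chromosomes at distinct,
#' strictly increasing positions. A deterministic subset of markers is
#' designated as the planted-QTL pool that \code{\link{simulate_phenotypes}}
#' draws from, and a configured fraction of genes is placed so that the gene
#' span overlaps a +/- \code{qtl_window_bp} window of a pool marker.
#' Duplicated base genes are emitted as multiple copies with distinct copy
#' indices, each copy placed independently (near a different pool marker when
#' near-QTL placement applies).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{marker_map} (data.frame: marker_id, chromosome,
#'   position, ref, alt), \code{genes} (data.frame: gene_id, copy_index,
#'   chromosome, start, end), \code{qtl_pool} (marker ids), and
#'   \code{genes_near_qtl} (gene ids placed near pool markers).
#' @export
simulate_genome <- function(cfg) {
  set.seed(stage_seed(cfg, "genome"))
  n_chr <- cfg$n_chromosomes
  per_chr <- diff(round(seq(0, cfg$n_markers, length.out = n_chr + 1L)))
  if (any(per_chr > cfg$chromosome_length_bp))
    stop("more markers than available positions on a chromosome")
  chrom <- rep(paste0("chr", seq_len(n_chr)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(cfg$chromosome_length_bp, k))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_markers, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  mm <- data.frame(marker_id = sprintf("M%05d", seq_len(cfg$n_markers)),
                   chromosome = chrom, position = pos,
                   ref = unname(ref), alt = unname(alt),
                   stringsAsFactors = FALSE)

  pool_n <- qtl_pool_size(cfg)
  qtl_pool <- sort(sample(mm$marker_id, min(pool_n, cfg$n_markers)))

  # gene placement
  n_near <- round(cfg$fraction_genes_near_qtl * cfg$n_genes)
  n_dup <- round(cfg$duplication_rate * cfg$n_genes)
  base_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  near_flag <- c(rep(TRUE, n_near), rep(FALSE, cfg$n_genes - n_near))
  copies <- rep(1L, cfg$n_genes)
  if (n_dup > 0) copies[sample.int(cfg$n_genes, n_dup)] <- 2L

  place_gene <- function(near) {
    len <- max(200, round(rnorm(1, cfg$gene_length_bp, cfg$gene_length_bp / 4)))
    if (near) {
      m <- mm[mm$marker_id == sample(qtl_pool, 1L), ]
      # any start that intersects [pos - w, pos + w]
      lo <- max(1, m$position - cfg$qtl_window_bp - len + 1L)
      hi <- m$position + cfg$qtl_window_bp
      start <- sample(seq.int(lo, hi), 1L)
      chr <- m$chromosome
    } else {
      chr <- paste0("chr", sample.int(cfg$n_chromosomes, 1L))
      start <- sample.int(max(1, cfg$chromosome_length_bp - len), 1L)
    }
    c(chr = chr, start = start, end = start + len - 1L)
  }
  rows <- vector("list", sum(copies))
  k <- 0L
  for (i in seq_len(cfg$n_genes)) {
    for (cp in seq_len(copies[i])) {
      pg <- place_gene(near_flag[i])
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = base_ids[i], copy_index = cp,
                              chromosome = pg[["chr"]],
                              start = as.integer(pg[["start"]]),
                              end = as.integer(pg[["end"]]),
                              stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chromosome, genes$start), ]
  rownames(genes) <- NULL
  list(marker_map = mm, genes = genes, qtl_pool = qtl_pool,
       genes_near_qtl = base_ids[near_flag])
}

# number of distinct QTL markers phenotype simulation will need
qtl_pool_size <- function(cfg) {
  sh <- shared_qtl_count(cfg)
  sh + (cfg$n_qtl - sh) * cfg$n_traits
}

shared_qtl_count <- function(cfg) {
  rho <- cfg$trait_corr
  if (rho == 0) return(0L)
  if (rho == 1) return(cfg$n_qtl)
  if (cfg$n_qtl < 2L)
    stop("cannot induce 0 < trait_corr < 1 with a single QTL per trait")
  min(cfg$n_qtl - 1L, max(1L, round(rho * cfg$n_qtl)))
}

#' Simulate true family allele frequencies
#'
#' Founder alternative-allele frequencies are drawn uniformly on the
#' configured range; each family's pool frequency is then drawn from a Beta
#' law with mean equal to the founder frequency and the configured
#' concentration, so between-family variance exists at every polymorphic
#' marker while frequencies stay in [0, 1]. Degenerate founder frequencies
#' (0 or 1) propagate unchanged to all families.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param marker_map marker map from \code{\link{simulate_genome}}.
#' @return list with \code{freqs} (families x markers matrix in [0,1]) and
#'   \code{founder_freqs}.
#' @export
simulate_family_freqs <- function(cfg, marker_map) {
  set.seed(stage_seed(cfg, "freqs"))
  p0 <- runif(cfg$n_markers, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  conc <- cfg$family_concentration
  F <- matrix(0, cfg$n_families, cfg$n_markers,
              dimnames = list(sprintf("F%02d", seq_len(cfg$n_families)),
                              marker_map$marker_id))
  for (j in seq_len(cfg$n_markers)) {
    if (p0[j] <= 0) F[, j] <- 0
    else if (p0[j] >= 1) F[, j] <- 1
    else F[, j] <- rbeta(cfg$n_families, p0[j] * conc, (1 - p0[j]) * conc)
  }
  list(freqs = F, founder_freqs = setNames(p0, marker_map$marker_id))
}

#' Simulate pooled GBS read counts from true family frequencies
#'
#' Per (family, marker) cell the total depth is negative-binomial with the
#' configured mean and dispersion, the alternative-allele count is binomial
#' in the true frequency, and a \code{missing_rate} fraction of cells is
#' forced to depth 0 — the form missing data takes in GBS pools.
#'
#' @param true_freqs families x markers matrix in [0, 1].
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{read_counts} object: list of integer matrices \code{ref}
#'   and \code{alt} (families x markers).
#' @export
simulate_read_counts <- function(true_freqs, cfg) {
  stopifnot(all(true_freqs >= 0 & true_freqs <= 1))
  set.seed(stage_seed(cfg, "counts"))
  n <- length(true_freqs)
  depth <- rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  if (cfg$missing_rate > 0) {
    miss <- sample.int(n, round(cfg$missing_rate * n))
    depth[miss] <- 0L
  }
  alt <- rbinom(n, depth, as.vector(true_freqs))
  dm <- dimnames(true_freqs)
  out <- list(ref = matrix(as.integer(depth - alt), nrow(true_freqs),
                           dimnames = dm),
              alt = matrix(as.integer(alt), nrow(true_freqs), dimnames = dm))
  class(out) <- "read_counts"
  out
}

#' Simulate individual phenotypes with planted QTLs
#'
#' Each trait's family genetic value is a linear combination of family allele
#' frequencies at its QTL markers. Traits share a common QTL subset (with
#' common effects) whose variance share equals the target inter-trait
#' correlation, so correlated trait-clippings arise from shared markers
#' rather than correlated noise. Individual values add a within-family
#' genetic deviation and a residual, scaled so the family-mean heritability
#' matches the per-trait target; small fixed block effects are added so the
#' mixed-model machinery is exercised.
#'
#' @param true_freqs families x markers matrix.
#' @param cfg a \code{\link{sim_config}}.
#' @param qtl_pool marker ids reserved for QTLs (from
#'   \code{\link{simulate_genome}}); defaults to the first markers.
#' @return list with \code{individuals} (long data.frame: individual_id,
#'   family_id, block, trait, value), \code{family_genetic_values}
#'   (families x traits), and \code{ground_truth} (per-trait QTL ids,
#'   effects, realized h2).
#' @export
simulate_phenotypes <- function(true_freqs, cfg, qtl_pool = NULL) {
  set.seed(stage_seed(cfg, "pheno"))
  n_fam <- nrow(true_freqs)
  n_ind <- cfg$n_individuals
  layout <- trait_layout(cfg$n_traits)
  if (is.null(qtl_pool)) {
    qtl_pool <- colnames(true_freqs)[seq_len(min(qtl_pool_size(cfg),
                                                 ncol(true_freqs)))]
  }
  rho <- cfg$trait_corr
  s <- shared_qtl_count(cfg)
  u <- cfg$n_qtl - s
  shared <- if (s > 0) qtl_pool[seq_len(s)] else character(0)
  rest <- setdiff(qtl_pool, shared)
  if (length(rest) < u * cfg$n_traits)
    stop("QTL pool too small for the requested private QTLs per trait")
  eff_shared <- rnorm(s, 0, cfg$qtl_effect_sd)
  g_shared <- if (s > 0) drop(true_freqs[, shared, drop = FALSE] %*% eff_shared)
              else rep(0, n_fam)
  var_s <- var(g_shared)
  if (rho > 0 && rho < 1 && var_s < 1e-12)
    stop("infeasible correlation target: shared QTLs carry no variance")

  qtl_markers <- qtl_effects <- vector("list", cfg$n_traits)
  G <- matrix(0, n_fam, cfg$n_traits,
              dimnames = list(rownames(true_freqs), layout$label))
  for (t in seq_len(cfg$n_traits)) {
    priv <- if (u > 0) rest[((t - 1L) * u + 1L):(t * u)] else character(0)
    eff_p <- rnorm(length(priv), 0, cfg$qtl_effect_sd)
    g_p <- if (u > 0) drop(true_freqs[, priv, drop = FALSE] %*% eff_p)
           else rep(0, n_fam)
    if (rho > 0 && rho < 1) {
      # scale private variance so shared share equals the correlation target
      target_vp <- var_s * (1 - rho) / rho
      vp <- var(g_p)
      if (vp < 1e-12) stop("infeasible correlation target: degenerate private QTLs")
      sc <- sqrt(target_vp / vp)
      eff_p <- eff_p * sc
      g_p <- g_p * sc
    } else if (rho == 1) {
      eff_p <- numeric(0); priv <- character(0); g_p <- rep(0, n_fam)
    }
    g <- if (rho == 0) g_p else g_shared + g_p
    qtl_markers[[t]] <- c(shared, priv)
    qtl_effects[[t]] <- setNames(c(if (rho > 0) eff_shared else numeric(0), eff_p),
                                 c(if (rho > 0) shared else character(0), priv))
    G[, t] <- g
  }

  block <- factor(seq_len(n_ind))  # one plant per family per block
  block_eff <- rnorm(n_ind, 0, 0.1 * sqrt(max(apply(G, 2, var))))
  rows <- vector("list", cfg$n_traits)
  realized_h2 <- numeric(cfg$n_traits)
  for (t in seq_len(cfg$n_traits)) {
    h2 <- cfg$h2_targets[t]
    vb <- var(G[, t])
    vtot <- if (h2 >= 1) 0 else n_ind * vb * (1 - h2) / h2
    vw <- cfg$within_family_frac * vtot
    ve <- vtot - vw
    w <- matrix(rnorm(n_fam * n_ind, 0, sqrt(vw)), n_fam)
    e <- matrix(rnorm(n_fam * n_ind, 0, sqrt(ve)), n_fam)
    y <- outer(G[, t], rep(1, n_ind)) + w + e +
         matrix(block_eff, n_fam, n_ind, byrow = TRUE)
    dev_var <- var(as.vector(w + e))
    realized_h2[t] <- vb / (vb + dev_var / n_ind)
    rows[[t]] <- data.frame(
      individual_id = paste0(rep(rownames(true_freqs), n_ind), "_I",
                             rep(seq_len(n_ind), each = n_fam)),
      family_id = rep(rownames(true_freqs), n_ind),
      block = rep(seq_len(n_ind), each = n_fam),
      trait = colnames(G)[t],
      value = as.vector(y), stringsAsFactors = FALSE)
  }
  individuals <- do.call(rbind, rows)
  rownames(individuals) <- NULL
  gt <- list(qtl_markers = setNames(qtl_markers, colnames(G)),
             qtl_effects = setNames(qtl_effects, colnames(G)),
             realized_h2 = setNames(realized_h2, colnames(G)),
             shared_qtls = shared)
  list(individuals = individuals, family_genetic_values = G,
       trait_layout = layout, ground_truth = gt)
}

#' Simulate a TPM expression matrix with planted coexpression modules
#'
#' Planted modules are generated from a shared latent factor with the
#' configured within-module correlation; module genes are drawn preferentially
#' from genes placed near planted QTLs so the marker-to-network path of the
#' analysis has a recoverable signal. Background genes are independent, and a
#' configured fraction is generated at low expression so it fails the TPM
#' filter.
#'
#' @param genome output of \code{\link{simulate_genome}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{tpm} (genes x samples matrix), \code{modules}
#'   (list of gene-id vectors, disjoint), \code{low_expressed} (gene ids).
#' @export
simulate_expression <- function(genome, cfg) {
  set.seed(stage_seed(cfg, "expr"))
  gene_ids <- unique(genome$genes$gene_id)
  n_g <- length(gene_ids)
  n_s <- cfg$n_expr_samples
  sizes <- vapply(cfg$module_spec, function(m) as.integer(m$size), integer(1))
  cors <- vapply(cfg$module_spec, function(m) as.numeric(m$cor), numeric(1))
  # modules preferentially recruit genes near planted QTLs
  pref <- intersect(genome$genes_near_qtl, gene_ids)
  ordered_pool <- c(pref, setdiff(gene_ids, pref))
  modules <- list(); used <- 0L
  for (i in seq_along(sizes)) {
    modules[[i]] <- ordered_pool[(used + 1L):(used + sizes[i])]
    used <- used + sizes[i]
  }
  background <- setdiff(gene_ids, unlist(modules))
  n_low <- round(cfg$low_expr_frac * length(background))
  low <- if (n_low > 0) sample(background, n_low) else character(0)

  tpm <- matrix(0, n_g, n_s,
                dimnames = list(gene_ids, sprintf("S%02d", seq_len(n_s))))
  mu <- exp(runif(n_g, log(5), log(200)))
  names(mu) <- gene_ids
  z <- matrix(rnorm(n_g * n_s), n_g, n_s, dimnames = dimnames(tpm))
  for (i in seq_along(modules)) {
    f <- rnorm(n_s)
    r <- sqrt(cors[i])
    for (g in modules[[i]]) z[g, ] <- r * f + sqrt(1 - cors[i]) * rnorm(n_s)
  }
  cv <- 0.3  # coefficient of variation keeps TPM positive in practice
  for (g in gene_ids) tpm[g, ] <- pmax(0, mu[g] * (1 + cv * z[g, ]))
  for (g in low) tpm[g, ] <- runif(n_s, 0, 0.9)
  list(tpm = tpm, modules = modules, low_expressed = low)
}

#' Run the whole generator for one configuration
#'
#' Convenience wrapper producing every input the analysis pipeline consumes
#' plus the ground truth needed by recovery tests: marker map, gene
#' annotation, true family frequencies, read counts, individual phenotypes,
#' TPM expression, and a gene-to-term map in which one term is concentrated
#' in each planted module (so enrichment has a recoverable signal).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return named list of all generated pieces; \code{$ground_truth} collects
#'   planted QTLs, realized heritabilities, modules and genes near QTLs.
#' @export
simulate_study <- function(cfg) {
  genome <- simulate_genome(cfg)
  fr <- simulate_family_freqs(cfg, genome$marker_map)
  counts <- simulate_read_counts(fr$freqs, cfg)
  ph <- simulate_phenotypes(fr$freqs, cfg, genome$qtl_pool)
  ex <- simulate_expression(genome, cfg)

  set.seed(stage_seed(cfg, "expr") + 7L)
  gene_ids <- unique(genome$genes$gene_id)
  n_terms <- max(6L, length(ex$modules) + 4L)
  terms <- sprintf("T%04d", seq_len(n_terms))
  tm <- data.frame(gene_id = sample(gene_ids, length(gene_ids), replace = FALSE),
                   term = sample(terms[-seq_along(ex$modules)],
                                 length(gene_ids), replace = TRUE),
                   stringsAsFactors = FALSE)
  mod_rows <- do.call(rbind, lapply(seq_along(ex$modules), function(i)
    data.frame(gene_id = ex$modules[[i]], term = terms[i],
               stringsAsFactors = FALSE)))
  term_map <- rbind(tm, mod_rows)
  term_map <- term_map[order(term_map$gene_id, term_map$term), ]
  rownames(term_map) <- NULL

  gt <- c(ph$ground_truth,
          list(planted_modules = ex$modules,
               genes_near_qtl = genome$genes_near_qtl,
               low_expressed = ex$low_expressed,
               qtl_pool = genome$qtl_pool,
               founder_freqs = fr$founder_freqs))
  list(config = cfg, marker_map = genome$marker_map, genes = genome$genes,
       true_freqs = fr$freqs, counts = counts,
       individuals = ph$individuals,
       family_genetic_values = ph$family_genetic_values,
       trait_layout = ph$trait_layout,
       tpm = ex$tpm, term_map = term_map, ground_truth = gt)
}
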