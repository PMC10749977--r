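#' Expression filter on TPM values
#'
#' Keeps genes with strictly more than \code{min_tpm} TPM in at least
#' \code{min_samples} samples.
#'
#' @param tpm genes x samples matrix.
#' @param min_tpm threshold (default 1, strict).
#' @param min_samples minimum qualifying samples (default 3).
#' @return filtered matrix.
#' @export
tpm_filter <- function(tpm, min_tpm = 1, min_samples = 3L) {
  keep <- rowSums(tpm > min_tpm) >= min_samples
  tpm[keep, , drop = FALSE]
}

#' Pairwise Pearson correlations with two-sided p values
#'
#' Pearson r for every gene pair and the p value of the t transform
#' t = r sqrt(n-2) / sqrt(1-r^2) on n-2 degrees of freedom. The Bonferroni
#' multiplier m = number of tested pairs is returned for downstream
#' correction. Zero-variance genes are excluded with a warning.
#'
#' @param expr genes x samples matrix with >= 3 samples.
#' @return list with \code{r} (genes x genes), \code{p} (same shape),
#'   \code{m} (pair count), \code{dropped} (excluded gene ids).
#' @export
correlation_tests <- function(expr) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  v <- apply(expr, 1, var)
  dropped <- rownames(expr)[v == 0]
  if (length(dropped))
    warning("excluding zero-variance gene(s): ",
            paste(head(dropped), collapse = ", "))
  expr <- expr[v > 0, , drop = FALSE]
  n <- ncol(expr)
  r <- cor(t(expr))
  rr <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- rr * sqrt(n - 2) / sqrt(1 - rr^2)
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  g <- nrow(expr)
  list(r = r, p = p, m = g * (g - 1) / 2, dropped = dropped)
}

#' Highest-reciprocal-rank coexpression network
#'
#' For each gene, all other genes are ranked by descending correlation
#' (rank 1 = strongest; ties broken by gene order for determinism). The HRR
#' of a pair is the larger of its two directed ranks, and an edge is kept
#' iff HRR <= \code{hrr_limit} (\code{hrr_mode = "rank_cutoff"}, the rank
#' convention of the HRR method). \code{"top_edges"} instead caps every
#' node at its \code{hrr_limit} smallest-HRR edges post hoc.
#'
#' @param corr output of \code{\link{correlation_tests}} (or a list with at
#'   least \code{r} and \code{p}).
#' @param hrr_limit rank limit (default 30).
#' @param hrr_mode "rank_cutoff" or "top_edges".
#' @return an \pkg{igraph} graph; edges carry r, p, hrr and origin
#'   ("hrr"), vertices carry the gene names.
#' @export
hrr_network <- function(corr, hrr_limit = 30L,
                        hrr_mode = c("rank_cutoff", "top_edges")) {
  hrr_mode <- match.arg(hrr_mode)
  r <- corr$r
  g <- nrow(r)
  genes <- rownames(r)
  # directed ranks: rank_i(j) among all j != i, descending r, ties by order
  rank_mat <- matrix(NA_integer_, g, g, dimnames = dimnames(r))
  for (i in seq_len(g)) {
    o <- order(-r[i, -i])
    others <- seq_len(g)[-i]
    rank_mat[i, others[o]] <- seq_len(g - 1L)
  }
  hrr <- pmax(rank_mat, t(rank_mat))
  keep <- which(upper.tri(hrr) & hrr <= (if (hrr_mode == "rank_cutoff")
                                           hrr_limit else g), arr.ind = TRUE)
  ed <- data.frame(from = genes[keep[, 1]], to = genes[keep[, 2]],
                   r = r[keep], p = corr$p[keep], hrr = hrr[keep],
                   origin = "hrr", stringsAsFactors = FALSE)
  if (hrr_mode == "top_edges" && nrow(ed)) {
    ed <- ed[order(ed$hrr), ]
    deg <- setNames(integer(g), genes)
    sel <- logical(nrow(ed))
    for (k in seq_len(nrow(ed))) {
      a <- ed$from[k]; b <- ed$to[k]
      if (deg[a] < hrr_limit && deg[b] < hrr_limit) {
        sel[k] <- TRUE
        deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      }
    }
    ed <- ed[sel, ]
  }
  gr <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                      vertices = data.frame(name = genes))
  gr
}

#' Expand a seed gene set by high correlations
#'
#' Adds every non-seed gene whose correlation with some seed gene is at
#' least \code{r_min} with Bonferroni-corrected p at most \code{alpha}
#' (multiplier \code{corr$m}); qualifying edges are added with origin
#' "expansion".
#'
#' @param network an \pkg{igraph} graph from \code{\link{hrr_network}}.
#' @param corr output of \code{\link{correlation_tests}}.
#' @param seed_genes character vector of seed gene ids (non-empty).
#' @return list with \code{network} (graph including expansion edges),
#'   \code{added} (new gene ids).
#' @export
expand_seed_set <- function(network, corr, seed_genes, r_min = 0.9,
                            alpha = 0.01) {
  if (!length(seed_genes)) stop("empty seed set")
  genes <- rownames(corr$r)
  seed_genes <- intersect(seed_genes, genes)
  cand <- setdiff(genes, seed_genes)
  rs <- corr$r[cand, seed_genes, drop = FALSE]
  ps <- corr$p[cand, seed_genes, drop = FALSE] * corr$m
  ok <- rs >= r_min & ps <= alpha
  idx <- which(ok, arr.ind = TRUE)
  added <- unique(cand[idx[, 1]])
  if (nrow(idx)) {
    new_edges <- data.frame(from = cand[idx[, 1]],
                            to = seed_genes[idx[, 2]],
                            r = rs[idx], p = corr$p[cand, seed_genes,
                                                    drop = FALSE][idx],
                            hrr = NA_integer_, origin = "expansion",
                            stringsAsFactors = FALSE)
    # drop pairs already present as HRR edges
    have <- igraph::as_data_frame(network, what = "edges")
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    new_edges <- new_edges[!(key(new_edges$from, new_edges$to) %in%
                               key(have$from, have$to)), , drop = FALSE]
    if (nrow(new_edges)) {
      network <- igraph::add_edges(
        network, as.vector(rbind(new_edges$from, new_edges$to)),
        r = new_edges$r, p = new_edges$p, hrr = new_edges$hrr,
        origin = new_edges$origin)
    }
  }
  list(network = network, added = added)
}

#' First/second-neighbor subnetwork of a gene set
#'
#' Induced subgraph on the seeds and their neighbors up to \code{order}
#' steps, with each node tagged by its shell (0 = seed, 1 = first neighbor,
#' 2 = second neighbor, ...).
#'
#' @param network an \pkg{igraph} graph.
#' @param genes seed gene ids (must be vertices).
#' @param order neighborhood order (default 2).
#' @return list with \code{graph} (induced subgraph) and \code{shell}
#'   (named integer vector).
#' @export
gene_neighborhood <- function(network, genes, order = 2L) {
  vn <- igraph::V(network)$name
  stopifnot(all(genes %in% vn))
  d <- igraph::distances(network, v = genes)
  mind <- apply(d, 2, min)
  keep <- vn[mind <= order]
  sub <- igraph::induced_subgraph(network, keep)
  shell <- setNames(as.integer(mind[keep]), keep)
  list(graph = sub, shell = shell[igraph::V(sub)$name])
}

#' Wet- and dry-season subnetworks
#'
#' Splits seed genes by the clippings of the traits they are associated
#' with (wet = clippings 2, 3, 7, 8, 9; dry = 4, 5, 6; total "T"
#' associations are not season-specific and seed neither network) and
#' rebuilds the neighborhood from each season-restricted seed set. A gene
#' may appear in both networks.
#'
#' @param network the full \pkg{igraph} graph.
#' @param gene_clippings named list: gene id -> character vector of
#'   associated clippings.
#' @param order neighborhood order (default 2).
#' @return list with \code{wet} and \code{dry} (each a
#'   \code{\link{gene_neighborhood}} result, or NULL when no seeds) and
#'   the seed sets used.
#' @export
seasonal_split <- function(network, gene_clippings, order = 2L) {
  wet_cl <- c("2", "3", "7", "8", "9")
  dry_cl <- c("4", "5", "6")
  known <- c(wet_cl, dry_cl, "T")
  all_cl <- unique(unlist(gene_clippings))
  if (length(setdiff(all_cl, known)))
    stop("unknown clipping label(s): ",
         paste(setdiff(all_cl, known), collapse = ", "))
  vn <- igraph::V(network)$name
  pick <- function(cls) {
    s <- names(gene_clippings)[vapply(gene_clippings,
                                      function(x) any(x %in% cls), logical(1))]
    intersect(s, vn)
  }
  wet_seeds <- pick(wet_cl); dry_seeds <- pick(dry_cl)
  list(wet = if (length(wet_seeds))
         gene_neighborhood(network, wet_seeds, order) else NULL,
       dry = if (length(dry_seeds))
         gene_neighborhood(network, dry_seeds, order) else NULL,
       wet_seeds = wet_seeds, dry_seeds = dry_seeds)
}

#' Degree table with outlier-based hub flags
#'
#' Degree is the number of incident edges; a gene is a hub when its degree
#' exceeds the Tukey fence Q3 + 1.5 IQR of the degree distribution. The
#' fence is reported so the empirical cutoff is visible.
#'
#' @param network an \pkg{igraph} graph (non-empty).
#' @return list with \code{degrees} (data.frame gene, degree, hub) and
#'   \code{fence}.
#' @export
degree_hubs <- function(network) {
  if (igraph::vcount(network) == 0L) stop("empty network")
  deg <- igraph::degree(network)
  qs <- quantile(deg, c(0.25, 0.75), names = FALSE)
  fence <- qs[2] + 1.5 * (qs[2] - qs[1])
  data <- data.frame(gene = names(deg), degree = as.integer(deg),
                     hub = deg > fence, stringsAsFactors = FALSE)
  data <- data[order(-data$degree, data$gene), ]
  rownames(data) <- NULL
  list(degrees = data, fence = fence)
}

#' Hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of observing at
#' least k set genes annotated to the term given K background genes
#' annotated, a set of size n and a background of size N. Terms with
#' p < \code{p_max} are returned, sorted by p.
#'
#' @param gene_set character vector (subset of \code{background}).
#' @param background character vector of all considered genes.
#' @param term_map data.frame with gene_id, term.
#' @param p_max significance cutoff (default 0.01, uncorrected).
#' @return data.frame with term, k, K, n, N, p.
#' @export
term_enrichment <- function(gene_set, background, term_map, p_max = 0.01) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  gene_set <- unique(intersect(gene_set, background))
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(gene_set)
  terms <- unique(tm$term)
  rows <- lapply(terms, function(t) {
    ann <- unique(tm$gene_id[tm$term == t])
    K <- length(ann)
    k <- length(intersect(ann, gene_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0)))
  out <- out[out$p < p_max, , drop = FALSE]
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
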