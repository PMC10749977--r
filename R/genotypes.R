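#' Pool allele frequencies from read counts
#'
#' The family-pool genotype at a marker is the ratio between the number of
#' reads for the alternative allele and the total read count. Cells with
#' depth 0 are missing, not errors.
#'
#' @param counts a \code{read_counts} object.
#' @return families x markers numeric matrix in [0, 1] with NA at depth-0
#'   cells.
#' @export
allele_frequency <- function(counts) {
  depth <- counts$ref + counts$alt
  out <- counts$alt / depth
  out[depth == 0] <- NA_real_
  out
}

#' Filter pooled markers by depth, missingness and redundancy
#'
#' Applies the marker quality filters in a fixed order: (1) cells with depth
#' below \code{min_depth} are set missing (the per-genotype convention of the
#' usual VCF filtering tools); (2) markers missing in more than
#' \code{max_missing} of families are removed; (3) markers whose
#' allele-frequency vector is identical (within 1e-12) to an
#' earlier-positioned marker are removed as redundant, keeping the first in
#' (chromosome, position) order. Biallelic screening happens in the VCF
#' reader, upstream. Imputation is strictly after all filters.
#'
#' @param counts a \code{read_counts} object.
#' @param marker_map matching marker map.
#' @param min_depth minimum per-cell depth (default 20 reads).
#' @param max_missing maximum missing fraction per marker (default 0.25).
#' @param drop_redundant remove markers duplicating an earlier frequency
#'   vector (default TRUE).
#' @param depth_mode \code{"cell"} (default) sets individual low-depth cells
#'   missing; \code{"site_mean"} instead drops whole markers whose mean depth
#'   is below the threshold.
#' @return list with \code{freqs} (filtered families x markers matrix, NAs
#'   where missing), \code{marker_map} (surviving markers) and \code{report}
#'   (per-filter removal counts).
#' @export
filter_markers <- function(counts, marker_map, min_depth = 20,
                           max_missing = 0.25, drop_redundant = TRUE,
                           depth_mode = c("cell", "site_mean")) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(identical(colnames(counts$ref), marker_map$marker_id))
  ord <- order(marker_map$chromosome, marker_map$position)
  marker_map <- marker_map[ord, , drop = FALSE]
  counts <- list(ref = counts$ref[, ord, drop = FALSE],
                 alt = counts$alt[, ord, drop = FALSE])
  depth <- counts$ref + counts$alt
  freqs <- counts$alt / depth
  freqs[depth == 0] <- NA_real_
  n_in <- ncol(freqs)

  dropped_depth_sites <- 0L
  if (depth_mode == "cell") {
    freqs[depth < min_depth] <- NA_real_
  } else {
    keep <- colMeans(depth) >= min_depth
    dropped_depth_sites <- sum(!keep)
    freqs <- freqs[, keep, drop = FALSE]
    marker_map <- marker_map[keep, , drop = FALSE]
  }

  miss_frac <- colMeans(is.na(freqs))
  keep <- miss_frac <= max_missing
  dropped_missing <- sum(!keep)
  freqs <- freqs[, keep, drop = FALSE]
  marker_map <- marker_map[keep, , drop = FALSE]

  dropped_redundant <- 0L
  if (drop_redundant && ncol(freqs) > 1L) {
    key <- apply(round(freqs, 12), 2, function(x)
      paste(ifelse(is.na(x), "NA", sprintf("%.12f", x)), collapse = ","))
    dup <- duplicated(key)  # first in genome order kept
    dropped_redundant <- sum(dup)
    freqs <- freqs[, !dup, drop = FALSE]
    marker_map <- marker_map[!dup, , drop = FALSE]
  }
  if (ncol(freqs) == 0L) stop("no markers survive filtering")
  report <- data.frame(
    step = c("input", "depth_site", "missingness", "redundant", "output"),
    markers = c(n_in, dropped_depth_sites, dropped_missing,
                dropped_redundant, ncol(freqs)))
  list(freqs = freqs, marker_map = marker_map, report = report)
}

#' Impute missing pool frequencies with the site mean
#'
#' Missing cells are replaced by the mean of the non-missing allele
#' frequencies at that marker; observed cells are untouched.
#'
#' @param freqs families x markers matrix with NAs.
#' @return matrix with no missing entries.
#' @export
impute_site_mean <- function(freqs) {
  all_missing <- colSums(!is.na(freqs)) == 0L
  if (any(all_missing))
    stop("marker(s) with all values missing: ",
         paste(head(colnames(freqs)[all_missing]), collapse = ", "),
         " (filter before imputing)")
  mu <- colMeans(freqs, na.rm = TRUE)
  idx <- which(is.na(freqs), arr.ind = TRUE)
  if (nrow(idx)) freqs[idx] <- mu[idx[, 2L]]
  freqs
}

#' Principal component analysis of the genotype matrix
#'
#' PCA on centered, unscaled allele frequencies (all entries share the [0,1]
#' scale). Component signs are fixed by making the largest-magnitude loading
#' of each component positive, so results do not depend on the eigen solver.
#'
#' @param x samples x features numeric matrix without missing values.
#' @param n_components number of components to keep.
#' @return list with \code{scores} (samples x components),
#'   \code{variance_explained} (fractions, nonincreasing) and
#'   \code{loadings}.
#' @export
pca_scores <- function(x, n_components = 2L) {
  if (anyNA(x)) stop("PCA input must not contain missing values")
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_comp)
    stop("n_components exceeds min(samples - 1, features) = ", max_comp)
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pr$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    l <- rot[, j]; sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x[, k, drop = FALSE], 2, flip, `*`)
  rot <- sweep(rot, 2, flip, `*`)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, variance_explained = ve[k], loadings = rot)
}
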