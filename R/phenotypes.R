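#' Family means of individual phenotypes
#'
#' Arithmetic mean of each trait over the available individuals of each
#' family, with the per-cell observation counts reported. Family x trait
#' combinations with no record are flagged explicitly rather than silently
#' propagated as NA.
#'
#' @param individuals long data.frame with family_id, trait, value.
#' @return list with \code{means} (families x traits matrix), \code{counts}
#'   (same shape) and \code{missing_cells} (data.frame of absent
#'   combinations, zero rows when complete).
#' @export
family_means <- function(individuals) {
  fams <- sort(unique(individuals$family_id))
  traits <- unique(individuals$trait)
  means <- counts <- matrix(NA_real_, length(fams), length(traits),
                            dimnames = list(fams, traits))
  agg_m <- tapply(individuals$value, individuals[c("family_id", "trait")], mean)
  agg_n <- tapply(individuals$value, individuals[c("family_id", "trait")], length)
  means[rownames(agg_m), colnames(agg_m)] <- agg_m
  counts[rownames(agg_n), colnames(agg_n)] <- agg_n
  counts[is.na(counts)] <- 0
  idx <- which(counts == 0, arr.ind = TRUE)
  missing_cells <- data.frame(family_id = fams[idx[, 1]],
                              trait = traits[idx[, 2]],
                              stringsAsFactors = FALSE)
  list(means = means, counts = counts, missing_cells = missing_cells)
}

#' Min-Max scale columns to [0, 1]
#'
#' Per column, x' = (x - min) / (max - min). A constant column cannot be
#' scaled; it is returned as all zeros with a warning.
#'
#' @param m numeric matrix without missing values.
#' @return matrix of the same shape with every non-constant column spanning
#'   exactly [0, 1].
#' @export
minmax_scale <- function(m) {
  if (anyNA(m)) stop("minmax_scale input must not contain missing values")
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning("constant column(s) scaled to all zeros: ",
            paste(colnames(m)[const], collapse = ", "))
    span[const] <- 1
  }
  out <- sweep(sweep(m, 2, rng[1, ]), 2, span, `/`)
  out[, const] <- 0
  out
}

#' Pearson correlations among trait columns
#'
#' @param m families x traits matrix (>= 3 families).
#' @return list with \code{r} (symmetric correlation matrix, unit diagonal)
#'   and \code{mean_offdiag} (mean of the strictly upper triangle, NA pairs
#'   from constant columns excluded).
#' @export
trait_correlations <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 families")
  const <- apply(m, 2, sd) == 0
  r <- suppressWarnings(cor(m))
  diag(r) <- 1
  if (any(const))
    warning("constant column(s) have undefined correlations: ",
            paste(colnames(m)[const], collapse = ", "))
  up <- r[upper.tri(r)]
  list(r = r, mean_offdiag = mean(up, na.rm = TRUE))
}
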