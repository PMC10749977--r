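#' Compare cross-validation scenarios with ANOVA and Tukey letters
#'
#' Repetition-level metric values of each scenario (model x dataset) are
#' compared with a one-way ANOVA followed by Tukey HSD pairwise tests, and
#' summarized as a compact letter display: scenarios sharing a letter are
#' not significantly different at \code{alpha}. Letters are assigned with
#' "a" on the highest mean and ascend toward lower means. The best-scenario
#' rule follows the metric direction: for PA (higher is better) a scenario
#' is best when its letter set contains "a"; for MSE (lower is better) when
#' it contains the last letter in use.
#'
#' If every group has zero within-group variance and all means are equal,
#' the comparison short-circuits to a single letter "a" for all scenarios.
#'
#' @param values named list of equal-length numeric vectors, one per
#'   scenario (>= 2 scenarios).
#' @param metric "PA" or "MSE"; only the best-flag direction depends on it.
#' @param alpha significance level (default 0.05).
#' @return data.frame with scenario, mean, letters, best.
#' @export
compare_scenarios <- function(values, metric = c("PA", "MSE"),
                              alpha = 0.05) {
  metric <- match.arg(metric)
  stopifnot(length(values) >= 2L, !is.null(names(values)))
  lens <- lengths(values)
  if (length(unique(lens)) != 1L)
    stop("all scenarios need the same repetition count")
  means <- vapply(values, mean, numeric(1))
  ord <- order(means, decreasing = TRUE)
  scen <- names(values)[ord]
  means <- means[ord]

  within_var <- vapply(values, var, numeric(1))
  if (all(within_var == 0) || length(unique(round(unlist(values), 15))) == 1L) {
    if (length(unique(means)) == 1L) {
      letters_out <- rep("a", length(scen))
      best <- rep(TRUE, length(scen))
      return(data.frame(scenario = scen, mean = means,
                        letters = letters_out, best = best,
                        row.names = NULL, stringsAsFactors = FALSE))
    }
  }

  d <- data.frame(value = unlist(values[scen], use.names = FALSE),
                  group = factor(rep(scen, each = lens[1]), levels = scen))
  fit <- aov(value ~ group, data = d)
  tk <- TukeyHSD(fit)$group
  q <- length(scen)
  sig <- matrix(FALSE, q, q, dimnames = list(scen, scen))
  pair_names <- rownames(tk)
  for (i in seq_len(nrow(tk))) {
    # scenario names may themselves contain "-": match against known levels
    hit <- find_pair(pair_names[i], scen)
    if (is.null(hit)) next
    s <- !is.na(tk[i, "p adj"]) && tk[i, "p adj"] < alpha
    sig[hit[1], hit[2]] <- sig[hit[2], hit[1]] <- s
  }
  letters_out <- cld_insert_absorb(sig)
  last_letter <- max(unlist(strsplit(letters_out, "")))
  best <- if (metric == "PA") grepl("a", letters_out, fixed = TRUE)
          else grepl(last_letter, letters_out, fixed = TRUE)
  data.frame(scenario = scen, mean = means, letters = letters_out,
             best = best, row.names = NULL, stringsAsFactors = FALSE)
}

# split a TukeyHSD row name "g2-g1" into the two group labels, robust to
# labels that contain "-" themselves
find_pair <- function(pair, levels) {
  for (a in levels) {
    for (b in levels) {
      if (a != b && identical(pair, paste0(a, "-", b))) return(c(a, b))
    }
  }
  NULL
}

# insert-absorb compact letter display; rows/cols of `sig` are ordered by
# decreasing group mean, TRUE = significantly different
cld_insert_absorb <- function(sig) {
  q <- nrow(sig)
  cols <- list(seq_len(q))
  for (i in seq_len(q - 1L)) {
    for (j in seq.int(i + 1L, q)) {
      if (!sig[i, j]) next
      touched <- FALSE
      new_cols <- list()
      for (cset in cols) {
        if (i %in% cset && j %in% cset) {
          touched <- TRUE
          new_cols <- c(new_cols, list(setdiff(cset, i)), list(setdiff(cset, j)))
        } else new_cols <- c(new_cols, list(cset))
      }
      if (touched) {
        # absorb: drop duplicated or subset columns
        new_cols <- new_cols[lengths(new_cols) > 0]
        keep <- rep(TRUE, length(new_cols))
        for (a in seq_along(new_cols)) {
          for (b in seq_along(new_cols)) {
            if (a != b && keep[b] &&
                all(new_cols[[a]] %in% new_cols[[b]]) &&
                (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
              keep[a] <- FALSE
              break
            }
          }
        }
        cols <- new_cols[keep]
      }
    }
  }
  # order letters by the best (lowest-index) group they contain
  first <- vapply(cols, min, numeric(1))
  cols <- cols[order(first)]
  out <- character(q)
  for (k in seq_along(cols)) {
    out[cols[[k]]] <- paste0(out[cols[[k]]], letters[k])
  }
  out
}
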