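#' Tree-ensemble feature selection on the marker matrix
#'
#' Fits one of the three tree-ensemble selectors and returns its impurity
#' importances plus the selected marker set. A marker is "selected" iff its
#' importance is strictly positive (\code{selection_rule = "positive"},
#' the default), which reproduces the characteristic set-size ordering
#' (boosting selects far fewer markers than the forests);
#' \code{"top_k"} instead keeps the \code{k} highest-importance markers.
#'
#' Methods and hyperparameters:
#' \itemize{
#'   \item \code{gbt} — gradient tree boosting: squared-error loss, learning
#'     rate 0.1, 100 boosting stages, trees capped at 3 leaf nodes
#'     (via \pkg{xgboost}, lossguide growth, no regularization terms).
#'   \item \code{extratrees} — extremely randomized trees: 100 trees, all
#'     features considered per split with one random cut each, no bootstrap
#'     (via \pkg{ranger}).
#'   \item \code{rf} — random forest: 100 trees, variance split criterion,
#'     minimum split size 2 and leaf size 1, bootstrap, no depth limit
#'     (via \pkg{ranger}).
#' }
#'
#' @param method "gbt", "extratrees" or "rf".
#' @param Z imputed families x markers matrix.
#' @param y scaled response.
#' @param seed integer seed.
#' @param selection_rule "positive" or "top_k".
#' @param k set size when \code{selection_rule = "top_k"}.
#' @return list with \code{importance} (named, >= 0, all markers) and
#'   \code{selected} (marker ids, genome order of \code{colnames(Z)}).
#' @export
fs_select <- function(method = c("gbt", "extratrees", "rf"), Z, y, seed = 1L,
                      selection_rule = c("positive", "top_k"), k = 100L) {
  method <- match.arg(method)
  selection_rule <- match.arg(selection_rule)
  if (sd(y) == 0) stop("degenerate response: y is constant")
  imp <- switch(method,
                gbt = gbt_importance(Z, y, seed),
                extratrees = {
                  spec <- list(num_trees = 100L, min_node_split = 2L,
                               min_bucket = 1L, mtry = ncol(Z))
                  fit <- ranger_fit(Z, y, spec, seed, importance = "impurity",
                                    splitrule = "extratrees", replace = FALSE)
                  setNames(fit$variable.importance, colnames(Z))
                },
                rf = {
                  spec <- list(num_trees = 100L, min_node_split = 2L,
                               min_bucket = 1L, mtry = ncol(Z))
                  fit <- ranger_fit(Z, y, spec, seed, importance = "impurity",
                                    splitrule = "variance", replace = TRUE)
                  setNames(fit$variable.importance, colnames(Z))
                })
  imp[imp < 0] <- 0
  sel <- if (selection_rule == "positive") names(imp)[imp > 0]
         else names(sort(imp, decreasing = TRUE))[seq_len(min(k, length(imp)))]
  sel <- colnames(Z)[colnames(Z) %in% sel] # genome order
  list(importance = imp, selected = sel, method = method)
}

gbt_importance <- function(Z, y, seed) {
  set.seed(seed)
  params <- list(objective = "reg:squarederror", eta = 0.1,
                 max_depth = 0L, grow_policy = "lossguide", max_leaves = 3L,
                 tree_method = "hist", lambda = 0, alpha = 0, gamma = 0,
                 subsample = 1, colsample_bytree = 1, nthread = 1L)
  fit <- xgboost::xgb.train(params = params,
                            data = xgboost::xgb.DMatrix(Z, label = y),
                            nrounds = 100L, verbose = 0)
  imp <- setNames(rep(0, ncol(Z)), colnames(Z))
  tab <- xgboost::xgb.importance(model = fit)
  if (!is.null(tab) && nrow(tab)) imp[tab$Feature] <- tab$Gain
  imp
}

#' Intersect feature-selection sets
#'
#' Markers present in at least \code{min_methods} of the three selector sets
#' (FI-1 with \code{min_methods = 2}; FI-2 with 3), returned in genome
#' order. An empty intersection is allowed and warned about.
#'
#' @param sets list of exactly 3 character vectors of marker ids.
#' @param min_methods 2 or 3.
#' @param marker_order optional marker ids giving genome order.
#' @return character vector of marker ids.
#' @export
feature_intersection <- function(sets, min_methods = 2L, marker_order = NULL) {
  stopifnot(length(sets) == 3L, min_methods %in% c(2L, 3L))
  cnt <- table(unlist(lapply(sets, unique)))
  out <- names(cnt)[cnt >= min_methods]
  if (!length(out)) warning("empty feature intersection")
  if (!is.null(marker_order)) out <- marker_order[marker_order %in% out]
  else out <- sort(out)
  out
}

#' Normalized Gini importance of a marker subset
#'
#' Random-forest impurity importances (same hyperparameters as the rf
#' selector) on the given markers, normalized to sum to 1.
#'
#' @param Z families x markers matrix restricted to the marker subset.
#' @param y response.
#' @param seed integer seed.
#' @return named importance vector summing to 1.
#' @export
gini_importance <- function(Z, y, seed = 1L) {
  stopifnot(ncol(Z) >= 1L)
  if (sd(y) == 0) stop("degenerate response: y is constant")
  if (ncol(Z) == 1L) return(setNames(1, colnames(Z)))
  spec <- list(num_trees = 100L, min_node_split = 2L, min_bucket = 1L,
               mtry = ncol(Z))
  fit <- ranger_fit(Z, y, spec, seed, importance = "impurity",
                    splitrule = "variance", replace = TRUE)
  imp <- pmax(fit$variable.importance, 0)
  tot <- sum(imp)
  if (tot <= 0) imp[] <- 1 / length(imp) else imp <- imp / tot
  setNames(imp, colnames(Z))
}

#' Major-importance marker selection
#'
#' Sorts markers by Gini importance (ties broken by genome order), takes the
#' top \code{top_n}, then keeps appending markers while the cumulative
#' importance is below \code{cum_threshold}.
#'
#' @param importance normalized importance vector (names = marker ids).
#' @param top_n base set size (default 3).
#' @param cum_threshold cumulative importance to reach (default 0.5).
#' @param marker_order optional marker ids in genome order for tie-breaking.
#' @return data.frame with marker_id and importance, in selection order.
#' @export
major_importance_selection <- function(importance, top_n = 3L,
                                       cum_threshold = 0.5,
                                       marker_order = NULL) {
  ids <- names(importance)
  if (!is.null(marker_order)) {
    pos <- match(ids, marker_order)
    o <- order(-importance, pos)
  } else o <- order(-importance, ids)
  imp <- importance[o]
  if (length(imp) < top_n) {
    warning("fewer markers than top_n: returning all")
    return(data.frame(marker_id = names(imp), importance = unname(imp),
                      stringsAsFactors = FALSE))
  }
  n_take <- top_n
  while (sum(imp[seq_len(n_take)]) < cum_threshold && n_take < length(imp))
    n_take <- n_take + 1L
  data.frame(marker_id = names(imp)[seq_len(n_take)],
             importance = unname(imp[seq_len(n_take)]),
             stringsAsFactors = FALSE)
}

#' Chromosome and trait-sharing summaries of selected marker sets
#'
#' Produces (a) per-chromosome counts and percentages (one decimal) for any
#' number of named marker sets, (b) pairwise shared-marker counts between
#' per-trait sets with clippings collapsed to the base trait, and (c) the
#' markers associated with more than one trait-clipping.
#'
#' @param sets named list of character vectors (e.g. CD, FI2, MAJOR unions).
#' @param per_trait_sets named list (trait-clipping label -> marker ids).
#' @param marker_map marker map covering every id used.
#' @return list with \code{chromosome_table}, \code{trait_pair_counts},
#'   \code{multi_trait_markers}.
#' @export
marker_set_summaries <- function(sets, per_trait_sets, marker_map) {
  all_ids <- unique(c(unlist(sets), unlist(per_trait_sets)))
  missing <- setdiff(all_ids, marker_map$marker_id)
  if (length(missing))
    stop("marker id(s) absent from map: ", paste(head(missing), collapse = ", "))
  chroms <- unique(marker_map$chromosome)
  chr_tab <- data.frame(chromosome = chroms, stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    chr_of <- marker_map$chromosome[match(sets[[nm]], marker_map$marker_id)]
    cnt <- as.integer(table(factor(chr_of, levels = chroms)))
    chr_tab[[paste0(nm, "_n")]] <- cnt
    chr_tab[[paste0(nm, "_pct")]] <- round(100 * cnt / sum(cnt), 1)
  }
  base_trait <- sub("-.*$", "", names(per_trait_sets))
  traits <- unique(base_trait)
  collapsed <- lapply(traits, function(tr)
    unique(unlist(per_trait_sets[base_trait == tr])))
  names(collapsed) <- traits
  pair <- expand.grid(trait1 = traits, trait2 = traits,
                      stringsAsFactors = FALSE)
  pair <- pair[pair$trait1 < pair$trait2, , drop = FALSE]
  pair$shared <- mapply(function(a, b)
    length(intersect(collapsed[[a]], collapsed[[b]])),
    pair$trait1, pair$trait2)
  assoc <- table(unlist(lapply(per_trait_sets, unique)))
  multi <- data.frame(marker_id = names(assoc),
                      n_trait_clippings = as.integer(assoc),
                      stringsAsFactors = FALSE)
  multi <- multi[order(-multi$n_trait_clippings, multi$marker_id), ]
  rownames(multi) <- NULL
  list(chromosome_table = chr_tab, trait_pair_counts = pair,
       multi_trait_markers = multi)
}
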