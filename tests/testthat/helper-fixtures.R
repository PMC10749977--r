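# Shared small fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# small but complete study: 50 families, 500 markers, 3 traits, strong QTLs
small_study <- function() {
  cached("small_study", function() {
    cfg <- sim_config(seed = 11, n_markers = 500, n_traits = 3, n_qtl = 5,
                      qtl_effect_sd = 2, h2_targets = c(0.8, 0.85, 0.9),
                      n_genes = 80, fraction_genes_near_qtl = 0.4,
                      duplication_rate = 0.1)
    simulate_study(cfg)
  })
}

small_geno <- function() {
  cached("small_geno", function() {
    st <- small_study()
    filt <- filter_markers(st$counts, st$marker_map)
    Z <- impute_site_mean(filt$freqs)
    Y <- minmax_scale(family_means(st$individuals)$means[rownames(Z), ])
    list(study = st, Z = Z, Y = Y, marker_map = filt$marker_map)
  })
}

# per-trait feature-selection chain on the small study
small_featsel <- function() {
  cached("small_featsel", function() {
    g <- small_geno()
    y <- g$Y[, 1]
    fs <- lapply(c("gbt", "extratrees", "rf"), function(m)
      fs_select(m, g$Z, y, seed = 21))
    sets <- lapply(fs, `[[`, "selected")
    fi1 <- feature_intersection(sets, 2L, colnames(g$Z))
    fi2 <- feature_intersection(sets, 3L, colnames(g$Z))
    gini <- gini_importance(g$Z[, fi2, drop = FALSE], y, seed = 22)
    major <- major_importance_selection(gini, marker_order = colnames(g$Z))
    list(fs = fs, sets = sets, fi1 = fi1, fi2 = fi2, gini = gini,
         major = major, y = y)
  })
}

rand_expr <- function(g, s, seed) {
  set.seed(seed)
  matrix(rexp(g * s, 0.1), g, s,
         dimnames = list(sprintf("g%03d", seq_len(g)),
                         sprintf("s%02d", seq_len(s))))
}

# reference double-loop HRR: rank by descending r, ties by gene order
brute_hrr_edges <- function(r, limit) {
  g <- nrow(r); out <- character(0)
  for (i in seq_len(g - 1)) for (j in seq.int(i + 1, g)) {
    ri <- sum(r[i, -i] > r[i, j]) + sum(r[i, -i] == r[i, j] &
                                          seq_len(g)[-i] < j) + 1
    rj <- sum(r[j, -j] > r[j, i]) + sum(r[j, -j] == r[j, i] &
                                          seq_len(g)[-j] < i) + 1
    if (max(ri, rj) <= limit)
      out <- c(out, paste(rownames(r)[i], rownames(r)[j]))
  }
  out
}

edge_keys <- function(net) {
  ed <- igraph::as_data_frame(net, "edges")
  paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
}

# distance in bp from a marker to the nearest planted QTL of a trait
min_qtl_distance <- function(marker_ids, qtl_ids, marker_map) {
  mpos <- marker_map$position[match(marker_ids, marker_map$marker_id)]
  mchr <- marker_map$chromosome[match(marker_ids, marker_map$marker_id)]
  qpos <- marker_map$position[match(qtl_ids, marker_map$marker_id)]
  qchr <- marker_map$chromosome[match(qtl_ids, marker_map$marker_id)]
  vapply(seq_along(marker_ids), function(i) {
    same <- qchr == mchr[i]
    if (!any(same)) return(Inf)
    min(abs(qpos[same] - mpos[i]))
  }, numeric(1))
}
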