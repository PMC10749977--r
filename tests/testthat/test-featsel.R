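test_that("a planted single-marker signal tops every selector", {
  for (s in 1:5) {
    set.seed(400 + s)
    Z <- matrix(runif(50 * 200), 50,
                dimnames = list(NULL, sprintf("M%03d", 1:200)))
    y <- 4 * Z[, 37] + 0.1 * rnorm(50)
    for (m in c("gbt", "extratrees", "rf")) {
      res <- fs_select(m, Z, y, seed = s)
      expect_true("M037" %in% res$selected)
      expect_equal(names(which.max(res$importance)), "M037")
    }
  }
})

test_that("boosting selects far fewer markers than the forests on noise", {
  set.seed(5)
  Z <- matrix(runif(50 * 300), 50,
              dimnames = list(NULL, sprintf("M%03d", 1:300)))
  y <- rnorm(50)
  n_gbt <- length(fs_select("gbt", Z, y, seed = 1)$selected)
  n_et <- length(fs_select("extratrees", Z, y, seed = 1)$selected)
  n_rf <- length(fs_select("rf", Z, y, seed = 1)$selected)
  expect_lt(n_gbt, n_et)
  expect_lt(n_gbt, n_rf)
})

test_that("feature intersections follow set arithmetic", {
  sets <- list(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"))
  expect_setequal(feature_intersection(sets, 2), c("B", "C"))
  expect_equal(feature_intersection(sets, 3), "C")
  expect_warning(
    out <- feature_intersection(list("A", "B", "C"), 2), "empty")
  expect_length(out, 0)
  # genome ordering honored
  expect_equal(feature_intersection(sets, 2, marker_order = c("C", "B", "A")),
               c("C", "B"))
})

test_that("Gini importances are normalized and recover a planted QTL", {
  fs <- small_featsel()
  expect_equal(sum(fs$gini), 1, tolerance = 1e-9)
  expect_true(all(fs$gini >= 0))
  expect_equal(unname(gini_importance(
    matrix(runif(50), 50, dimnames = list(NULL, "M1")), rnorm(50))), 1)

  hits <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    Z <- matrix(runif(50 * 100), 50,
                dimnames = list(NULL, sprintf("M%03d", 1:100)))
    y <- 3 * Z[, 11] + 0.3 * rnorm(50)
    g <- gini_importance(Z, y, seed = s)
    if (names(which.max(g)) == "M011") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("major-importance selection implements the top-3/cumulative-0.5 rule", {
  mk <- function(x) setNames(x, sprintf("M%02d", seq_along(x)))
  # top 3 already reach 0.5
  r1 <- major_importance_selection(mk(c(0.30, 0.20, 0.10, 0.05, 0.03)))
  expect_equal(nrow(r1), 3)
  expect_equal(sum(r1$importance), 0.60)
  # 0.45 < 0.5 -> take a fourth
  r2 <- major_importance_selection(mk(c(0.20, 0.15, 0.10, 0.08, rep(0.47 / 10, 10))))
  expect_equal(nrow(r2), 4)
  # uniform 0.1 over 10 markers -> 5 needed
  r3 <- major_importance_selection(mk(rep(0.1, 10)))
  expect_equal(nrow(r3), 5)
  # minimality: dropping the last element falls below 0.5 when size > 3
  expect_lt(sum(r2$importance[-nrow(r2)]), 0.5)
  expect_lt(sum(r3$importance[-nrow(r3)]), 0.5)
  # fewer markers than top_n returns all with a warning
  expect_warning(r4 <- major_importance_selection(mk(c(0.6, 0.4))), "fewer")
  expect_equal(nrow(r4), 2)
})

test_that("selected sets nest: MAJOR within FI-2 within FI-1", {
  fs <- small_featsel()
  union_fs <- unique(unlist(fs$sets))
  expect_true(all(fs$fi1 %in% union_fs))
  expect_true(all(fs$fi2 %in% fs$fi1))
  expect_true(all(fs$major$marker_id %in% fs$fi2))
})

test_that("marker-set summaries compute chromosome shares and associations", {
  mm <- data.frame(marker_id = sprintf("M%02d", 1:20),
                   chromosome = rep(c("chr1", "chr2"), each = 10),
                   position = rep(1:10 * 100, 2), stringsAsFactors = FALSE)
  sets <- list(CD = mm$marker_id, FI2 = c("M01", "M02", "M11"))
  per_trait <- list("GM-2" = c("M01", "M02"), "GM-3" = c("M01", "M02"),
                    "DM-2" = c("M01", "M11"))
  sm <- marker_set_summaries(sets, per_trait, mm)
  expect_equal(sm$chromosome_table$CD_pct, c(50, 50))
  expect_equal(sm$chromosome_table$FI2_n, c(2, 1))
  # identical per-trait sets share their full size
  gm_dm <- sm$trait_pair_counts$shared[
    sm$trait_pair_counts$trait1 == "DM" & sm$trait_pair_counts$trait2 == "GM"]
  expect_equal(gm_dm, 1)
  expect_equal(
    sm$multi_trait_markers$n_trait_clippings[
      sm$multi_trait_markers$marker_id == "M01"], 3)
  expect_error(marker_set_summaries(list(A = "MX"), per_trait, mm), "absent")
})

test_that("percentage arithmetic matches the benchmark tables", {
  chr <- gwfp_benchmark("marker_chromosomes")
  pct <- chromosome_percentages(setNames(chr$cd_n, chr$chromosome))
  expect_equal(pct$pct[pct$chromosome == "1"], 16.8)
  expect_lt(abs(sum(pct$pct) - 100), 0.3)
  sz <- gwfp_benchmark("set_sizes")
  ssp <- set_size_percentages(setNames(sz$mean_size, sz$set),
                              sz$mean_size[sz$set == "CD"])
  expect_equal(ssp$pct_of_cd[ssp$set == "FI-1"], 0.36)
  expect_equal(ssp$pct_of_cd[ssp$set == "FI-2"], 0.04)
})
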