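test_that("genome simulation places markers and genes consistently", {
  cfg <- sim_config(seed = 1, n_markers = 10, n_chromosomes = 2,
                    n_genes = 5, fraction_genes_near_qtl = 1,
                    module_spec = list())
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$marker_map), 10L)
  expect_false(any(duplicated(g$marker_map$marker_id)))
  expect_true(all(g$marker_map$chromosome %in% c("chr1", "chr2")))
  for (ch in unique(g$marker_map$chromosome)) {
    pos <- g$marker_map$position[g$marker_map$chromosome == ch]
    expect_true(all(diff(pos) > 0))
  }
  expect_true(all(g$genes$start <= g$genes$end))
  # every gene overlaps some QTL-pool window when the fraction is 1
  qtl <- g$marker_map[g$marker_map$marker_id %in% g$qtl_pool, ]
  overlaps <- vapply(seq_len(nrow(g$genes)), function(i) {
    w <- qtl[qtl$chromosome == g$genes$chromosome[i], ]
    any(g$genes$start[i] <= w$position + 5000 &
          g$genes$end[i] >= w$position - 5000)
  }, logical(1))
  expect_true(all(overlaps))
})

test_that("gene duplication emits the configured number of multi-copy genes", {
  cfg <- sim_config(seed = 2, n_markers = 50, n_genes = 10,
                    duplication_rate = 0.2, module_spec = list())
  g <- simulate_genome(cfg)
  copies <- table(g$genes$gene_id)
  expect_equal(sum(copies >= 2), 2L)
  expect_false(any(duplicated(paste(g$genes$gene_id, g$genes$copy_index))))
})

test_that("family frequencies follow the Beta law around founder frequencies", {
  # degenerate founder frequency propagates unchanged
  cfg0 <- sim_config(seed = 3, n_markers = 20, founder_freq_range = c(0, 0))
  g0 <- simulate_genome(cfg0)
  fr0 <- simulate_family_freqs(cfg0, g0$marker_map)
  expect_true(all(fr0$freqs == 0))

  # determinism under the seed
  cfg <- sim_config(seed = 4, n_markers = 50)
  g <- simulate_genome(cfg)
  expect_identical(simulate_family_freqs(cfg, g$marker_map),
                   simulate_family_freqs(cfg, g$marker_map))

  # Beta moments: mean of 50 family freqs around founder 0.5, conc 10:
  # SD of the mean = sqrt(0.25/11/50) ~ 0.0213, so 0.5 +/- 0.07 is ~3.3 SD
  for (s in 1:10) {
    cfgm <- sim_config(seed = 100 + s, n_markers = 30,
                       founder_freq_range = c(0.5, 0.5),
                       family_concentration = 10)
    gm <- simulate_genome(cfgm)
    fr <- simulate_family_freqs(cfgm, gm$marker_map)
    expect_true(all(abs(colMeans(fr$freqs) - 0.5) < 0.07))
  }
})

test_that("read counts follow the depth and missingness model", {
  cfg <- sim_config(seed = 5, n_markers = 2000, mean_depth = 60,
                    missing_rate = 0)
  g <- simulate_genome(cfg)
  fr <- simulate_family_freqs(cfg, g$marker_map)
  rc <- simulate_read_counts(fr$freqs, cfg)
  depth <- rc$ref + rc$alt
  expect_lt(abs(mean(depth) - 60), 2)            # LLN on 100k cells
  expect_lt(mean(depth == 0), 0.01)              # only NegBin mass at 0

  # boundary: true frequency 1 gives pure-alt reads
  f1 <- matrix(1, 5, 4, dimnames = list(paste0("F", 1:5), paste0("M", 1:4)))
  rc1 <- simulate_read_counts(f1, cfg)
  expect_true(all(rc1$ref == 0))

  # configured missingness shows up as depth-0 cells
  cfg2 <- sim_config(seed = 6, n_markers = 500, missing_rate = 0.1)
  rc2 <- simulate_read_counts(fr$freqs[, 1:500], cfg2)
  expect_equal(mean((rc2$ref + rc2$alt) == 0), 0.1, tolerance = 0.02)
})

test_that("allele-frequency estimates converge to truth with depth", {
  cfg <- sim_config(seed = 7, n_markers = 300, mean_depth = 500,
                    missing_rate = 0)
  g <- simulate_genome(cfg)
  fr <- simulate_family_freqs(cfg, g$marker_map)
  rc <- simulate_read_counts(fr$freqs, cfg)
  est <- allele_frequency(rc)
  expect_lt(mean(abs(est - fr$freqs), na.rm = TRUE), 0.02)
})

test_that("phenotype simulation hits heritability and correlation targets", {
  st <- small_study()
  G <- st$family_genetic_values

  # h2 = 1 boundary: family means equal genetic values up to the block shift
  cfg1 <- sim_config(seed = 8, n_markers = 100, n_traits = 1, n_qtl = 3,
                     h2_targets = 1, trait_corr = 1)
  g1 <- simulate_genome(cfg1)
  fr1 <- simulate_family_freqs(cfg1, g1$marker_map)
  ph1 <- simulate_phenotypes(fr1$freqs, cfg1, g1$qtl_pool)
  fm1 <- family_means(ph1$individuals)$means
  offset <- fm1[, 1] - ph1$family_genetic_values[rownames(fm1), 1]
  expect_lt(sd(offset), 1e-10)
  expect_equal(unname(ph1$ground_truth$realized_h2), 1)

  # full QTL sharing with high h2 gives strongly correlated family means
  for (s in 1:3) {
    cfg2 <- sim_config(seed = 200 + s, n_markers = 100, n_traits = 2,
                       n_qtl = 4, h2_targets = 0.9, trait_corr = 1,
                       qtl_effect_sd = 2)
    g2 <- simulate_genome(cfg2)
    fr2 <- simulate_family_freqs(cfg2, g2$marker_map)
    ph2 <- simulate_phenotypes(fr2$freqs, cfg2, g2$qtl_pool)
    fm2 <- family_means(ph2$individuals)$means
    expect_gt(cor(fm2[, 1], fm2[, 2]), 0.8)
  }

  # planted QTLs are emitted marker ids
  expect_true(all(unlist(st$ground_truth$qtl_markers) %in%
                    st$marker_map$marker_id))
})

test_that("genetic correlations increase with the sharing target", {
  mean_gen_cor <- function(rho, seed) {
    cfg <- sim_config(seed = seed, n_markers = 120, n_traits = 3, n_qtl = 5,
                      trait_corr = rho, qtl_effect_sd = 2)
    g <- simulate_genome(cfg)
    fr <- simulate_family_freqs(cfg, g$marker_map)
    ph <- simulate_phenotypes(fr$freqs, cfg, g$qtl_pool)
    trait_correlations(ph$family_genetic_values)$mean_offdiag
  }
  for (s in 1:5) {
    lo <- mean_gen_cor(0.2, 300 + s)
    mid <- mean_gen_cor(0.5, 300 + s)
    hi <- mean_gen_cor(0.9, 300 + s)
    expect_true(lo < mid && mid < hi)
  }
})

test_that("expression modules and low-expression genes are planted as configured", {
  cfg <- sim_config(seed = 9, n_markers = 100, n_genes = 60,
                    module_spec = list(list(size = 5, cor = 0.95)),
                    low_expr_frac = 0.2)
  g <- simulate_genome(cfg)
  ex <- simulate_expression(g, cfg)
  mod <- ex$modules[[1]]
  r <- cor(t(ex$tpm[mod, ]))
  expect_true(all(r[upper.tri(r)] > 0.7))

  bg <- setdiff(rownames(ex$tpm), c(mod, ex$low_expressed))
  rb <- cor(t(ex$tpm[bg, ]))
  expect_lt(mean(abs(rb[upper.tri(rb)])), 0.3)

  for (gid in ex$low_expressed)
    expect_gte(sum(ex$tpm[gid, ] <= 1), 9)
})

test_that("fixtures round-trip exactly and are byte-stable under the seed", {
  cfg <- sim_config(seed = 10, n_markers = 60, n_traits = 2, n_genes = 20)
  st <- simulate_study(cfg)
  d1 <- withr::local_tempdir()
  p1 <- write_fixtures(st, d1)

  rt <- read_vcf_counts(p1[["vcf"]])
  expect_identical(unname(rt$counts$ref), unname(st$counts$ref))
  expect_identical(unname(rt$counts$alt), unname(st$counts$alt))
  expect_identical(rt$marker_map$position, st$marker_map$position)

  tpm <- read_expression_tsv(p1[["expr"]])
  expect_identical(unname(tpm), unname(st$tpm))

  ph <- read_phenotypes_tsv(p1[["pheno"]])
  expect_identical(ph$value, st$individuals$value)

  genes <- read_gene_bed(p1[["bed"]])
  genes <- genes[order(genes$chromosome, genes$start), ]
  expect_identical(genes$start, st$genes$start)
  expect_identical(genes$end, st$genes$end)

  truth <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_setequal(unname(unlist(truth$qtl_markers)),
                  unname(unlist(st$ground_truth$qtl_markers)))

  # byte-identical rerun
  st2 <- simulate_study(cfg)
  d2 <- withr::local_tempdir()
  p2 <- write_fixtures(st2, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
})
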