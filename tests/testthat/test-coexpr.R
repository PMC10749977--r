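test_that("TPM filtering applies the strict >1-in-3 rule", {
  m <- rbind(kept = c(1.5, 1.2, 1.1, rep(0, 8)),
             boundary = rep(1.0, 11),
             two_only = c(1.5, 1.2, rep(0.5, 9)))
  colnames(m) <- sprintf("s%02d", 1:11)
  out <- tpm_filter(m)
  expect_identical(rownames(out), "kept")
})

test_that("correlation tests use the t transform on n-2 df", {
  e <- rand_expr(20, 11, 1)
  e[2, ] <- 2 * e[1, ] + 3            # collinear pair
  e[3, ] <- 5                         # constant gene
  expect_warning(ct <- correlation_tests(e), "zero-variance")
  expect_identical(ct$dropped, "g003")
  expect_equal(unname(ct$r["g001", "g002"]), 1)
  expect_lt(ct$p["g001", "g002"], 1e-12)
  # n = 11, r = 0.9: t = 6.197, p ~ 1.6e-4
  r <- 0.9; tstat <- r * 3 / sqrt(1 - r^2)
  p_exp <- 2 * pt(tstat, 9, lower.tail = FALSE)
  closest <- which.min(abs(ct$r - 0.9))
  expect_equal(tstat, 6.197, tolerance = 1e-3)
  expect_equal(p_exp, 1.6e-4, tolerance = 0.05)
  expect_equal(ct$m, choose(19, 2))
  expect_error(correlation_tests(e[, 1:2]), "3 samples")
})

test_that("HRR network equals the brute-force double-loop ranks", {
  for (s in 1:20) {
    e <- rand_expr(50, 11, 600 + s)
    ct <- correlation_tests(e)
    net <- hrr_network(ct, hrr_limit = 30)
    expect_setequal(edge_keys(net), brute_hrr_edges(ct$r, 30))
  }
})

test_that("HRR edge cases: worked example, full graph, mutual best pair", {
  rr <- diag(4); dimnames(rr) <- list(LETTERS[1:4], LETTERS[1:4])
  rr["A","B"] <- rr["B","A"] <- 0.95; rr["B","C"] <- rr["C","B"] <- 0.90
  rr["C","D"] <- rr["D","C"] <- 0.85; rr["A","C"] <- rr["C","A"] <- 0.50
  rr["B","D"] <- rr["D","B"] <- 0.20; rr["A","D"] <- rr["D","A"] <- 0.10
  corr <- list(r = rr, p = rr * 0)
  net <- hrr_network(corr, hrr_limit = 2)
  expect_setequal(edge_keys(net), c("A B", "B C", "C D"))
  # limit >= n-1 yields the complete graph
  net_full <- hrr_network(corr, hrr_limit = 3)
  expect_equal(igraph::ecount(net_full), 6)
  # a mutual-best pair has HRR 1 and survives any limit >= 1
  net1 <- hrr_network(corr, hrr_limit = 1)
  expect_setequal(edge_keys(net1), "A B")
  # monotonicity in the limit
  e <- rand_expr(30, 11, 7)
  ct <- correlation_tests(e)
  for (lim in c(2, 5, 10)) {
    expect_true(all(edge_keys(hrr_network(ct, lim)) %in%
                      edge_keys(hrr_network(ct, lim + 5))))
  }
})

test_that("seed expansion enforces both the r and adjusted-p thresholds", {
  # build a correlation structure by hand
  genes <- c("A", "X", "Y", "Z")
  r <- diag(4); dimnames(r) <- list(genes, genes)
  r["A","X"] <- r["X","A"] <- 0.95
  r["A","Y"] <- r["Y","A"] <- 0.95
  r["A","Z"] <- r["Z","A"] <- 0.89
  p <- matrix(1e-6, 4, 4, dimnames = list(genes, genes))
  m <- 6
  p["A","Y"] <- p["Y","A"] <- 0.02 / m * 2   # adjusted p = 0.04 > 0.01
  corr <- list(r = r, p = p, m = m)
  net <- hrr_network(corr, hrr_limit = 1)
  res <- expand_seed_set(net, corr, "A", r_min = 0.9, alpha = 0.01)
  expect_true("X" %in% res$added)     # r and p both pass
  expect_false("Y" %in% res$added)    # adjusted p fails
  expect_false("Z" %in% res$added)    # r below threshold
  expect_error(expand_seed_set(net, corr, character(0)), "empty seed")
  # raising r_min never adds nodes
  res_lo <- expand_seed_set(net, corr, "A", r_min = 0.85, alpha = 0.01)
  expect_true(all(res$added %in% res_lo$added))
})

test_that("neighborhoods walk the graph by shells and compose", {
  path <- igraph::make_graph(~ A - B, B - C, C - D, D - E)
  nb <- gene_neighborhood(path, "A", order = 2)
  expect_setequal(igraph::V(nb$graph)$name, c("A", "B", "C"))
  expect_equal(unname(nb$shell[c("A", "B", "C")]), c(0L, 1L, 2L))
  # order 0: seeds only
  nb0 <- gene_neighborhood(path, c("A", "C"), order = 0)
  expect_setequal(igraph::V(nb0$graph)$name, c("A", "C"))
  # star center at order 1 captures everything
  star <- igraph::make_star(8, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:8)
  nb1 <- gene_neighborhood(star, "v1", order = 1)
  expect_equal(igraph::vcount(nb1$graph), 8)
  # idempotence: N1 of N1 = N2 (node-wise)
  g <- igraph::sample_gnp(40, 0.08)
  igraph::V(g)$name <- paste0("n", 1:40)
  seeds <- c("n1", "n2")
  n1 <- gene_neighborhood(g, seeds, 1)
  n11 <- gene_neighborhood(g, igraph::V(n1$graph)$name, 1)
  n2 <- gene_neighborhood(g, seeds, 2)
  expect_setequal(igraph::V(n11$graph)$name, igraph::V(n2$graph)$name)
})

test_that("seasonal split follows the clipping-to-season mapping", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- paste0("g", 1:6)
  cl <- list(g1 = "5", g2 = c("3", "5"), g3 = "T")
  res <- seasonal_split(ring, cl, order = 1)
  expect_setequal(res$dry_seeds, c("g1", "g2"))
  expect_setequal(res$wet_seeds, "g2")
  expect_false("g3" %in% c(res$wet_seeds, res$dry_seeds))
  expect_error(seasonal_split(ring, list(g1 = "12")), "unknown clipping")
})

test_that("hub detection flags outlier degrees by the Tukey fence", {
  star <- igraph::make_star(11, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:11)
  h <- degree_hubs(star)
  expect_true(h$degrees$hub[h$degrees$gene == "v1"])
  expect_false(any(h$degrees$hub[h$degrees$gene != "v1"]))
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  expect_false(any(degree_hubs(ring)$degrees$hub))
  expect_error(degree_hubs(igraph::make_empty_graph(0)), "empty")
})

test_that("planted high-degree genes are recovered as hubs across seeds", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    # sparse background graph with one planted hub wired to 15 extra genes
    g <- igraph::sample_gnp(40, 0.05)
    igraph::V(g)$name <- paste0("n", 1:40)
    targets <- sample(2:40, 15)
    for (t in targets)
      if (!igraph::are_adjacent(g, 1, t)) g <- igraph::add_edges(g, c(1, t))
    h <- degree_hubs(g)
    if (h$degrees$hub[h$degrees$gene == "n1"]) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("planted coexpression modules gain dense HRR connectivity", {
  ok <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = 800 + s, n_markers = 50, n_genes = 60,
                      module_spec = list(list(size = 8, cor = 0.95)))
    g <- simulate_genome(cfg)
    ex <- simulate_expression(g, cfg)
    keep <- tpm_filter(ex$tpm)
    ct <- suppressWarnings(correlation_tests(keep))
    net <- hrr_network(ct, hrr_limit = 30)
    mod <- intersect(ex$modules[[1]], igraph::V(net)$name)
    sub <- igraph::induced_subgraph(net, mod)
    dens <- igraph::ecount(sub) / choose(length(mod), 2)
    if (dens >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("hypergeometric enrichment matches the closed form", {
  bg <- paste0("g", 1:20)
  tm <- rbind(data.frame(gene_id = paste0("g", 1:5), term = "T1"),
              data.frame(gene_id = paste0("g", 6:10), term = "T2"))
  res <- term_enrichment(paste0("g", 1:5), bg, tm, p_max = 0.01)
  expect_equal(res$term, "T1")
  expect_equal(res$p, choose(15, 0) / choose(20, 5) * choose(5, 5))
  # k = 0 means p = 1, never enriched
  res0 <- term_enrichment(paste0("g", 11:15), bg,
                          data.frame(gene_id = "g1", term = "T3"), p_max = 1.1)
  expect_equal(res0$p[res0$term == "T3"], 1)
  # gene set = background: every term has p = 1
  res_all <- term_enrichment(bg, bg, tm, p_max = 1.1)
  expect_true(all(res_all$p == 1))
  expect_error(term_enrichment("g1", character(0), tm), "empty background")
})
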