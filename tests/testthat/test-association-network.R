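test_that("variance decomposition centers within strata and is idempotent", {
  m <- matrix(c(1, 3, 6, 4), 4, 1)
  strata <- c("a", "a", "b", "b")
  r <- variance_decompose(m, strata)
  expect_equal(as.numeric(r), c(-1, 1, 1, -1))
  expect_equal(variance_decompose(r, strata), r)
  # single stratum is global centering; constant columns become zero
  m2 <- cbind(stats::rnorm(6), 7)
  g <- variance_decompose(m2, rep("s", 6))
  expect_equal(g[, 1], m2[, 1] - mean(m2[, 1]))
  expect_equal(g[, 2], rep(0, 6))
  expect_error(variance_decompose(m, c("a", "a", "a", "b")), "singleton")
})

test_that("feature preparation filters taxa, transforms blocks and centers
          every stratum", {
  meta <- generate_metadata(3, 23, 1)
  pair <- generate_paired_taxa_gene(meta, seed = 4)
  # add an all-zero taxon and a rare taxon at exactly the boundary
  tc <- cbind(pair$taxa_counts, absent = 0L)
  blk <- prepare_features(tc, pair$expr_counts, meta)
  expect_false("absent" %in% colnames(blk$X))
  expect_equal(ncol(blk$X), 15)
  expect_equal(ncol(blk$Y), 43)
  for (s in levels(blk$strata)) {
    rows <- blk$strata == s
    expect_lt(max(abs(colMeans(blk$X[rows, , drop = FALSE]))), 1e-9)
    expect_lt(max(abs(colMeans(blk$Y[rows, , drop = FALSE]))), 1e-9)
  }
  expect_error(prepare_features(pair$taxa_counts[1:3, ],
                                pair$expr_counts[, 4:6], meta),
               "no shared samples")
})

test_that("the abundance filter is strict at the printed boundary", {
  meta <- generate_metadata(2, 23, 1)
  n <- nrow(meta)
  # taxon 2 sits at exactly 0.01% mean relative abundance: excluded
  tc <- cbind(a = rep(9990L, n), b = rep(10L, n), c = rep(90000L, n))
  rownames(tc) <- meta$sample_id
  ec <- matrix(50L, 5, n, dimnames = list(paste0("g", 1:5), meta$sample_id))
  blk <- suppressWarnings(prepare_features(tc, ec, meta,
                                           min_rel_abund = 1e-4))
  expect_false("b" %in% colnames(blk$X))
  expect_true(all(c("a", "c") %in% colnames(blk$X)))
})

test_that("sPLS reduces to exact regression on noise-free toys", {
  x <- matrix(c(1, -2, 3, 0.5, -1, 2), ncol = 1)
  blk <- list(X = x, Y = 2 * x)
  fit <- spls_fit(blk, lambda = 0)
  expect_equal(as.numeric(fit$coefficients), 2, tolerance = 1e-8)
  # full shrinkage zeroes everything
  fit1 <- spls_fit(blk, lambda = 1)
  expect_true(all(fit1$coefficients == 0))
  expect_true(all(!fit1$support))
  # lambda = 0 with K = full rank reproduces least-squares predictions
  set.seed(5)
  X <- matrix(stats::rnorm(30), 10, 3)
  B0 <- matrix(c(1, 0, -2, 0.5, 3, 0), 3, 2)
  Y <- X %*% B0
  fit2 <- spls_fit(list(X = X, Y = Y), lambda = 0, K = ncol(X))
  expect_lt(max(abs(X %*% fit2$coefficients - Y)), 1e-6)
  expect_error(spls_fit(list(X = X * 0, Y = Y), 0), "all-zero")
})

test_that("support size shrinks as lambda grows", {
  blk <- toy_block(p = 6, q = 8, seed = 12)
  sizes <- vapply(seq(0, 0.9, by = 0.1),
                  function(l) sum(spls_fit(blk, l)$support), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 48)  # dense at lambda 0
})

test_that("StARS instability is bounded, monotonized and selects a sparse
          model on null data", {
  blk <- toy_block(p = 5, q = 6, seed = 13)
  st <- stars_select(blk, lambda_grid = seq(0.9, 0.1, by = -0.2),
                     n_subsamples = 20, seed = 13)
  expect_true(all(st$instability >= 0 & st$instability <= 0.5))
  expect_true(all(diff(st$instability_monotone) >= 0))
  # densest lambda meeting the bound is selected; when no lambda meets it
  # the sparsest model is the fallback
  ok <- which(st$instability_monotone <= st$beta)
  expect_equal(st$selected_index, if (length(ok) > 0) max(ok) else 1L)
  expect_error(stars_select(blk, lambda_grid = 0.5), ">= 2 values")
  expect_error(stars_select(blk, lambda_grid = c(0.1, 0.5)), "decreasing")
})

test_that("bootstrap significance hits the p-value floor on noise-free
          planted edges and returns p = 1 for zero coefficients", {
  meta <- generate_metadata(4, 23, 1)
  pair <- generate_paired_taxa_gene(meta, n_taxa = 4, n_genes = 5,
                                    n_true_edges = 4, noise_sd = 0,
                                    stratum_sd = 0, seed = 6)
  # use the latent blocks: the exported counts pass through clr, which
  # removes one dimension and leaves a coefficient direction unidentified
  strata <- interaction(meta$sex, meta$treatment, drop = TRUE)
  blk <- list(X = variance_decompose(pair$truth$latent_taxa, strata),
              Y = variance_decompose(pair$truth$latent_genes, strata),
              strata = strata)
  fit <- spls_fit(blk, lambda = 0, K = ncol(blk$X))  # full rank: exact fit
  edges <- bootstrap_significance(blk, fit, B = 150, seed = 7)
  truth <- pair$truth$edges
  on_true <- mapply(function(t, g) truth[t, g], edges$taxon, edges$gene)
  expect_equal(edges$empirical_p[on_true], rep(1 / 151, sum(on_true)),
               tolerance = 1e-12)
  # a support edge whose observed coefficient is exactly zero gets p = 1
  fit0 <- fit
  fit0$coefficients[edges$taxon[1], edges$gene[1]] <- 0
  e0 <- bootstrap_significance(blk, fit0, B = 100, seed = 8)
  expect_equal(e0$empirical_p[e0$taxon == edges$taxon[1] &
                                e0$gene == edges$gene[1]], 1)
  expect_error(bootstrap_significance(blk, fit, B = 50), ">= 100")
})

test_that("the bipartite network carries node and edge annotation and a
          deterministic GraphML serialization", {
  meta <- generate_metadata(3, 23, 1)
  pair <- generate_paired_taxa_gene(meta, seed = 9)
  genes <- colnames(pair$truth$beta)
  # 31 edges on 31 distinct genes of 43: coverage fraction 31/43
  edges <- data.frame(taxon = rep(colnames(pair$taxa_counts)[1], 31),
                      gene = genes[1:31], coefficient = 0.5, sign = "+",
                      empirical_p = 0.001, q = 0.01, selected = TRUE,
                      significant = TRUE)
  g <- build_network(edges, pair$taxa_counts, pair$taxonomy, genes = genes)
  expect_equal(igraph::graph_attr(g, "gene_coverage"), 31 / 43)
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::ecount(g), 31)
  expect_equal(unique(igraph::E(g)$width), 3)
  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".graphml")
  igraph::write_graph(g, f1, format = "graphml")
  igraph::write_graph(g, f2, format = "graphml")
  expect_identical(readLines(f1), readLines(f2))
  # empty edge list keeps declared isolated nodes
  g0 <- build_network(edges[0, ], pair$taxa_counts, pair$taxonomy,
                      genes = genes)
  expect_equal(igraph::vcount(g0), 15 + 43)
  expect_equal(igraph::ecount(g0), 0)
  bad <- edges; bad$taxon <- "nope"
  expect_error(build_network(bad, pair$taxa_counts, genes = genes),
               "unknown nodes")
})
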