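test_that("metadata generator builds the full crossed design
          deterministically", {
  meta <- generate_metadata(3, c(12, 42), seed = 1)
  expect_equal(nrow(meta), 24)
  expect_equal(length(unique(meta$mouse_id)), 12)
  expect_equal(nrow(generate_metadata(6, c(21, 35, 49))), 72)
  expect_identical(meta, generate_metadata(3, c(12, 42), seed = 1))
  # each mouse keeps constant sex and treatment
  by_mouse <- split(meta[c("sex", "treatment")], meta$mouse_id)
  expect_true(all(vapply(by_mouse, function(d) nrow(unique(d)) == 1,
                         logical(1))))
  expect_error(generate_metadata(0, 12), ">= 1")
})

test_that("taxa counts respect depth, determinism and the null
          configuration", {
  meta <- generate_metadata(3, 21, 1)
  tx <- generate_taxa_counts(meta, n_taxa = 50, depth = 5000, seed = 9)
  expect_true(all(rowSums(tx$counts) == 5000))
  expect_identical(tx$counts,
                   generate_taxa_counts(meta, n_taxa = 50, depth = 5000,
                                        seed = 9)$counts)
  null <- generate_taxa_counts(meta, n_taxa = 50, log2_effect = 0, seed = 9)
  expect_equal(null$truth$baseline, null$truth$pat_proportions)
})

test_that("planted taxa shifts reach the configured fold-change on
          average", {
  lfc <- sapply(1:20, function(sd) {
    meta <- generate_metadata(10, 21, sd)
    tx <- generate_taxa_counts(meta, seed = sd)
    rel <- tx$counts / rowSums(tx$counts)
    up <- tx$truth$up_taxa
    pat <- meta$treatment == "PAT"
    mean(log2(colMeans(rel[pat, up, drop = FALSE]) /
              colMeans(rel[!pat, up, drop = FALSE])))
  })
  expect_lt(abs(mean(lfc) - 2), 0.3)
})

test_that("expression generator plants class-specific timepoint shifts", {
  meta <- generate_metadata(8, c(12, 42), 1)
  ex <- generate_expression(meta, seed = 5)
  expect_identical(ex$counts, generate_expression(meta, seed = 5)$counts)
  expect_error(generate_expression(meta, class_counts = c(bogus = 3)),
               "unknown maturation class")
  # class-III genes shift in both arms with the planted sign
  lfc_by_arm <- function(counts, meta, arm, gene) {
    sel <- meta$treatment == arm
    sub <- meta[sel, ]
    lg <- log2(counts[gene, sub$sample_id] + 1)
    mean(lg[sub$day == 42]) - mean(lg[sub$day == 12])
  }
  lfcs <- sapply(1:20, function(sd) {
    ex <- generate_expression(meta, seed = sd)
    g3 <- ex$truth[ex$truth$class == "III", ][1, ]
    c(lfc_by_arm(ex$counts, meta, "control", g3$gene) * g3$sign,
      lfc_by_arm(ex$counts, meta, "PAT", g3$gene) * g3$sign)
  })
  expect_lt(abs(mean(lfcs[1, ]) - 2), 0.4)
  expect_lt(abs(mean(lfcs[2, ]) - 2), 0.4)
  # all-null configuration leaves every expected mean static
  ex0 <- generate_expression(meta, class_counts = c(III = 0), seed = 5)
  expect_true(all(ex0$truth$class == "NC"))
})

test_that("BGC reference honours the planted homology structure", {
  ref <- generate_bgc_reference(12, n_homology_groups = 3, seed = 2)
  sets <- strsplit(ref$orf_families, ";")
  jac <- function(i, j) {
    length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  for (i in 1:11) for (j in (i + 1):12) {
    if (ref$group[i] == ref$group[j]) expect_gte(jac(i, j), 0.8)
    else expect_lte(jac(i, j), 0.2)
  }
  # all-singleton construction: everything dissimilar
  solo <- generate_bgc_reference(5, n_homology_groups = 5, seed = 2)
  s2 <- strsplit(solo$orf_families, ";")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lte(length(intersect(s2[[i]], s2[[j]])), 0.2 *
                 length(union(s2[[i]], s2[[j]])))
  }
  t0 <- proc.time()[["elapsed"]]
  big <- generate_bgc_reference(228, seed = 3)
  expect_equal(nrow(big), 228)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
  expect_error(generate_bgc_reference(2, n_homology_groups = 3), "n_bgcs")
})

test_that("read-coverage simulator clips at the BGC end and covers nothing
          with no reads", {
  expect_equal(simulate_read_coverage(1000, 0, 100)$covered_bases, 0)
  full <- simulate_read_coverage(500, 3, 600, seed = 1)
  expect_equal(full$covered_bases, 500)
  obs <- simulate_read_coverage(10000, 50, 100, seed = 7)
  expect_identical(obs, simulate_read_coverage(10000, 50, 100, seed = 7))
  expect_lte(obs$covered_bases, 50 * 100)
  expect_error(simulate_read_coverage(1000, 10, 0), "read_len")
})

test_that("paired generator plants the requested sparse linear structure", {
  meta <- generate_metadata(3, 23, 1)
  none <- generate_paired_taxa_gene(meta, n_true_edges = 0, seed = 1)
  expect_true(all(none$truth$beta == 0))
  exact <- generate_paired_taxa_gene(meta, noise_sd = 0, stratum_sd = 0,
                                     seed = 2)
  expect_equal(exact$truth$latent_genes,
               exact$truth$latent_taxa %*% exact$truth$beta,
               tolerance = 1e-12)
  expect_error(generate_paired_taxa_gene(meta, n_taxa = 2, n_genes = 2,
                                         n_true_edges = 5), "exceed")
  pair <- generate_paired_taxa_gene(meta, seed = 3)
  expect_true(all(rowSums(pair$taxa_counts) == 50000))
  expect_equal(sum(pair$truth$beta != 0), 25)
})
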