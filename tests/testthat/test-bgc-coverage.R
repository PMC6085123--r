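test_that("expected coverage follows the Lander-Waterman closed form and its
          monotonicities", {
  expect_equal(expected_coverage(0, 100, 1000), 0)
  expect_equal(expected_coverage(100, 100, 10000), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(expected_coverage(500, 150, 25000), 1 - exp(-3),
               tolerance = 1e-12)
  N <- 1:50
  E <- expected_coverage(N, 100, 10000)
  expect_true(all(diff(E) > 0))
  expect_true(all(E >= 0 & E < 1))
  expect_true(all(diff(expected_coverage(10, c(50, 100, 200), 10000)) > 0))
  expect_true(all(diff(expected_coverage(10, 100, c(5000, 10000, 20000))) < 0))
  expect_error(expected_coverage(-1, 100, 1000), "non-negative")
})

test_that("coverage ratio relates breadth to the expectation, with r = 0 for
          absent BGCs", {
  expect_equal(coverage_ratio(0, 0, 150, 25000), 0)
  E <- expected_coverage(500, 150, 25000)
  expect_equal(coverage_ratio(E * 25000, 500, 150, 25000), 1,
               tolerance = 1e-12)
  expect_equal(coverage_ratio(17000, 500, 150, 25000), 0.68 / E,
               tolerance = 1e-6)
  expect_error(coverage_ratio(30000, 10, 100, 25000), "L_BGC")
})

test_that("presence calling uses an inclusive threshold and imputes missing
          pairs as absent", {
  bgcs <- data.frame(bgc_id = c("B1", "B2"), length_bp = c(25000L, 10000L))
  E1 <- expected_coverage(500, 150, 25000)
  obs <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    bgc_id = c("B1", "B2", "B1"),
    n_reads = c(500L, 100L, 500L),
    read_len = c(150L, 100L, 150L),
    covered_bases = c(as.integer(ceiling(0.75 * E1 * 25000)),  # r = 0.75
                      0L, 17000L))                             # r ~ 0.716
  pres <- call_presence(obs, bgcs)
  expect_true(pres["s1", "B1"])     # boundary r = 0.75 is present
  expect_false(pres["s2", "B1"])    # r = 0.7156 below threshold
  expect_false(pres["s1", "B2"])
  expect_false(pres["s2", "B2"])    # missing pair imputed absent
  expect_equal(attr(pres, "n_imputed_zero"), 1)
  # monotone: more covered bases can only turn presence on
  obs2 <- obs
  obs2$covered_bases[3] <- 25000L
  expect_true(call_presence(obs2, bgcs)["s2", "B1"])
  expect_error(call_presence(data.frame(sample_id = "s1", bgc_id = "BX",
                                        n_reads = 1L, read_len = 10L,
                                        covered_bases = 5L), bgcs),
               "unknown BGCs: BX")
})

test_that("group enrichment reproduces the exact Fisher example and flags
          direction at q < 0.15", {
  meta <- generate_metadata(3, 21, 1)  # 6 PAT, 6 control
  pres <- matrix(FALSE, 12, 1, dimnames = list(meta$sample_id, "B1"))
  pres[meta$treatment == "PAT", 1] <- TRUE
  enr <- bgc_enrichment(pres, meta)
  expect_equal(enr$p, 2 / choose(12, 6), tolerance = 1e-9)
  expect_equal(enr$q, enr$p)
  expect_equal(enr$enriched_in, "PAT")
  expect_equal(enr$odds_ratio, Inf)
  # identical frequencies in both arms: p = 1, no call; degenerate all-present
  # BGC still tested with p = 1
  pres2 <- cbind(B1 = meta$sex == "F", B2 = rep(TRUE, 12))
  rownames(pres2) <- meta$sample_id
  enr2 <- bgc_enrichment(pres2, meta)
  expect_equal(enr2$p, c(1, 1))
  expect_equal(enr2$enriched_in, c("none", "none"))
  expect_error(bgc_enrichment(pres[meta$treatment == "PAT", , drop = FALSE],
                              meta), "two treatment levels")
})

test_that("enrichment on planted presence patterns recovers the enriched set
          and label permutation controls false positives", {
  set.seed(11)
  meta <- generate_metadata(6, 21, 1)  # 12 per arm
  n_bgc <- 100; planted <- sprintf("B%03d", 1:10)
  ids <- sprintf("B%03d", 1:n_bgc)
  pat <- meta$treatment == "PAT"
  recall <- fdp <- numeric(5)
  for (sd in 1:5) {
    set.seed(sd)
    pres <- sapply(ids, function(b) {
      pp <- if (b %in% planted) ifelse(pat, 0.95, 0.05) else 0.4
      stats::runif(nrow(meta)) < pp
    })
    rownames(pres) <- meta$sample_id
    enr <- bgc_enrichment(pres, meta)
    hits <- enr$bgc_id[enr$enriched_in == "PAT"]
    recall[sd] <- mean(planted %in% hits)
    fdp[sd] <- if (length(hits) > 0) mean(!hits %in% planted) else 0
  }
  expect_gte(mean(recall), 0.9)
  expect_lte(mean(fdp), 0.15)
  # permuting treatment labels should leave ~no calls beyond the FDR level
  set.seed(99)
  pres <- sapply(ids, function(b) stats::runif(nrow(meta)) < 0.4)
  rownames(pres) <- meta$sample_id
  fp <- replicate(20, {
    meta_perm <- meta
    meta_perm$treatment <- sample(meta$treatment)
    sum(bgc_enrichment(pres, meta_perm)$enriched_in != "none")
  })
  expect_lte(mean(fp / n_bgc), 0.15)
})

test_that("homology clustering groups identical sets, splits disjoint sets,
          and recovers planted groups at threshold 0.5", {
  ref <- data.frame(bgc_id = c("A", "B", "C"),
                    orf_families = c("x;y;z", "x;y;z", "p;q"))
  cl <- cluster_bgcs(ref, threshold = 0.9)
  expect_equal(cl$cluster_id[1], cl$cluster_id[2])
  expect_false(cl$cluster_id[1] == cl$cluster_id[3])
  disj <- data.frame(bgc_id = c("A", "B", "C"),
                     orf_families = c("a;b", "c;d", "e;f"))
  expect_equal(length(unique(cluster_bgcs(disj, threshold = 0.1)$cluster_id)),
               3)
  ref3 <- generate_bgc_reference(30, n_homology_groups = 3, seed = 4)
  cl3 <- cluster_bgcs(ref3, threshold = 0.5)
  expect_equal(length(unique(cl3$cluster_id)), 3)
  # planted groups map one-to-one onto recovered clusters
  expect_equal(length(unique(paste(ref3$group[match(cl3$bgc_id, ref3$bgc_id)],
                                   cl3$cluster_id))), 3)
  expect_error(cluster_bgcs(ref, similarity = matrix(1, 2, 2)), "square")
})
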