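# random 2x2 table with total at most `max_total`
random_table <- function(max_total = 40) {
  repeat {
    tab <- matrix(stats::rbinom(4, size = max_total %/% 4, prob = 0.5), 2, 2)
    if (sum(tab) > 0 && sum(tab) <= max_total) return(tab)
  }
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test:
# probabilities from choose(), summed over all tables with the observed
# margins whose probability does not exceed the observed one
fisher_enumeration_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc; total <- m + n
  if (m == 0 || n == 0 || k == 0 || k == total) return(1)
  denom <- choose(total, k)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / denom
  p_obs <- choose(m, a) * choose(n, k - a) / denom
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small paired-data feature block for association tests
toy_block <- function(n_per_stratum = 6, p = 4, q = 5, seed = 1) {
  set.seed(seed)
  n <- 4 * n_per_stratum
  strata <- factor(rep(c("F.ctl", "F.pat", "M.ctl", "M.pat"),
                       each = n_per_stratum))
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("t", seq_len(p))))
  Y <- matrix(stats::rnorm(n * q), n, q,
              dimnames = list(NULL, paste0("g", seq_len(q))))
  list(X = variance_decompose(X, strata),
       Y = variance_decompose(Y, strata), strata = strata)
}

# full association pipeline on one synthetic seed; returns precision/recall
# of the significant edge set against the planted truth
run_network_recovery <- function(seed, n_true_edges = 25, B = 500) {
  meta <- generate_metadata(12, 23, 1)
  pair <- generate_paired_taxa_gene(meta, n_true_edges = n_true_edges,
                                    seed = seed)
  blk <- prepare_features(pair$taxa_counts, pair$expr_counts, meta)
  st <- stars_select(blk, seed = seed + 1000)
  fit <- spls_fit(blk, st$selected_lambda, K = st$K)
  edges <- bootstrap_significance(blk, fit, B = B, seed = seed + 2000)
  sig <- edges[edges$significant, , drop = FALSE]
  truth <- pair$truth$edges
  pred <- matrix(FALSE, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  if (nrow(sig) > 0) pred[cbind(sig$taxon, sig$gene)] <- TRUE
  list(precision = if (sum(pred) > 0) sum(pred & truth) / sum(pred) else NA,
       recall = if (sum(truth) > 0) sum(pred & truth) / sum(truth) else NA,
       n_support = sum(fit$support), n_significant = nrow(sig),
       edges = edges, block = blk, fit = fit, truth = truth)
}
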