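#' Lander-Waterman expected coverage probability
#'
#' Probability that a given base of a reference of length `L_BGC` is covered
#' by at least one of `N` uniformly placed reads of length `L_read`:
#' `E = 1 - exp(-N * L_read / L_BGC)`.
#'
#' Note: a widely circulated rendering of this formula omits the minus sign
#' in the exponent, which would yield negative "probabilities"; the correct
#' Lander-Waterman sign is used here.
#'
#' @param N Number of aligned reads (>= 0); vectorized.
#' @param L_read Read length in bp (>= 1).
#' @param L_BGC Reference (BGC) length in bp (>= 1).
#' @return Expected coverage probability in `[0, 1)`.
#' @examples
#' expected_coverage(100, 100, 10000)  # 1 - exp(-1)
#' @export
expected_coverage <- function(N, L_read, L_BGC) {
  if (any(N < 0)) stop("N must be non-negative", call. = FALSE)
  if (any(L_read < 1) || any(L_BGC < 1)) {
    stop("L_read and L_BGC must be >= 1", call. = FALSE)
  }
  1 - exp(-as.numeric(N) * L_read / L_BGC)
}

#' Ratio of actual to expected coverage
#'
#' Actual coverage is the breadth `C / L_BGC` (fraction of BGC bases covered
#' at >= 1x); expected coverage comes from [expected_coverage()]. With no
#' reads the expected coverage is 0 and the ratio is defined as 0, so that
#' zero-coverage observations always map to absence.
#'
#' @param C Covered bases (breadth numerator), `0 <= C <= L_BGC`; vectorized.
#' @param N Number of aligned reads.
#' @param L_read Read length in bp.
#' @param L_BGC BGC length in bp.
#' @return Non-negative coverage ratio (1 means observed breadth equals the
#'   Lander-Waterman expectation).
#' @export
coverage_ratio <- function(C, N, L_read, L_BGC) {
  if (any(C < 0) || any(C > L_BGC)) {
    stop("covered bases C must lie in [0, L_BGC]", call. = FALSE)
  }
  E <- expected_coverage(N, L_read, L_BGC)
  ifelse(E == 0, 0, (C / L_BGC) / E)
}

#' Call BGC presence per sample from coverage observations
#'
#' A BGC is called present in a sample when the ratio of actual to expected
#' coverage is at least `min_ratio` (inclusive). Missing (sample, BGC) pairs
#' are treated as zero-coverage, hence absent; the number of imputed pairs is
#' recorded.
#'
#' @param observations Data.frame with columns `sample_id`, `bgc_id`,
#'   `n_reads`, `read_len`, `covered_bases`.
#' @param bgcs BGC reference data.frame with columns `bgc_id`, `length_bp`.
#' @param min_ratio Presence threshold on the coverage ratio; default 0.75.
#' @param samples Optional character vector fixing the sample universe
#'   (defaults to the samples seen in `observations`).
#' @return Logical matrix samples x BGCs with attributes `min_ratio` and
#'   `n_imputed_zero` (number of missing pairs treated as absent).
#' @export
call_presence <- function(observations, bgcs, min_ratio = 0.75,
                          samples = NULL) {
  if (!is.numeric(min_ratio) || min_ratio <= 0) {
    stop("min_ratio must be positive", call. = FALSE)
  }
  unknown <- setdiff(unique(observations$bgc_id), bgcs$bgc_id)
  if (length(unknown) > 0) {
    stop("coverage observations reference unknown BGCs: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(samples)) samples <- sort(unique(observations$sample_id))
  pres <- matrix(FALSE, length(samples), nrow(bgcs),
                 dimnames = list(samples, bgcs$bgc_id))
  if (nrow(observations) > 0) {
    L <- bgcs$length_bp[match(observations$bgc_id, bgcs$bgc_id)]
    bad <- observations$covered_bases > L
    if (any(bad)) {
      stop("covered_bases exceeds BGC length for ",
           sum(bad), " observation(s)", call. = FALSE)
    }
    r <- coverage_ratio(observations$covered_bases, observations$n_reads,
                        observations$read_len, L)
    keep <- observations$sample_id %in% samples
    pres[cbind(observations$sample_id[keep], observations$bgc_id[keep])] <-
      r[keep] >= min_ratio
  }
  attr(pres, "min_ratio") <- min_ratio
  attr(pres, "n_imputed_zero") <- length(samples) * nrow(bgcs) -
    sum(observations$sample_id %in% samples)
  pres
}

#' Treatment-group enrichment of BGC presence
#'
#' For every BGC, builds the 2x2 table of treatment group versus
#' presence/absence across samples, computes a two-sided Fisher exact
#' p-value, adjusts across all tested BGCs by Benjamini-Hochberg, and labels
#' the group in which the BGC is over-represented when `q < q_threshold`.
#' BGCs present in zero or all samples are still tested (their p is 1), so
#' the multiplicity accounting is reproducible.
#'
#' @param presence Logical matrix samples x BGCs from [call_presence()].
#' @param meta Sample metadata with `sample_id` and `treatment` (exactly two
#'   levels among the presence-matrix samples).
#' @param q_threshold FDR threshold for calling enrichment; default 0.15.
#' @return Data.frame with one row per BGC: counts `a` (group1 present),
#'   `b` (group1 absent), `c` (group2 present), `d` (group2 absent),
#'   `odds_ratio`, `p`, `q`, `enriched_in`.
#' @export
bgc_enrichment <- function(presence, meta, q_threshold = 0.15) {
  idx <- match(rownames(presence), meta$sample_id)
  if (any(is.na(idx))) {
    stop("presence matrix contains samples absent from metadata", call. = FALSE)
  }
  treatment <- meta$treatment[idx]
  levels <- sort(unique(treatment))
  # report the treated group first: "control" (or any reference-sounding
  # level) goes last, independent of locale collation
  if ("control" %in% levels) {
    levels <- c(setdiff(levels, "control"), "control")
  }
  if (length(levels) != 2) {
    stop("exactly two treatment levels are required, got: ",
         paste(unique(treatment), collapse = ", "), call. = FALSE)
  }
  g1 <- treatment == levels[1]
  res <- lapply(colnames(presence), function(b) {
    pr <- presence[, b]
    a <- sum(pr & g1); bb <- sum(!pr & g1)
    cc <- sum(pr & !g1); d <- sum(!pr & !g1)
    tab <- rbind(c(a, bb), c(cc, d))
    p <- fisher_exact_two_sided(tab)
    or <- if (bb * cc == 0) {
      if (a * d == 0) NaN else Inf
    } else (a * d) / (bb * cc)
    data.frame(bgc_id = b, a = a, b = bb, c = cc, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  f1 <- res$a / (res$a + res$b)
  f2 <- res$c / (res$c + res$d)
  res$enriched_in <- ifelse(res$q < q_threshold & f1 > f2, levels[1],
                     ifelse(res$q < q_threshold & f2 > f1, levels[2], "none"))
  attr(res, "q_threshold") <- q_threshold
  attr(res, "group_levels") <- levels
  res
}

# Jaccard similarity matrix between ORF-family sets
orf_jaccard <- function(orf_sets) {
  n <- length(orf_sets)
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(orf_sets[[i]], orf_sets[[j]]))
      uni <- length(union(orf_sets[[i]], orf_sets[[j]]))
      sim[i, j] <- sim[j, i] <- if (uni == 0) 0 else inter / uni
    }
  }
  sim
}

#' Collapse BGCs into homology clusters
#'
#' Average-linkage agglomerative clustering of BGCs on a similarity matrix --
#' by default the Jaccard index of their ORF-family sets, optionally a
#' user-supplied (e.g. amino-acid identity) matrix. Clusters are cut so that
#' merges happen while the average-linkage similarity is at least
#' `threshold`. BGCs are processed in lexicographic id order, which fixes
#' tie-breaking.
#'
#' @param bgcs BGC reference data.frame with `bgc_id` and `orf_families`
#'   (semicolon-joined ORF family labels).
#' @param similarity Optional symmetric similarity matrix in `[0, 1]`
#'   (rows/cols in the order of `bgcs$bgc_id` after sorting).
#' @param threshold Similarity threshold in `[0, 1]`; default 0.5.
#' @param linkage Only `"average"` is supported.
#' @return Data.frame `bgc_id`, `cluster_id` with attributes `threshold` and
#'   `linkage`.
#' @export
cluster_bgcs <- function(bgcs, similarity = NULL, threshold = 0.5,
                         linkage = "average") {
  linkage <- match.arg(linkage, "average")
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(bgcs$bgc_id)
  bgcs <- bgcs[ord, , drop = FALSE]
  n <- nrow(bgcs)
  if (is.null(similarity)) {
    sets <- strsplit(bgcs$orf_families, ";", fixed = TRUE)
    similarity <- orf_jaccard(sets)
  } else {
    similarity <- as.matrix(similarity)
    if (nrow(similarity) != n || ncol(similarity) != n) {
      stop("similarity matrix must be square with one row per BGC",
           call. = FALSE)
    }
    if (max(abs(similarity - t(similarity))) > 1e-8) {
      stop("similarity matrix must be symmetric", call. = FALSE)
    }
    similarity <- similarity[ord, ord, drop = FALSE]
  }
  if (n == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
    cl <- stats::cutree(hc, h = 1 - threshold)
  }
  out <- data.frame(bgc_id = bgcs$bgc_id,
                    cluster_id = sprintf("cluster_%03d", cl),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "linkage") <- linkage
  out
}
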