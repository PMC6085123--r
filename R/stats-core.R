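#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided p-value by the probability-mass method: the
#' sum of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table. A
#' relative tolerance of `1e-7` is used when comparing table probabilities,
#' so that floating-point ties are counted as ties.
#'
#' @param tab A 2x2 matrix (or something coercible to one, e.g.
#'   `rbind(c(a, b), c(c, d))`) of non-negative integer counts. Rows index the
#'   group (e.g. treatment arm), columns the outcome (present/absent).
#' @return The two-sided p-value, a number in `[0, 1]`.
#' @examples
#' fisher_exact_two_sided(rbind(c(6, 0), c(0, 6)))  # 2 / choose(12, 6)
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- validate_contingency(tab)
  m <- tab[1, 1] + tab[1, 2]   # row 1 total
  n <- tab[2, 1] + tab[2, 2]   # row 2 total
  k <- tab[1, 1] + tab[2, 1]   # column 1 total
  if (m == 0L || n == 0L || k == 0L || k == m + n) {
    return(1)
  }
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

validate_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) {
    stop("contingency table must be 2x2", call. = FALSE)
  }
  if (any(is.na(tab)) || any(tab < 0)) {
    stop("contingency table entries must be non-negative counts", call. = FALSE)
  }
  if (any(abs(tab - round(tab)) > 1e-8)) {
    stop("contingency table entries must be integers", call. = FALSE)
  }
  if (sum(tab) == 0) {
    stop("contingency table must contain at least one positive count",
         call. = FALSE)
  }
  storage.mode(tab) <- "integer"
  tab
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' Thin, validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#' Returned q-values preserve the order of the input p-values and are clipped
#' to 1.
#'
#' @param p Numeric vector of p-values, all in `[0, 1]`.
#' @return Numeric vector of BH-adjusted q-values, same length and names as
#'   `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must all lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Centered log-ratio transform of a composition
#'
#' Maps a vector of non-negative abundances to clr coordinates:
#' `log(x_i) - mean_j log(x_j)`. When the vector contains zeros, a pseudocount
#' is first added to every entry (to all entries, so that ratios between
#' non-zero parts are perturbed symmetrically); zero-free vectors are
#' transformed exactly.
#'
#' @param x Non-negative numeric vector, length >= 2.
#' @param pseudocount Positive value added to every entry when any entry is
#'   zero. Default 0.5.
#' @return Numeric vector of clr coordinates; sums to zero.
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (length(x) < 2) stop("composition must have length >= 2", call. = FALSE)
  if (any(is.na(x)) || any(x < 0)) {
    stop("composition entries must be non-negative", call. = FALSE)
  }
  if (all(x == 0)) stop("all-zero composition cannot be clr-transformed",
                        call. = FALSE)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive", call. = FALSE)
  }
  if (any(x == 0)) x <- x + pseudocount
  lx <- log(x)
  lx - mean(lx)
}

#' Median-of-ratios normalization of a count matrix
#'
#' Computes per-sample size factors as the median, over reference genes, of
#' the ratio of the gene's count to its across-sample geometric mean.
#' Reference genes are those with a non-zero count in every sample. Size
#' factors are then rescaled to have geometric mean 1, and counts are divided
#' by them. This is a deterministic median-of-ratios scheme of the kind used
#' for sequencing-depth correction of count matrices.
#'
#' @param counts Non-negative numeric matrix, genes x samples, >= 2 samples.
#' @return A list with `size_factors` (length = number of samples) and
#'   `normalized` (matrix of the same shape as `counts`).
#' @export
median_ratio_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  usable <- rowSums(counts == 0) == 0
  if (!any(usable)) {
    stop(paste("no gene has non-zero counts in every sample;",
               "add a pseudocount before normalizing"), call. = FALSE)
  }
  ref <- counts[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))  # center to geometric mean 1
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Welch two-sample test on log-scale values
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom, two-sided
#' p-value, and the direction of the shift from group A to group B. When both
#' groups are exactly constant the test degenerates: p = 1 for equal means,
#' p = 0 otherwise.
#'
#' @param a,b Numeric vectors (log-normalized values), each of length >= 2.
#' @return A list with `t`, `df`, `p`, and `direction` (`"up"` if
#'   mean(b) > mean(a), `"down"` if lower, `"none"` if equal).
#' @export
welch_log_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  delta <- mb - ma
  direction <- if (delta > 0) "up" else if (delta < 0) "down" else "none"
  if (se2 == 0) {
    return(list(t = if (delta == 0) 0 else sign(delta) * Inf,
                df = na + nb - 2,
                p = if (delta == 0) 1 else 0,
                direction = direction))
  }
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df),
       direction = direction)
}

#' Bootstrap/resampling empirical p-value
#'
#' Two-sided empirical p-value of an observed statistic against a vector of
#' null draws, with the +1 correction that keeps the estimate positive:
#' `p = (1 + #{|null| >= |observed|}) / (B + 1)`.
#'
#' @param observed Observed statistic (scalar).
#' @param null_draws Numeric vector of draws from the null distribution.
#' @return Empirical p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_draws) {
  if (length(null_draws) < 1) stop("need at least one null draw", call. = FALSE)
  if (length(observed) != 1 || is.na(observed)) {
    stop("observed must be a single number", call. = FALSE)
  }
  (1 + sum(abs(null_draws) >= abs(observed))) / (length(null_draws) + 1)
}
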