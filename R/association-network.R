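#' Within-stratum centering (two-factor variance decomposition)
#'
#' Removes the stratum mean of every column within each stratum (e.g. the
#' sex x treatment cells of the design), retaining the within-stratum
#' variation that association inference should operate on.
#'
#' @param M Numeric matrix, samples x features.
#' @param strata Factor (or vector) of stratum labels, one per row.
#' @return Residual matrix of the same shape; per-stratum column means are 0.
#' @export
variance_decompose <- function(M, strata) {
  M <- as.matrix(M)
  strata <- as.factor(strata)
  if (length(strata) != nrow(M)) {
    stop("one stratum label per row is required", call. = FALSE)
  }
  tab <- table(strata)
  if (any(tab < 2)) {
    stop("every stratum needs >= 2 samples; singleton strata: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  for (s in levels(strata)) {
    rows <- strata == s
    M[rows, ] <- sweep(M[rows, , drop = FALSE], 2,
                       colMeans(M[rows, , drop = FALSE]))
  }
  M
}

#' Prepare aligned taxa and expression feature blocks for association
#' inference
#'
#' Filters taxa, applies the compositional and expression transforms, and
#' removes between-stratum (sex x treatment) variation from both blocks:
#' taxa with overall mean relative abundance <= `min_rel_abund` (strictly
#' greater is kept) or absent from every sample are dropped; retained taxa
#' counts are clr-transformed per sample; expression counts are
#' median-of-ratios normalized and log2(x + 1) transformed; both blocks are
#' then centered within each stratum.
#'
#' @param taxa_counts Samples x taxa count matrix (rownames = sample ids).
#' @param expr_counts Genes x samples count matrix.
#' @param meta Sample metadata (`sample_id`, `sex`, `treatment`).
#' @param min_rel_abund Strict lower bound on mean relative abundance;
#'   default `1e-4` (0.01%).
#' @return A list of class `"feature_block"`: `X` (samples x taxa residuals),
#'   `Y` (samples x genes residuals), `strata`, `sample_ids`,
#'   `mean_rel_abund` (of retained taxa).
#' @export
prepare_features <- function(taxa_counts, expr_counts, meta,
                             min_rel_abund = 1e-4) {
  shared <- intersect(rownames(taxa_counts), colnames(expr_counts))
  shared <- intersect(shared, meta$sample_id)
  if (length(shared) == 0) {
    stop("no shared samples between taxa, expression and metadata",
         call. = FALSE)
  }
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  tc <- taxa_counts[shared, , drop = FALSE]
  ec <- expr_counts[, shared, drop = FALSE]

  rel <- tc / rowSums(tc)
  keep <- colMeans(rel) > min_rel_abund & colSums(tc) > 0
  if (!any(keep)) stop("no taxa pass the abundance filter", call. = FALSE)
  tc <- tc[, keep, drop = FALSE]

  X <- t(apply(tc, 1, clr_transform))
  dimnames(X) <- dimnames(tc)
  Y <- t(log2(median_ratio_normalize(ec)$normalized + 1))

  strata <- interaction(meta$sex, meta$treatment, drop = TRUE)
  out <- list(X = variance_decompose(X, strata),
              Y = variance_decompose(Y, strata),
              strata = strata, sample_ids = shared,
              mean_rel_abund = colMeans(rel)[keep])
  class(out) <- "feature_block"
  out
}

# soft-threshold a weight vector at a fraction lambda of its largest entry
soft_threshold <- function(w, lambda) {
  sign(w) * pmax(abs(w) - lambda * max(abs(w)), 0)
}

# penalized rank-1 factor of M by alternating soft-thresholding, started at
# the leading singular-vector pair; returns unit-norm sparse u, v (all-zero
# when lambda shrinks every entry away)
penalized_rank1 <- function(M, u0, v0, lambda, max_iter = 100, tol = 1e-6) {
  u <- u0; v <- v0
  for (it in seq_len(max_iter)) {
    u_new <- soft_threshold(M %*% v, lambda)
    if (all(u_new == 0)) return(list(u = as.numeric(u_new), v = v * 0))
    u_new <- u_new / sqrt(sum(u_new^2))
    v_new <- soft_threshold(crossprod(M, u_new), lambda)
    if (all(v_new == 0)) return(list(u = as.numeric(u_new),
                                     v = as.numeric(v_new)))
    v_new <- v_new / sqrt(sum(v_new^2))
    done <- max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol
    u <- as.numeric(u_new); v <- as.numeric(v_new)
    if (done) break
  }
  list(u = u, v = v)
}

# Moore-Penrose pseudoinverse via SVD (guards rank-deficient K x K systems)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Sparse partial least squares regression between two blocks
#'
#' Fits a sparse PLS model of `Y` on `X` by iterative deflation. Each
#' component is a penalized rank-1 approximation of the current
#' cross-covariance matrix, obtained by alternating soft-thresholding of the
#' weight vectors (initialized at the leading singular-vector pair and
#' iterated to convergence): `u <- S(M v)`, `v <- S(M' u)`, each
#' soft-thresholded at `lambda * max(|weight|)` and renormalized. `lambda`
#' is therefore a sparsity fraction in `[0, 1]`: `lambda = 0` recovers the
#' plain singular vectors (dense PLS), `lambda >= 1` zeroes every weight.
#' Blocks are deflated by the component scores; the coefficient matrix maps
#' X to Y through the retained components, and its nonzero pattern (the
#' support) is the union over components of selected taxa times selected
#' genes, so sparsity acts at the taxon-gene edge level.
#'
#' @param block A `"feature_block"` from [prepare_features()], or a list with
#'   numeric matrices `X` and `Y` (equal row counts).
#' @param lambda Sparsity level in `[0, 1]`.
#' @param K Number of latent components; default (`NULL`) uses the number of
#'   singular values of the cross-covariance exceeding `1e-8` times the
#'   largest.
#' @return An object of class `"spls_model"`: `coefficients` (taxa x genes),
#'   `support` (logical matrix, nonzero pattern), `K`, `lambda`, `weights`
#'   (X-weight matrix).
#' @export
spls_fit <- function(block, lambda, K = NULL) {
  X <- as.matrix(block$X); Y <- as.matrix(block$Y)
  if (nrow(X) != nrow(Y)) stop("X and Y need equal row counts", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 samples", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (all(X == 0) || all(Y == 0)) {
    stop("all-zero block cannot be fitted", call. = FALSE)
  }
  p <- ncol(X); q <- ncol(Y)
  M0 <- crossprod(X, Y)
  d0 <- svd(M0, nu = 0, nv = 0)$d
  if (is.null(K)) K <- max(1L, sum(d0 > 1e-8 * max(d0)))

  W <- matrix(0, p, 0); P <- matrix(0, p, 0)
  C <- matrix(0, q, 0); V <- matrix(0, q, 0)
  Xk <- X; Yk <- Y
  for (k in seq_len(K)) {
    M <- crossprod(Xk, Yk)
    if (max(abs(M)) < 1e-12) break
    s <- svd(M, nu = 1, nv = 1)
    uv <- penalized_rank1(M, s$u[, 1], s$v[, 1], lambda)
    u <- uv$u; v <- uv$v
    if (all(u == 0) || all(v == 0)) break
    tt <- Xk %*% u
    ss <- sum(tt^2)
    if (ss < 1e-12) break
    pk <- crossprod(Xk, tt) / ss
    ck <- crossprod(Yk, tt) / ss
    Xk <- Xk - tt %*% t(pk)
    Yk <- Yk - tt %*% t(ck)
    W <- cbind(W, u); P <- cbind(P, pk); C <- cbind(C, ck)
    V <- cbind(V, v)
  }
  if (ncol(W) == 0) {
    B <- matrix(0, p, q)
    support <- matrix(FALSE, p, q)
  } else {
    B <- W %*% pinv(crossprod(P, W)) %*% t(C)
    support <- matrix(FALSE, p, q)
    for (k in seq_len(ncol(W))) {
      support <- support | outer(W[, k] != 0, V[, k] != 0)
    }
    B[!support] <- 0
  }
  dimnames(B) <- list(colnames(X), colnames(Y))
  dimnames(support) <- dimnames(B)
  out <- list(coefficients = B, support = support,
              K = K, n_components = ncol(W), lambda = lambda, weights = W)
  class(out) <- "spls_model"
  out
}

# stratified subsample (without replacement) or bootstrap resample (with)
stratified_rows <- function(strata, size_frac = NULL, replace = FALSE) {
  idx <- integer(0)
  for (s in levels(strata)) {
    rows <- which(strata == s)
    k <- if (replace) length(rows) else max(2L, round(size_frac * length(rows)))
    k <- min(k, length(rows))
    idx <- c(idx, sample(rows, k, replace = replace))
  }
  idx
}

#' StARS stability selection of the sPLS sparsity level
#'
#' Repeatedly refits the sparse PLS model on stratified subsamples drawn
#' without replacement (subsample size `min(floor(10 * sqrt(n)), 0.8 n)`) and
#' records, for every candidate `lambda` and every taxon-gene edge, the
#' frequency `theta` with which the edge enters the support. The edgewise
#' instability `D(lambda) = mean(2 * theta * (1 - theta))` is monotonized by
#' a running supremum from the sparsest end of the grid, and the selected
#' `lambda` is the densest (smallest) one whose monotonized instability is
#' at most `beta` -- i.e. StARS maximizes density subject to bounded
#' instability.
#'
#' @param block A `"feature_block"` (or list with `X`, `Y`, `strata`).
#' @param lambda_grid Decreasing vector of candidate sparsity levels
#'   (length >= 2).
#' @param n_subsamples Number of subsamples; default 50.
#' @param beta Instability threshold; default 0.05.
#' @param seed Integer seed.
#' @param K Number of components passed to [spls_fit()] (default: computed
#'   once on the full block).
#' @return A list of class `"stars_result"`: `lambda_grid`, `instability`,
#'   `instability_monotone`, `selected_lambda`, `selected_index`, `theta`
#'   (list of edge-frequency matrices), `beta`, `subsample_size`.
#' @export
stars_select <- function(block, lambda_grid = seq(0.95, 0.05, by = -0.05),
                         n_subsamples = 50, beta = 0.05, seed = 1L,
                         K = NULL) {
  if (length(lambda_grid) < 2) {
    stop("lambda grid needs >= 2 values", call. = FALSE)
  }
  if (is.unsorted(rev(lambda_grid), strictly = TRUE)) {
    stop("lambda grid must be sorted decreasing", call. = FALSE)
  }
  if (n_subsamples < 2) stop("need >= 2 subsamples", call. = FALSE)
  strata <- as.factor(block$strata)
  n <- nrow(block$X)
  b <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  frac <- b / n
  if (is.null(K)) {
    d0 <- svd(crossprod(block$X, block$Y), nu = 0, nv = 0)$d
    K <- max(1L, sum(d0 > 1e-8 * max(d0)))
  }
  set.seed(seed)
  p <- ncol(block$X); q <- ncol(block$Y)
  counts <- lapply(lambda_grid, function(l) matrix(0, p, q))
  for (s in seq_len(n_subsamples)) {
    rows <- stratified_rows(strata, size_frac = frac, replace = FALSE)
    sub <- list(X = variance_decompose(block$X[rows, , drop = FALSE],
                                       strata[rows]),
                Y = variance_decompose(block$Y[rows, , drop = FALSE],
                                       strata[rows]))
    for (i in seq_along(lambda_grid)) {
      fit <- spls_fit(sub, lambda_grid[i], K = K)
      counts[[i]] <- counts[[i]] + fit$support
    }
  }
  theta <- lapply(counts, function(ct) ct / n_subsamples)
  D <- vapply(theta, function(th) mean(2 * th * (1 - th)), numeric(1))
  Dbar <- cummax(D)  # running supremum from the sparsest (largest-lambda) end
  ok <- which(Dbar <= beta)
  sel <- if (length(ok) > 0) max(ok) else 1L
  out <- list(lambda_grid = lambda_grid, instability = D,
              instability_monotone = Dbar,
              selected_lambda = lambda_grid[sel], selected_index = sel,
              theta = theta, beta = beta, subsample_size = b, K = K)
  class(out) <- "stars_result"
  out
}

#' Bootstrap empirical significance of StARS-selected associations
#'
#' Refits the sPLS model at the selected sparsity level on `B` stratified
#' bootstrap resamples (rows resampled with replacement within each
#' stratum). For every edge in the selected support the bootstrap
#' coefficient distribution, recentred at zero by subtracting its bootstrap
#' mean, serves as the null reference; the two-sided empirical p-value of
#' the observed coefficient is computed with the +1 correction and adjusted
#' across support edges by Benjamini-Hochberg.
#'
#' @param block A `"feature_block"`.
#' @param model A fitted `"spls_model"` (on `block`).
#' @param B Number of bootstrap resamples (>= 100); default 5000.
#' @param alpha FDR threshold on q; default 0.05.
#' @param seed Integer seed.
#' @return Data.frame of class `"association_edges"`, one row per support
#'   edge: `taxon`, `gene`, `coefficient`, `sign`, `empirical_p`, `q`,
#'   `selected`, `significant`.
#' @export
bootstrap_significance <- function(block, model, B = 5000, alpha = 0.05,
                                   seed = 1L) {
  if (B < 100) stop("B must be >= 100 for a usable p-value floor",
                    call. = FALSE)
  strata <- as.factor(block$strata)
  sup <- which(model$support)
  if (length(sup) == 0) {
    out <- data.frame(taxon = character(0), gene = character(0),
                      coefficient = numeric(0), sign = character(0),
                      empirical_p = numeric(0), q = numeric(0),
                      selected = logical(0), significant = logical(0))
    class(out) <- c("association_edges", class(out))
    return(out)
  }
  set.seed(seed)
  boot <- matrix(NA_real_, B, length(sup))
  for (bb in seq_len(B)) {
    rows <- stratified_rows(strata, replace = TRUE)
    sub <- list(X = variance_decompose(block$X[rows, , drop = FALSE],
                                       strata[rows]),
                Y = variance_decompose(block$Y[rows, , drop = FALSE],
                                       strata[rows]))
    fit <- spls_fit(sub, model$lambda, K = model$K)
    boot[bb, ] <- fit$coefficients[sup]
  }
  centred <- sweep(boot, 2, colMeans(boot))
  obs <- model$coefficients[sup]
  pvals <- vapply(seq_along(sup), function(j) {
    if (obs[j] == 0) 1 else empirical_pvalue(obs[j], centred[, j])
  }, numeric(1))
  q <- bh_fdr(pvals)
  rc <- arrayInd(sup, dim(model$coefficients))
  out <- data.frame(
    taxon = rownames(model$coefficients)[rc[, 1]],
    gene = colnames(model$coefficients)[rc[, 2]],
    coefficient = obs,
    sign = ifelse(obs >= 0, "+", "-"),
    empirical_p = pvals, q = q,
    selected = TRUE, significant = q < alpha,
    stringsAsFactors = FALSE)
  class(out) <- c("association_edges", class(out))
  out
}

#' Build the bipartite taxa-gene association network
#'
#' Assembles significant (or all supplied) edges into a bipartite igraph
#' object. Taxon nodes carry mean relative abundance and family annotation;
#' edges carry coefficient, sign, empirical p, q, and a width attribute
#' `-log10(empirical_p)`.
#'
#' @param edges An `"association_edges"` data.frame (typically filtered to
#'   `significant` rows).
#' @param taxa_counts Samples x taxa count matrix (for mean relative
#'   abundance).
#' @param taxonomy Optional data.frame `taxon`, `family`.
#' @param genes Character vector of all candidate genes (for the gene
#'   coverage fraction; defaults to the genes present in `edges`).
#' @return An igraph graph with graph attribute `gene_coverage` = fraction
#'   of candidate genes touched by at least one edge.
#' @export
build_network <- function(edges, taxa_counts, taxonomy = NULL, genes = NULL) {
  taxa <- colnames(taxa_counts)
  if (is.null(genes)) genes <- sort(unique(edges$gene))
  bad_t <- setdiff(unique(edges$taxon), taxa)
  bad_g <- setdiff(unique(edges$gene), genes)
  if (length(bad_t) > 0 || length(bad_g) > 0) {
    stop("edges reference unknown nodes: ",
         paste(c(bad_t, bad_g), collapse = ", "), call. = FALSE)
  }
  rel <- taxa_counts / rowSums(taxa_counts)
  mra <- colMeans(rel)
  fam <- if (is.null(taxonomy)) rep(NA_character_, length(taxa)) else
    taxonomy$family[match(taxa, taxonomy$taxon)]

  nodes <- data.frame(
    name = c(taxa, genes),
    type = c(rep(FALSE, length(taxa)), rep(TRUE, length(genes))),
    node_class = c(rep("taxon", length(taxa)), rep("gene", length(genes))),
    mean_rel_abund = c(mra, rep(NA_real_, length(genes))),
    family = c(fam, rep(NA_character_, length(genes))),
    stringsAsFactors = FALSE)
  el <- data.frame(from = edges$taxon, to = edges$gene,
                   coefficient = edges$coefficient, sign = edges$sign,
                   empirical_p = edges$empirical_p, q = edges$q,
                   width = -log10(edges$empirical_p),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "gene_coverage",
                              length(unique(edges$gene)) / length(genes))
  g
}
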