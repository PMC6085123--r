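#' Per-gene maturation test within one treatment arm
#'
#' Tests every gene for a change in expression between two postnatal
#' timepoints within a single arm: counts are median-of-ratios normalized
#' across the arm's samples, log2(x + 1) transformed, compared by a Welch
#' two-sample test, and adjusted across genes by Benjamini-Hochberg. The
#' reported direction is gated on significance: it is `"none"` unless
#' `q < alpha`.
#'
#' @param expr Count matrix, genes x samples.
#' @param meta Sample metadata (`sample_id`, `treatment`, `day`).
#' @param arm Treatment arm to analyse (a level of `meta$treatment`).
#' @param t0,t1 The two postnatal days compared (t1 vs t0).
#' @param alpha Significance level on the BH-adjusted q; default 0.05.
#' @return Data.frame with one row per gene: `gene`, `arm`, `log2fc`
#'   (mean log2 difference, t1 minus t0), `p`, `q`, `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @export
maturation_test <- function(expr, meta, arm, t0, t1, alpha = 0.05) {
  if (t0 == t1) stop("t0 and t1 must differ", call. = FALSE)
  sel <- meta$treatment == arm & meta$day %in% c(t0, t1)
  sub <- meta[sel, , drop = FALSE]
  for (d in c(t0, t1)) {
    if (sum(sub$day == d) < 2) {
      stop(sprintf("need >= 2 samples in arm '%s' at day %s", arm, d),
           call. = FALSE)
    }
  }
  m <- expr[, sub$sample_id, drop = FALSE]
  logm <- log2(median_ratio_normalize(m)$normalized + 1)
  i0 <- sub$day == t0
  i1 <- sub$day == t1
  res <- lapply(seq_len(nrow(logm)), function(g) {
    w <- welch_log_test(logm[g, i0], logm[g, i1])
    data.frame(gene = rownames(logm)[g], arm = arm,
               log2fc = mean(logm[g, i1]) - mean(logm[g, i0]),
               p = w$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res$direction <- ifelse(res$q < alpha,
                          ifelse(res$log2fc > 0, "up", "down"), "none")
  res
}

#' Classify per-gene maturation across the control and PAT arms
#'
#' Combines per-arm maturation calls into the five-class scheme for
#' developmental gene-expression maturation under a perturbation:
#' \describe{
#'   \item{III}{both arms significant, same direction (maturation resistant
#'     to the perturbation)}
#'   \item{IV}{both arms significant, opposite directions (maturation
#'     altered)}
#'   \item{I_only}{significant in the control arm only (maturation lost
#'     under the perturbation)}
#'   \item{V}{significant in the PAT arm only (dysmaturation)}
#'   \item{NC}{no significant change in either arm}
#' }
#' The marginal views are also reported: `marginal_I` (gene matures in
#' control, i.e. classes I_only/III/IV) and `marginal_II` (gene matures in
#' PAT, i.e. classes III/IV/V).
#'
#' @param control,pat Per-gene results from [maturation_test()] for the two
#'   arms (same genes, any order).
#' @return Data.frame with `gene`, per-arm `log2fc`/`q`/`direction`,
#'   `primary_class`, `marginal_I`, `marginal_II`.
#' @export
classify_maturation <- function(control, pat) {
  if (!setequal(control$gene, pat$gene)) {
    stop("control and PAT results must cover the same genes", call. = FALSE)
  }
  pat <- pat[match(control$gene, pat$gene), , drop = FALSE]
  sc <- control$direction != "none"
  sp <- pat$direction != "none"
  primary <- ifelse(sc & sp & control$direction == pat$direction, "III",
             ifelse(sc & sp, "IV",
             ifelse(sc, "I_only",
             ifelse(sp, "V", "NC"))))
  data.frame(gene = control$gene,
             control_log2fc = control$log2fc, control_q = control$q,
             control_direction = control$direction,
             pat_log2fc = pat$log2fc, pat_q = pat$q,
             pat_direction = pat$direction,
             primary_class = primary,
             marginal_I = sc, marginal_II = sp,
             stringsAsFactors = FALSE)
}

#' Summarize maturation calls
#'
#' @param calls Data.frame from [classify_maturation()].
#' @return A list with `class_counts` (named counts over I_only/III/IV/V/NC),
#'   `marginal_I`, `marginal_II`, and `directions` (up/down counts per arm
#'   among significant genes).
#' @export
summarize_classes <- function(calls) {
  if (nrow(calls) == 0) stop("no maturation calls to summarize", call. = FALSE)
  classes <- c("I_only", "III", "IV", "V", "NC")
  cc <- vapply(classes, function(k) sum(calls$primary_class == k), integer(1))
  list(class_counts = cc,
       marginal_I = sum(calls$marginal_I),
       marginal_II = sum(calls$marginal_II),
       directions = list(
         control = table(factor(calls$control_direction[calls$marginal_I],
                                levels = c("up", "down"))),
         pat = table(factor(calls$pat_direction[calls$marginal_II],
                            levels = c("up", "down")))),
       total = nrow(calls))
}

#' Pathway over-representation of a gene class
#'
#' For each pathway, builds the 2x2 table of class membership versus pathway
#' membership over the gene universe, computes a two-sided Fisher exact
#' p-value and BH-adjusts across pathways.
#'
#' @param class_genes Character vector of genes in the class (subset of
#'   `universe`).
#' @param sets Named list of pathway gene vectors, or a collection from
#'   [read_gmt()].
#' @param universe Character vector of all genes tested. If `sets` comes from
#'   [read_gmt()] and `universe` is missing, its recorded universe is used.
#' @param alpha Significance level on q; default 0.05.
#' @return Data.frame `pathway`, `overlap`, `class_size`, `pathway_size`,
#'   `p`, `q`, `significant`.
#' @export
pathway_enrichment <- function(class_genes, sets, universe = NULL,
                               alpha = 0.05) {
  if (is.list(sets) && !is.null(sets$sets)) {
    if (is.null(universe)) universe <- sets$universe
    sets <- sets$sets
  }
  if (is.null(universe)) stop("a gene universe is required", call. = FALSE)
  universe <- unique(universe)
  outside <- setdiff(class_genes, universe)
  if (length(outside) > 0) {
    stop("class genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  class_genes <- unique(class_genes)
  res <- lapply(names(sets), function(pw) {
    pws <- intersect(unique(sets[[pw]]), universe)
    a <- length(intersect(class_genes, pws))
    b <- length(class_genes) - a
    cc <- length(pws) - a
    d <- length(universe) - a - b - cc
    data.frame(pathway = pw, overlap = a,
               class_size = length(class_genes), pathway_size = length(pws),
               p = fisher_exact_two_sided(rbind(c(a, b), c(cc, d))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < alpha
  res
}
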