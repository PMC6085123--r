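#' Generate a fully crossed longitudinal sample design
#'
#' Builds a sample metadata table for a 2 (sex) x 2 (treatment) design with
#' `n_mice_per_cell` mice per cell and one sample per mouse per timepoint,
#' mirroring the design of an early-life antibiotic-perturbation mouse study.
#'
#' @param n_mice_per_cell Number of mice in each sex x treatment cell.
#' @param timepoints Integer vector of postnatal days sampled (e.g.
#'   `c(12, 42)`).
#' @param seed Integer seed (kept for interface symmetry; the design is
#'   deterministic).
#' @return A data.frame with columns `sample_id`, `mouse_id`, `sex`
#'   (`"M"`/`"F"`), `treatment` (`"PAT"`/`"control"`), `day`.
#' @export
generate_metadata <- function(n_mice_per_cell, timepoints, seed = 1L) {
  if (n_mice_per_cell < 1) stop("n_mice_per_cell must be >= 1", call. = FALSE)
  if (length(timepoints) == 0) stop("timepoints must be non-empty", call. = FALSE)
  cells <- expand.grid(sex = c("F", "M"), treatment = c("control", "PAT"),
                       idx = seq_len(n_mice_per_cell),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$sex, cells$treatment, cells$idx), ]
  mouse_id <- sprintf("m_%s_%s_%02d", cells$sex,
                      ifelse(cells$treatment == "PAT", "pat", "ctl"), cells$idx)
  out <- do.call(rbind, lapply(sort(unique(as.integer(timepoints))), function(d) {
    data.frame(sample_id = sprintf("%s_P%02d", mouse_id, d),
               mouse_id = mouse_id, sex = cells$sex,
               treatment = cells$treatment, day = d,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate an overdispersed compositional taxa count table
#'
#' Draws per-sample counts from a Dirichlet-multinomial around log-normal
#' baseline proportions. In PAT samples the expected relative abundance of
#' `n_up` planted taxa is multiplied by `2^log2_effect` and that of `n_down`
#' taxa divided by it, then renormalized, emulating the handful of over- and
#' under-represented taxa an early-life antibiotic pulse induces.
#'
#' @param meta Metadata from [generate_metadata()].
#' @param n_taxa Number of taxa.
#' @param n_up,n_down Numbers of planted over-/under-represented taxa in PAT.
#' @param log2_effect Planted log2 fold-change of relative abundance.
#' @param depth Exact per-sample read depth (row sum).
#' @param overdispersion Dirichlet overdispersion; the Dirichlet concentration
#'   is `1/overdispersion` (0 gives plain multinomial sampling).
#' @param seed Integer seed.
#' @return A list with `counts` (samples x taxa integer matrix, rownames =
#'   sample ids, colnames = taxon labels), `taxonomy` (data.frame taxon,
#'   family), and `truth` (planted up/down taxa and parameters).
#' @export
generate_taxa_counts <- function(meta, n_taxa = 200, n_up = 4, n_down = 4,
                                 log2_effect = 2, depth = 50000,
                                 overdispersion = 0.02, seed = 1L) {
  if (n_up + n_down > n_taxa) stop("n_up + n_down must be <= n_taxa", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (log2_effect < 0) stop("log2_effect must be non-negative", call. = FALSE)
  set.seed(seed)
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  family <- sprintf("family_%02d", 1 + (seq_len(n_taxa) - 1) %% 12)
  base <- exp(stats::rnorm(n_taxa, 0, 1.5))
  p0 <- base / sum(base)
  # plant effects on detectable taxa (above-median baseline abundance), as
  # differentially represented genera in such studies are; very rare taxa
  # would yield zero counts in whole arms and an unmeasurable fold-change
  eligible <- which(p0 > stats::median(p0))
  planted <- sample(eligible, n_up + n_down)
  up <- planted[seq_len(n_up)]
  down <- planted[n_up + seq_len(n_down)]
  p_pat <- p0
  p_pat[up] <- p_pat[up] * 2^log2_effect
  p_pat[down] <- p_pat[down] / 2^log2_effect
  p_pat <- p_pat / sum(p_pat)

  counts <- matrix(0L, nrow = nrow(meta), ncol = n_taxa,
                   dimnames = list(meta$sample_id, taxa))
  for (i in seq_len(nrow(meta))) {
    p <- if (meta$treatment[i] == "PAT") p_pat else p0
    if (overdispersion > 0) {
      w <- stats::rgamma(n_taxa, shape = p / overdispersion)
      if (sum(w) == 0) w <- p
      p <- w / sum(w)
    }
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, p))
  }
  list(counts = counts,
       taxonomy = data.frame(taxon = taxa, family = family,
                             stringsAsFactors = FALSE),
       truth = list(up_taxa = taxa[up], down_taxa = taxa[down],
                    log2_effect = log2_effect, baseline = p0,
                    pat_proportions = p_pat, seed = seed,
                    overdispersion = overdispersion, depth = depth))
}

maturation_class_labels <- c("I_only", "III", "IV", "V")

#' Simulate a two-timepoint expression count matrix with planted maturation
#'
#' Negative-binomial counts around log-normal baseline means. Each planted
#' gene's mean shifts between the earlier and later timepoint by
#' `+/- log2_effect` (sign random per gene) in the arm(s) its class
#' prescribes: `I_only` shifts in the control arm only, `III` in both arms
#' with the same sign, `IV` in both arms with opposite signs, `V` in the PAT
#' arm only. All remaining genes are static.
#'
#' @param meta Metadata with exactly two timepoints per arm.
#' @param n_genes Total number of genes.
#' @param class_counts Named integer vector over
#'   `c("I_only", "III", "IV", "V")`.
#' @param log2_effect Planted log2 fold-change between timepoints.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples) and `truth` (data.frame
#'   gene, class, sign with class `"NC"` for static genes).
#' @export
generate_expression <- function(meta, n_genes = 547,
                                class_counts = c(I_only = 30, III = 30,
                                                 IV = 20, V = 20),
                                log2_effect = 2, dispersion = 0.05,
                                seed = 1L) {
  if (!all(names(class_counts) %in% maturation_class_labels)) {
    stop("unknown maturation class in class_counts; allowed: ",
         paste(maturation_class_labels, collapse = ", "), call. = FALSE)
  }
  if (sum(class_counts) > n_genes) {
    stop("sum of class_counts must be <= n_genes", call. = FALSE)
  }
  days <- sort(unique(meta$day))
  if (length(days) != 2) stop("meta must contain exactly two timepoints",
                              call. = FALSE)
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  mu0 <- exp(stats::rnorm(n_genes, log(300), 1))

  n_planted <- sum(class_counts)
  planted_idx <- sample.int(n_genes, n_planted)
  cls <- rep("NC", n_genes)
  cls[planted_idx] <- rep(names(class_counts), times = class_counts)
  sgn <- integer(n_genes)
  sgn[planted_idx] <- sample(c(-1L, 1L), n_planted, replace = TRUE)

  # multiplicative shift at the later timepoint, per arm
  shift <- function(class, s, arm) {
    on <- switch(class,
                 I_only = arm == "control",
                 III = TRUE,
                 IV = TRUE,
                 V = arm == "PAT",
                 NC = FALSE)
    if (!on) return(1)
    s_eff <- if (class == "IV" && arm == "PAT") -s else s
    2^(s_eff * log2_effect)
  }

  counts <- matrix(0L, nrow = n_genes, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  size <- 1 / dispersion
  for (j in seq_len(nrow(meta))) {
    arm <- meta$treatment[j]
    late <- meta$day[j] == days[2]
    mult <- if (late) {
      vapply(seq_len(n_genes),
             function(g) shift(cls[g], sgn[g], arm), numeric(1))
    } else rep(1, n_genes)
    counts[, j] <- as.integer(stats::rnbinom(n_genes, mu = mu0 * mult,
                                             size = size))
  }
  list(counts = counts,
       truth = data.frame(gene = genes, class = cls, sign = sgn,
                          stringsAsFactors = FALSE))
}

#' Generate a toy BGC reference with planted homology groups
#'
#' Each biosynthetic gene cluster (BGC) receives a length uniform in
#' `length_range` and a set of ORF-family labels. Members of the same
#' homology group share a disjoint pool of core families (pairwise Jaccard
#' similarity >= 0.8 by construction), while distinct groups share no
#' families (Jaccard 0).
#'
#' @param n_bgcs Number of BGCs (>= `n_homology_groups`).
#' @param length_range Integer pair, min/max BGC length in bp.
#' @param n_orf_families Approximate number of ORF families per BGC.
#' @param n_homology_groups Number of planted homology groups.
#' @param seed Integer seed.
#' @return A data.frame with columns `bgc_id`, `length_bp`, `orf_families`
#'   (semicolon-joined), `taxon`, `characterized`, `product_class`, `group`.
#' @export
generate_bgc_reference <- function(n_bgcs, length_range = c(5000L, 50000L),
                                   n_orf_families = 20,
                                   n_homology_groups = 3, seed = 1L) {
  if (n_homology_groups < 1 || n_bgcs < n_homology_groups) {
    stop("need n_bgcs >= n_homology_groups >= 1", call. = FALSE)
  }
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[2] < length_range[1]) {
    stop("invalid length_range", call. = FALSE)
  }
  set.seed(seed)
  n_core <- max(1L, ceiling(0.9 * n_orf_families))
  n_priv <- min(n_orf_families - n_core, floor(n_core / 8))
  group <- sort(rep_len(seq_len(n_homology_groups), n_bgcs))
  products <- c("siderophore", "aryl polyene", "NRPS", "polysaccharide",
                "bacteriocin", "terpene")
  orf <- character(n_bgcs)
  priv_counter <- 0L
  for (i in seq_len(n_bgcs)) {
    core <- sprintf("G%02d_core_%03d", group[i], seq_len(n_core))
    priv <- if (n_priv > 0) {
      sprintf("priv_%05d", priv_counter + seq_len(n_priv))
    } else character(0)
    priv_counter <- priv_counter + n_priv
    orf[i] <- paste(c(core, priv), collapse = ";")
  }
  data.frame(
    bgc_id = sprintf("BGC_%04d", seq_len(n_bgcs)),
    length_bp = as.integer(round(stats::runif(n_bgcs, length_range[1],
                                              length_range[2]))),
    orf_families = orf,
    taxon = sprintf("ref_taxon_%02d", group),
    characterized = stats::runif(n_bgcs) < 0.2,
    product_class = products[1 + (group - 1) %% length(products)],
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Simulate uniform shotgun read coverage over a single BGC
#'
#' Drops `n_reads` read start positions uniformly on the BGC, clips reads at
#' the 3' end, and reports the breadth of coverage (number of bases covered
#' by at least one read).
#'
#' @param bgc_length BGC length in bp.
#' @param n_reads Number of aligned reads.
#' @param read_len Read length in bp (>= 1).
#' @param seed Integer seed.
#' @param sample_id,bgc_id Identifiers attached to the observation.
#' @return A one-row data.frame: `sample_id`, `bgc_id`, `n_reads`,
#'   `read_len`, `covered_bases`.
#' @export
simulate_read_coverage <- function(bgc_length, n_reads, read_len, seed = 1L,
                                   sample_id = "S1", bgc_id = "BGC_0001") {
  if (read_len < 1) stop("read_len must be >= 1", call. = FALSE)
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  if (bgc_length < 1) stop("bgc_length must be >= 1", call. = FALSE)
  set.seed(seed)
  covered <- 0L
  if (n_reads > 0 && read_len >= bgc_length) {
    # a read at least as long as the reference aligns across all of it
    covered <- bgc_length
  } else if (n_reads > 0) {
    starts <- sort(sample.int(bgc_length, n_reads, replace = TRUE) - 1L)
    ends <- pmin(starts + read_len, bgc_length)
    covered <- interval_union_length(starts, ends)
  }
  data.frame(sample_id = sample_id, bgc_id = bgc_id,
             n_reads = as.integer(n_reads), read_len = as.integer(read_len),
             covered_bases = as.integer(covered), stringsAsFactors = FALSE)
}

# total length of the union of half-open intervals [start, end)
interval_union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  total <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Simulate paired taxa and gene-expression data with planted associations
#'
#' Latent clr-scale taxa signals are drawn i.i.d. standard normal; gene
#' responses are a sparse linear combination of them (a true coefficient
#' matrix with `n_true_edges` nonzero entries of magnitude
#' `coefficient_scale` and random signs) plus per-stratum (sex x treatment)
#' offsets and Gaussian noise. Taxa are exported as counts by
#' softmax-composition and multinomial sampling; genes by exponentiation.
#'
#' @param meta Metadata from [generate_metadata()] (one timepoint suffices).
#' @param n_taxa,n_genes Block dimensions.
#' @param n_true_edges Number of nonzero taxon-to-gene coefficients.
#' @param coefficient_scale Magnitude of each nonzero coefficient.
#' @param noise_sd Standard deviation of per-gene Gaussian noise.
#' @param stratum_sd Standard deviation of per-stratum gene offsets.
#' @param depth Per-sample taxa sequencing depth.
#' @param seed Integer seed.
#' @return A list with `taxa_counts` (samples x taxa), `expr_counts`
#'   (genes x samples), `taxonomy`, and `truth` (true coefficient matrix
#'   `beta`, logical `edges`, latent blocks).
#' @export
generate_paired_taxa_gene <- function(meta, n_taxa = 15, n_genes = 43,
                                      n_true_edges = 25,
                                      coefficient_scale = 1.0,
                                      noise_sd = 0.5, stratum_sd = 1.0,
                                      depth = 50000, seed = 1L) {
  if (n_true_edges > n_taxa * n_genes) {
    stop("n_true_edges cannot exceed n_taxa * n_genes", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(meta)
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  family <- sprintf("family_%02d", 1 + (seq_len(n_taxa) - 1) %% 5)

  Z <- matrix(stats::rnorm(n * n_taxa), n, n_taxa,
              dimnames = list(meta$sample_id, taxa))
  beta <- matrix(0, n_taxa, n_genes, dimnames = list(taxa, genes))
  if (n_true_edges > 0) {
    cells <- sample.int(n_taxa * n_genes, n_true_edges)
    beta[cells] <- sample(c(-1, 1), n_true_edges, replace = TRUE) *
      coefficient_scale
  }
  strata <- interaction(meta$sex, meta$treatment, drop = TRUE)
  offsets <- matrix(stats::rnorm(nlevels(strata) * n_genes, 0, stratum_sd),
                    nlevels(strata), n_genes)
  G <- Z %*% beta + offsets[as.integer(strata), , drop = FALSE] +
    matrix(stats::rnorm(n * n_genes, 0, noise_sd), n, n_genes)
  dimnames(G) <- list(meta$sample_id, genes)

  taxa_counts <- matrix(0L, n, n_taxa, dimnames = list(meta$sample_id, taxa))
  for (i in seq_len(n)) {
    p <- exp(Z[i, ] - max(Z[i, ]))
    taxa_counts[i, ] <- as.integer(stats::rmultinom(1, depth, p / sum(p)))
  }
  expr_counts <- t(round(2^(G + 8)))
  storage.mode(expr_counts) <- "integer"

  list(taxa_counts = taxa_counts, expr_counts = expr_counts,
       taxonomy = data.frame(taxon = taxa, family = family,
                             stringsAsFactors = FALSE),
       truth = list(beta = beta, edges = beta != 0, latent_taxa = Z,
                    latent_genes = G, noise_sd = noise_sd,
                    coefficient_scale = coefficient_scale, seed = seed))
}
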