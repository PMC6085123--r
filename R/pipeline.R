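#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' default: presence ratio threshold 0.75, enrichment FDR q < 0.15, taxa
#' relative-abundance filter > 0.01%, 5000 bootstraps, significance level
#' 0.05, StARS with 50 subsamples and instability bound 0.05.
#'
#' @param seed Master seed for every stochastic stage.
#' @return Named list of stage configurations.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "bgc", "maturation", "network"),
    simulate = list(n_mice_per_cell = 6, timepoints = c(12, 42),
                    n_taxa = 200, n_up = 4, n_down = 4, log2_effect = 2,
                    depth = 50000, overdispersion = 0.02,
                    n_genes = 547,
                    class_counts = c(I_only = 30, III = 30, IV = 20, V = 20),
                    expr_log2_effect = 2, dispersion = 0.05,
                    n_bgcs = 228, n_homology_groups = 3,
                    reads_per_present_bgc = 400, read_len = 150,
                    pair = list(n_taxa = 15, n_genes = 43, n_true_edges = 25,
                                coefficient_scale = 1.0, noise_sd = 0.5,
                                n_mice_per_cell = 12)),
    bgc = list(min_ratio = 0.75, q_threshold = 0.15,
               cluster_threshold = 0.5),
    maturation = list(t0 = 12, t1 = 42, alpha = 0.05),
    network = list(min_rel_abund = 1e-4,
                   lambda_grid = seq(0.95, 0.05, by = -0.05),
                   n_subsamples = 50, beta = 0.05,
                   bootstraps = 5000, alpha = 0.05)
  )
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Orchestrates the enabled stages in order (simulate, BGC presence and
#' enrichment, maturation classification, association network), writes all
#' stage artifacts as TSV/GraphML under `outdir`, and records a YAML run
#' manifest with the configuration, seed, input checksums, per-stage
#' runtimes and warnings.
#'
#' @param config Configuration list as from [default_config()], or a path to
#'   a YAML file containing one.
#' @param outdir Output directory (created if needed).
#' @return The run manifest, invisibly (also written to
#'   `manifest.yaml`).
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (length(stages) == 0) stop("nothing to do: no stages enabled",
                                call. = FALSE)
  known <- c("simulate", "bgc", "maturation", "network")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  }
  if (!"simulate" %in% stages) {
    stop("stage dependency missing: downstream stages require 'simulate'",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(tool = "patmicro", version = "0.1.0", seed = seed,
                   stages = stages, runtimes = list(), warnings = character(0))

  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  sim <- config$simulate
  meta <- generate_metadata(sim$n_mice_per_cell, sim$timepoints, seed)
  taxa <- generate_taxa_counts(meta, n_taxa = sim$n_taxa, n_up = sim$n_up,
                               n_down = sim$n_down,
                               log2_effect = sim$log2_effect,
                               depth = sim$depth,
                               overdispersion = sim$overdispersion,
                               seed = seed)
  expr <- generate_expression(meta, n_genes = sim$n_genes,
                              class_counts = unlist(sim$class_counts),
                              log2_effect = sim$expr_log2_effect,
                              dispersion = sim$dispersion, seed = seed + 1L)
  bgcs <- generate_bgc_reference(sim$n_bgcs,
                                 n_homology_groups = sim$n_homology_groups,
                                 seed = seed + 2L)
  # coverage: each sample covers a random subset of BGCs
  set.seed(seed + 3L)
  cov <- list()
  p21 <- meta[meta$day == min(meta$day), , drop = FALSE]
  for (i in seq_len(nrow(p21))) {
    hit <- which(stats::runif(nrow(bgcs)) < 0.5)
    for (b in hit) {
      cov[[length(cov) + 1L]] <- simulate_read_coverage(
        bgcs$length_bp[b], sim$reads_per_present_bgc, sim$read_len,
        seed = seed + 100L * i + b,
        sample_id = p21$sample_id[i], bgc_id = bgcs$bgc_id[b])
    }
  }
  coverage <- do.call(rbind, cov)
  write_metadata(meta, file.path(outdir, "metadata.tsv"))
  write_count_table(taxa$counts, file.path(outdir, "taxa_counts.tsv"),
                    "sample_id")
  write_count_table(expr$counts, file.path(outdir, "expression_counts.tsv"),
                    "gene")
  utils::write.table(bgcs, file.path(outdir, "bgc_reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(coverage, file.path(outdir, "coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(taxa_up = taxa$truth$up_taxa,
                        taxa_down = taxa$truth$down_taxa,
                        expression_classes = as.list(
                          table(expr$truth$class))),
                   file.path(outdir, "truth.yaml"))
  manifest$runtimes$simulate <- tic() - t0

  if ("bgc" %in% stages) {
    t1 <- tic()
    pres <- call_presence(coverage, bgcs, min_ratio = config$bgc$min_ratio,
                          samples = p21$sample_id)
    enr <- bgc_enrichment(pres, meta, q_threshold = config$bgc$q_threshold)
    clus <- cluster_bgcs(bgcs, threshold = config$bgc$cluster_threshold)
    write_count_table(pres * 1L, file.path(outdir, "presence.tsv"),
                      "sample_id")
    utils::write.table(enr, file.path(outdir, "bgc_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clus, file.path(outdir, "bgc_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$runtimes$bgc <- tic() - t1
  }

  if ("maturation" %in% stages) {
    t1 <- tic()
    mat <- config$maturation
    ctl <- maturation_test(expr$counts, meta, "control", mat$t0, mat$t1,
                           alpha = mat$alpha)
    pat <- maturation_test(expr$counts, meta, "PAT", mat$t0, mat$t1,
                           alpha = mat$alpha)
    calls <- classify_maturation(ctl, pat)
    utils::write.table(calls, file.path(outdir, "maturation_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_classes(calls)
    utils::write.table(
      data.frame(class = names(summ$class_counts),
                 count = as.integer(summ$class_counts)),
      file.path(outdir, "maturation_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$runtimes$maturation <- tic() - t1
  }

  if ("network" %in% stages) {
    t1 <- tic()
    nw <- config$network
    pair_meta <- generate_metadata(sim$pair$n_mice_per_cell, 23, seed + 4L)
    pair <- generate_paired_taxa_gene(
      pair_meta, n_taxa = sim$pair$n_taxa, n_genes = sim$pair$n_genes,
      n_true_edges = sim$pair$n_true_edges,
      coefficient_scale = sim$pair$coefficient_scale,
      noise_sd = sim$pair$noise_sd, seed = seed + 5L)
    blk <- prepare_features(pair$taxa_counts, pair$expr_counts, pair_meta,
                            min_rel_abund = nw$min_rel_abund)
    st <- stars_select(blk, lambda_grid = nw$lambda_grid,
                       n_subsamples = nw$n_subsamples, beta = nw$beta,
                       seed = seed + 6L)
    fit <- spls_fit(blk, st$selected_lambda, K = st$K)
    edges <- bootstrap_significance(blk, fit, B = nw$bootstraps,
                                    alpha = nw$alpha, seed = seed + 7L)
    write_edges(edges, file.path(outdir, "association_edges.tsv"))
    utils::write.table(
      data.frame(lambda = st$lambda_grid, instability = st$instability,
                 instability_monotone = st$instability_monotone),
      file.path(outdir, "stars_diagnostics.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- edges[edges$significant, , drop = FALSE]
    g <- build_network(sig,
                       pair$taxa_counts[blk$sample_ids, colnames(blk$X),
                                        drop = FALSE],
                       taxonomy = pair$taxonomy,
                       genes = colnames(blk$Y))
    igraph::write_graph(g, file.path(outdir, "association_network.graphml"),
                        format = "graphml")
    manifest$runtimes$network <- tic() - t1
  }

  inputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(inputs))
  names(manifest$checksums) <- basename(inputs)
  manifest$config <- rapply(config, as.vector, how = "list")
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
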