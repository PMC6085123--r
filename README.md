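# patmicro

Statistical toolkit for studying how a pulsed early-life antibiotic course
(PAT) perturbs the developing gut microbiome and the maturation of host
intestinal gene expression, in the NOD-mouse type-1-diabetes setting and
similar perturbation designs. It is aimed at microbiome researchers who
have shotgun-metagenomic coverage summaries, longitudinal expression
counts, and paired taxa/expression tables, and who want the three analyses
below as tested, reusable functions rather than one-off scripts.

## What it computes

**1. Biosynthetic-gene-cluster (BGC) presence and enrichment.** Under the
Lander–Waterman model, a reference of length `L_BGC` hit by `N` uniform
reads of length `L_read` has expected per-base coverage probability

    E = 1 − exp(−N · L_read / L_BGC)

A BGC is called *present* in a sample when the ratio of observed breadth of
coverage to `E` is ≥ 0.75. Presence is compared between treatment arms per
BGC by a two-sided Fisher exact test with Benjamini–Hochberg correction
(enrichment at q < 0.15), and homologous BGCs are collapsed by
average-linkage clustering on ORF-family Jaccard similarity.

**2. Five-class expression maturation.** Genes are tested per arm for
change between two postnatal days (Welch test on log2 median-of-ratios
normalized counts, BH across genes). Combining arms classifies each gene:
III = matures in both arms, same direction (PAT-resistant); IV = both arms,
opposite directions (altered); I_only = control arm only (maturation
lost); V = PAT arm only (dysmaturation); NC = neither. Marginal views
(maturing-in-control, maturing-in-PAT) are reported alongside, plus Fisher
pathway over-representation per class.

**3. Compositional sPLS taxa–gene association network.** Taxa counts are
filtered (mean relative abundance > 0.01%), clr-transformed, expression is
normalized and log-transformed, both blocks centered within sex×treatment
strata, and a sparse partial least squares model links taxa to genes. The
sparsity level is selected by StARS (edge-selection instability ≤ 0.05
across 50 stratified subsamples), and every selected edge receives a
bootstrap empirical p-value (recentred null, 5000 resamples by default)
with BH correction at q < 0.05. Significant edges form a bipartite GraphML
network.

A synthetic-data module generates all inputs (design metadata,
Dirichlet-multinomial taxa counts, negative-binomial expression with
planted maturation classes, uniform-read BGC coverage, paired taxa–gene
data with planted sparse associations) together with ground-truth sidecars,
so the whole pipeline is testable offline.

## Worked example

```r
library(patmicro)

## coverage statistic: 500 reads of 150 bp on a 25 kb BGC, breadth 17 kb
E <- expected_coverage(N = 500, L_read = 150, L_BGC = 25000)
r <- coverage_ratio(C = 17000, N = 500, L_read = 150, L_BGC = 25000)
# E = 0.950213, r = 0.71563  -> below 0.75: called absent

## association network on synthetic paired data (12 mice per design cell)
meta <- generate_metadata(12, 23, seed = 1)
pair <- generate_paired_taxa_gene(meta, seed = 42)   # 15 taxa, 43 genes, 25 edges
blk  <- prepare_features(pair$taxa_counts, pair$expr_counts, meta)
st   <- stars_select(blk, seed = 42)
fit  <- spls_fit(blk, st$selected_lambda, K = st$K)
edges <- bootstrap_significance(blk, fit, B = 500, seed = 43)
subset(edges, significant) |> head(3)
```

This run selects `lambda = 0.55` (a 40-edge support), finds 19 significant
edges, and against the planted truth scores precision 1.00 and recall 0.76.
The strongest edges sit at the empirical p floor `1/(B+1) = 0.002`:

```
     taxon      gene coefficient sign empirical_p           q
 taxon_012 gene_0003   1.0303399    + 0.001996008 0.007258211
 taxon_013 gene_0006   1.0616457    + 0.001996008 0.007258211
 taxon_012 gene_0007   1.1259939    + 0.001996008 0.007258211
```

Coefficients recover the planted magnitude 1, with matching signs.
`run_pipeline(default_config(seed), outdir)` chains all stages on synthetic
inputs and writes TSV/GraphML artifacts plus a YAML manifest.

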