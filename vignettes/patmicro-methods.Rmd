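---
title: "Methods: BGC presence, expression maturation, and taxa-gene association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BGC presence, expression maturation, and taxa-gene association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

patmicro implements three statistical procedures used to study how a brief
early-life antibiotic pulse (PAT: a therapeutic-dose macrolide course given
to mouse pups) reshapes the developing gut microbiome and the maturation of
intestinal immune gene expression. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

```{r setup}
library(patmicro)
```

## 1. BGC presence from metagenomic coverage

A biosynthetic gene cluster (BGC) of length $L_{BGC}$ hit by $N$ aligned
reads of length $L_{read}$ is expected, under the Lander-Waterman model of
uniform shotgun coverage, to have each base covered with probability

$$E = 1 - \exp(-N \cdot L_{read} / L_{BGC}).$$

The presence statistic is the ratio $r$ of the *observed* breadth of
coverage (fraction of bases covered at $\ge 1\times$) to $E$; a BGC is
called present in a sample when $r \ge 0.75$ (inclusive). Random uniform
coverage gives $r \approx 1$; reads piling onto a short homologous segment
of an absent cluster give high depth but low breadth, hence $r \ll 1$.
Three conventions are worth stating explicitly:

* The exponent carries a minus sign. A formula rendering without it (which
  circulates in print) would produce negative values and cannot be a
  probability; the restored sign is the only reading compatible with a
  ratio filter at 0.75.
* "Actual coverage" is interpreted as *breadth*, not depth: only breadth is
  dimensionally comparable to a coverage probability.
* Missing (sample, BGC) coverage rows are imputed as $N = 0$, giving
  $E = 0$; the ratio is defined as 0 there so absence of reads always maps
  to absence of the BGC. The number of imputed pairs is recorded on the
  presence matrix.

Group differences are tested per BGC with a two-sided Fisher exact test on
the treatment-by-presence 2x2 table, using the probability-mass definition
of two-sidedness (sum of all tables with fixed margins whose probability
does not exceed the observed table's, with a relative tie tolerance of
1e-7). BGCs present in all or no samples are still tested (p = 1) so the
Benjamini-Hochberg correction always runs over the same family; enrichment
is called at q < 0.15, the conventional discovery threshold for this
screen.

Homologous BGCs are collapsed by average-linkage agglomeration on the
Jaccard similarity of their ORF-family sets (or a user-supplied amino-acid
identity matrix; sequence alignment itself is out of scope). The tree is
cut so clusters merge while linkage similarity is at least the threshold
(default 0.5); rows are processed in lexicographic id order so ties break
deterministically.

## 2. Five-class expression maturation

Gene expression "matures" when it changes significantly between two
postnatal timepoints (defaults P12 and P42). Counts are median-of-ratios
normalized *within each arm* (mirroring arm-wise testing; size factors are
centered to geometric mean 1), log2(x+1) transformed, and tested per gene
with a Welch two-sample test; q-values are BH-adjusted across genes within
the arm and a direction is assigned only when q < 0.05.

Combining the control and PAT arms yields the classification:

| class | control arm | PAT arm |
|---|---|---|
| III (resistant maturation) | significant | significant, same direction |
| IV (altered maturation) | significant | significant, opposite direction |
| I_only (maturation lost) | significant | not significant |
| V (dysmaturation) | not significant | significant |
| NC | not significant | not significant |

The field's class I ("maturing in control") and class II ("maturing under
PAT") overlap classes III-V; because no exclusivity rule is encoded in the
arrow diagrams that defined them, patmicro makes III/IV/V/I_only/NC the
exclusive partition and *also* reports the marginal views (`marginal_I`,
`marginal_II`), so either reading is reproducible. "Altered" (IV) is
operationalized as opposite significant directions, the only attribute a
direction-of-maturation encoding carries; a same-direction magnitude change
is III. Pathway over-representation of any class uses the same two-sided
Fisher test over a 2x2 class-by-pathway table on the gene universe, BH
across pathways.

## 3. Compositional sPLS association network

To associate taxa with host genes while respecting the compositional
nature of sequencing counts, the pipeline (i) filters taxa to mean relative
abundance strictly above 0.01% and presence in at least one sample,
(ii) clr-transforms taxa counts per sample, (iii) normalizes and
log-transforms expression, (iv) removes between-cell variation by centering
both blocks within each sex-by-treatment stratum (each mouse contributes
one sample per analysis timepoint, so within-cell centering is the
implementable surrogate for within-subject variation), and (v) fits a
sparse partial least squares (sPLS) regression of genes on taxa.

**sPLS variant.** Each latent component is a penalized rank-1
approximation of the current cross-covariance matrix $M = X^\top Y$,
computed by alternating soft-thresholding (initialized at the leading
singular-vector pair): $u \leftarrow S(Mv)$, $v \leftarrow S(M^\top u)$,
where $S$ thresholds at `lambda * max(|w|)` and each vector is
renormalized. `lambda` is therefore a sparsity fraction in [0, 1]:
`lambda = 0` recovers the plain singular vectors (dense PLS) and
`lambda >= 1` removes every weight. Blocks are deflated by the component
scores; the number of components defaults to the number of singular values
of $M$ exceeding 1e-8 times the largest (a floating-point rank rule). The
support -- the edges the model selects -- is the union over components of
selected taxa times selected genes, so sparsity acts at the taxon-gene edge
level. We chose the alternating (penalized-matrix-decomposition style)
iteration over one-shot thresholding of the unpenalized singular vectors
after observing that the latter's supports are far less stable under
subsampling: their StARS instability exceeded the selection threshold at
every density at which recall of planted edges was complete, forcing
needlessly sparse models. Both weight vectors are thresholded because
X-only sparsity yields supports made of whole taxa rows, which carry no
edge-level information. Neither block is autoscaled: the clr and
log2 transforms already place features on comparable scales, and
autoscaling measurably destabilized support selection in development runs.

**StARS selection.** The sparsity level is chosen by stability: 50
subsamples of size $\min(\lfloor 10\sqrt n\rfloor, 0.8n)$ drawn without
replacement (stratified by design cell, re-centered after subsampling),
support recorded over a decreasing lambda grid (default 0.95 to 0.05 in
steps of 0.05), per-edge selection frequencies $\theta$, and instability
$D(\lambda) = \mathrm{mean}\, 2\theta(1-\theta) \in [0, 0.5]$. $D$ is
monotonized by a running supremum from the sparse end, and the selected
lambda is the *densest* model whose monotonized instability is at most
$\beta = 0.05$ — StARS maximizes density subject to bounded instability.

**Bootstrap significance.** At the selected lambda the model is refit on
5000 stratified bootstrap resamples (500 in the smoke profile used by the
automated checks). For each support edge, the bootstrap coefficient
distribution recentred at zero (coefficient minus its bootstrap mean) is
the null reference; the two-sided empirical p-value uses the +1/(B+1)
correction so p is never 0, and BH runs across support edges with
significance at q < 0.05. Recentring is the standard bootstrap-test
construction for an unspecified "empirical p"; it tests whether the
observed coefficient is extreme relative to its own sampling variability.
One master seed fans out to the subsampling and bootstrap streams.

The significant edges form a bipartite graph (exported as GraphML): taxon
nodes carry mean relative abundance and family, edges carry sign (+/- for
positive/negative association), coefficient, p, q, and a display width
$-\log_{10} p$.

## 4. What the synthetic generators emulate

Every stage is testable without downloads because the generators reproduce
the statistical structure the analyses assume:

* **Design**: a full 2 (sex) x 2 (treatment) crossing, one sample per mouse
  per timepoint; 6 mice per cell by default for microbiome-scale analyses
  (matching typical shotgun-arm group sizes), 8 per cell for expression,
  12 per cell for the paired association data.
* **Taxa**: Dirichlet-multinomial counts (concentration 1/overdispersion,
  default overdispersion 0.02) around log-normal baseline proportions, with
  4 over- and 4 under-represented taxa in PAT at log2 fold-change 2 —
  the kind of signal an antibiotic pulse leaves in relative abundances.
  Effects are planted on taxa with above-median baseline abundance, as the
  differentially represented genera in such studies are detectable ones; a
  planted fold-change on a taxon sequenced to zero counts in a whole arm
  would be unmeasurable by construction.
* **Expression**: negative-binomial counts (dispersion 0.05, log-normal
  baseline means around 300) with planted classes I_only/III/IV/V at log2
  effect 2; the marginal class II arises as the union of III, IV and V.
* **Coverage**: uniform read starts clipped at the BGC 3' end; a read at
  least as long as the reference is taken to align across all of it, as an
  aligner would place it. The closed form assumes reads never fall off the
  end, so law-agreement checks use $L_{read}/L_{BGC} \le 0.01$, where the
  edge effect is below the tolerance.
* **Paired taxa-gene data**: i.i.d. normal latent clr-scale taxa signals, a
  sparse coefficient matrix (25 edges of magnitude 1, random signs and
  positions), per-stratum gene offsets (sd 1), Gaussian noise (sd 0.5);
  exported as counts via softmax-composition plus multinomial sampling
  (depth 50000) and via exponentiation (round(2^(G+8))) for genes.

What they do **not** emulate: phylogenetic correlation among taxa,
taxon-taxon interactions, zero-inflation beyond the multinomial, library
size variation for expression, read sequencing errors, or reference-database
ambiguity. Passing recovery tests therefore demonstrates correctness of the
inference machinery under its own assumptions, not robustness to every
property of real sequencing data.

## 5. Numerical choices and degenerate inputs

* clr pseudocount: 0.5 added to every entry *only when zeros are present*,
  so zero-free compositions transform exactly.
* Fisher two-sidedness: probability-mass method, tie tolerance 1e-7
  relative (matching the convention of mainstream statistical software).
* Empirical p-values: +1/(B+1) floor; B < 100 is refused.
* Median-of-ratios reference genes: rows with no zero across samples; if
  none exists the error instructs adding a pseudocount.
* Welch test with two exactly constant groups degenerates to p = 1 (equal
  means) or p = 0; directions are reported from the mean difference but
  gated on q in the maturation pipeline.
* Rank-deficient PLS systems are solved through an SVD pseudoinverse
  (tolerance 1e-10 relative).
* BH is applied within each analysis family separately (per arm, per BGC
  run, per pathway collection), never pooled across stages.

## 6. Problem sizes in the automated checks

The recovery suites run at the generator defaults: 20 seeds for the
maturation recovery (547 genes, 8 mice per cell), 20 seeds for network
recovery with the 500-bootstrap smoke profile, 200 replicates for the
coverage law, 500 random tables for the Fisher oracle, and about 2600
pooled null edge-tests for p-value calibration. These sizes put the
Monte-Carlo error comfortably below each check's tolerance while keeping
the default suite quick on a laptop.

## Known limitations

* The expected-coverage model ignores read-length variation within a
  sample (the median read length stands in) and GC or mappability bias.
* With one sample per mouse per timepoint, within-cell centering cannot
  separate mouse identity from residual noise; repeated-measures designs
  would need a mixed model, which is out of scope.
* The five-class scheme keys on direction only; a gene whose maturation
  magnitude (but not direction) changes under PAT is classed III.
* StARS instability is estimated from 50 subsamples; with very small n the
  0.8n cap makes subsamples overlap heavily and instability is then
  slightly underestimated.
* The bootstrap does not refit StARS (the selected lambda is reused), so
  selection uncertainty is not propagated into the p-values.
* If no lambda on the grid meets the instability bound, StARS falls back to
  the sparsest candidate; widen the grid toward 1 if that happens on real
  data.
* The clr transform maps compositions into the hyperplane orthogonal to the
  all-ones vector, so one direction of the taxa-to-gene coefficient matrix
  is inherently unidentifiable from compositional data; coefficients are
  estimates of the projection onto that hyperplane, and bootstrap p-values
  correctly reflect the extra variability this induces.
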