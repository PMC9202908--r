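---
title: "Methods: paired differential expression, co-expression modules and TAD-based locus prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired differential expression, co-expression modules and TAD-based locus prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadscope)
```

## The analysis problem

Keloids are benign fibroproliferative skin tumours with a strong genetic
component: genome-wide association studies in Japanese and Chinese
populations have mapped susceptibility loci to cytoband-scale regions, but
most risk SNPs are non-coding and do not name a causal gene. `tadscope`
implements an integrative strategy for such designs: profile mRNA, lncRNA
and miRNA expression in a small set of paired lesion/normal tissue samples,
characterise the differentially expressed RNAs with co-expression modules,
regulatory networks and pathway enrichment, and finally use chromatin
topology — the topologically associating domain (TAD) containing each risk
SNP — to restrict the genome-wide DE lists to locus-level candidate genes.
The rationale is that genes sharing a TAD share cis-regulatory context, so
a non-coding risk variant is most plausibly acting on genes within its TAD.

Every stage is exercised end to end on synthetic data with machine-readable
ground truth; the generator is first-class, tested code.

## Paired negative-binomial differential expression

Counts for feature $g$ in sample $i$ (patient $p(i)$, condition
$c(i) \in \{0 = \text{normal}, 1 = \text{lesion}\}$) are modelled as
negative binomial with mean

$$\mu_{gi} = s_i \exp\left(\mu_g + \eta_{p(i)} + \beta_g\, c(i) \ln 2\right),
\qquad \mathrm{Var} = \mu + \alpha \mu^2,$$

so $\beta_g$ is the log2 fold change (positive = higher in lesion). Size
factors $s_i$ use the median-of-ratios rule, rescaled to geometric mean 1.
Features must be *uniformly detected* — a positive count in both samples of
every patient — before testing. The per-feature model is fit by IRLS at a
fixed dispersion and $\beta_g$ is tested with a two-sided Wald z-test;
Benjamini–Hochberg adjustment is applied across tested features.

**Dispersion.** With three pairs the model leaves two residual degrees of
freedom per feature, so a per-feature dispersion estimate is essentially
unidentifiable: in simulation, a per-feature method-of-moments dispersion
makes the Wald test reject ~19% of nulls at the 0.05 level, while switching
the reference to a t with 2 df restores the 0.05 level but obliterates
power at BH-adjusted thresholds (the t(2) tail makes genome-wide-small
p-values unreachable). Supplying the *true* dispersion yields a
well-calibrated z (5.4% at 0.05). The default therefore pools: per-feature
design-based Pearson estimates seed a single common dispersion solved from
the summed Pearson equation across all features, in the spirit of a
common-dispersion negative-binomial analysis; `dispersion_method =
"per-feature"` keeps the unpooled estimates for data where dispersion
varies strongly. The floor is $10^{-4}$. One consequence is documented
honesty rather than bit-compatibility with any specific DE package: this
is a minimal paired NB Wald test, without dispersion trends, shrinkage of
fold changes, independent filtering or outlier replacement.

**Selection thresholds.** Genome-wide lists use adjusted P < 0.05 with
|log2FC| ≥ 2 for mRNA/lncRNA and |log2FC| ≥ 0.67 for miRNA (the fold-change
cut is inclusive, the p cut strict); the TAD-local screen uses raw
P < 0.05 with |log2FC| ≥ 1, reflecting that a locus-restricted test set
needs less multiplicity control than the transcriptome. Both p-value
fields are switchable per class.

**A threshold-at-effect-size caveat.** When the true effect of a planted
feature sits exactly at the fold-change cut (|log2FC| = 2 planted, cut at
2), an unbiased estimator lands below the cut about half the time
(sd of the estimate ≈ 0.37 at three pairs and $\alpha = 0.1$), so the
sensitivity of the *full* filter saturates near 0.5 regardless of the
test's quality. Recovery of the DE *test* (q < 0.05) is the meaningful
power measure at these settings and is what the acceptance checks assert;
the strict-filter sensitivity is reported alongside it.

## Co-expression: PCC pairs and weighted modules

lncRNA–mRNA pairs are scored by Pearson correlation across all samples on
the `log2(normalized + 1)` scale and kept at r > 0.9 — the one-sided rule
as printed in the field's workflows; `use_abs = TRUE` admits negative
regulation. Module detection follows the weighted co-expression network
recipe: unsigned adjacency $a_{ij} = |r_{ij}|^\beta$ with the soft power
chosen as the smallest candidate whose connectivity distribution fits a
scale-free line with $R^2 \ge 0.8$; topological overlap

$$t_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj};$$

average-linkage clustering of $1 - t$; a static cut at 0.9 of the maximal
merge height (a 0.995 cut collapses everything into one or two clusters on
realistic inputs); clusters below `min_size = 30` become grey. Each
surviving cluster is refined by module membership: members with
|kME| < 0.9 against the module eigengene are dropped, the eigengene is
recomputed on the purified set and the original members re-admitted
against it. At six samples, chance correlations are large (the null |r|
has sd ≈ 0.45), and without this refinement each module drags in 20–30
unrelated features. Module labels follow the conventional color order by
decreasing size; module significance is the mean $-\log_{10} p$ of members'
DE p-values, with rank-based selection (the threshold that would select a
specific number of modules on real data is not identifiable from the
method description, so top-k with k = 3 is the default and configurable).

Dynamic tree cut, eigengene-based module merging and blockwise computation
are out of scope.

## Regulatory network and enrichment

The typed network unions directed miRNA→target edges (restricted to DE
miRNAs; optionally to DE targets), undirected lncRNA–mRNA co-expression
edges at the PCC threshold, and optional protein–protein edges read from a
file. Nodes carry class and DE direction; duplicate edges collapse under
set semantics; ranking is by total degree, descending, ties broken by node
id so the top-20 table is reproducible. Module-restricted subnetworks keep
edges with at least one endpoint in a selected module plus incident
miRNAs, and report connected components. Exports: GraphML (lossless for
classes, directions, edge types), SIF (edge type as relation token) and
edge TSV.

Enrichment is a one-sided Fisher's exact (hypergeometric upper tail)
over-representation test at P < 0.01, BH-adjusted across sets; the
universe defaults to detected features carrying at least one set
annotation. lncRNA "target-gene" enrichment substitutes each DE lncRNA by
its PCC-paired mRNAs before testing. Per-module reporting keeps each
module's top 8 sets by p-value.

## Hi-C, insulation score and TAD calling

Contact matrices are dense TSV or COO triplets at a fixed bin size (40 kb
default). The insulation score of bin $b$ is the log2 ratio of the mean
contact in the $w \times w$ square crossing $b$ (upstream bins
$b-w \dots b-1$ against downstream $b+1 \dots b+w$; $w = 5$, i.e. 200 kb)
to the chromosome-wide mean of that statistic; edge bins with incomplete
windows are undefined. Boundaries are local minima whose strength — the
drop below the lower of the two flanking local maxima — reaches
`delta_min`; domains tile the chromosome between boundaries, with a 3-bin
minimum span. The default `delta_min = 0.5` (half a doubling) reflects
measured noise: at a contact contrast of 3, Poisson fluctuation produces
spurious minima with strengths up to ≈ 0.35 while planted boundaries score
1.2–1.9. An optional second pass re-scans each called TAD at half window
width and emits the internal partition at `sub_tad` level; because a nested
high-contact domain produces step-like (one-sided) minima, the second pass
scores the *higher* flank and uses a doubled threshold. Loading
externally-called TADs from BED is supported as the browser-faithful
alternative to calling them from the matrix; both paths validate the same
interval invariants (same-level non-overlap, half-open bp coordinates).

Matrix balancing (ICE/KR), binary `.hic`/`.cool` containers, compartments
and loop calling are out of scope. Cytoband-style locus names are opaque
labels: loci must arrive as coordinates, and no cytoband resolver is
shipped.

## Locus prioritization

For each susceptibility locus, every containing interval (TAD and sub-TAD
level) is found by half-open containment of the SNP position; features are
assigned to a TAD when their TSS lies inside its span (promoter-centric
rule; `overlap = "any"` switches to body overlap), and the TAD-local filter
(raw P < 0.05, |log2FC| ≥ 1) yields the candidate table, sorted by locus
then p, with direction and sub-TAD flags. Loci with no containing TAD are
reported `no_tad`; loci whose TAD yields nothing are reported `empty`
rather than dropped. `run_pipeline()` chains every stage under one seed
and writes a manifest (package version, seed, configuration hash,
per-stage row counts); outputs are byte-identical across reruns of the
same configuration.

## What the synthetic generator emulates — and what it does not

Defaults mirror the target study design: 3 patients × 2 conditions,
NB counts with dispersion $\alpha = 0.1$, baseline means of roughly 20–400
(log-uniform), patient effects of sd 0.1 (log scale), library-size factors
log-normal (sd 0.1), 10% DE per class at |log2FC| = 2 (mRNA, lncRNA) and
1.5 (miRNA — comfortably above the 0.67 selection cut), Hi-C at 40 kb with
intra/inter contact rates 30/10 (contrast 3, the regime the boundary
caller is specified for) and a nested sub-TAD at 3× the intra rate, and
three risk loci: one with upregulated candidates, one with downregulated
candidates plus upregulated ones confined to the sub-TAD, and one planted
empty.

Deliberate design choices, each made for identifiability at n = 6 and
documented here rather than hidden:

- **Module factors are per-sample scores, orthogonalised** against the
  intercept, the lesion/normal contrast and each other. Unconstrained
  factors frequently chance-correlate at six samples — with the contrast
  (making co-expression masquerade as differential expression) or between
  modules (making the planted partition itself ill-defined). This caps
  `n_modules` at `2 * n_patients - 2`.
- **Randomly DE and module-member features keep a one-bin margin from
  risk-locus TADs**, because a correctly-working insulation caller may
  place a boundary one bin off and would otherwise swallow adjacent true
  DE features into a locus.
- **The empty locus is a gene desert**: no random TSS is placed inside its
  TAD. At realistic feature density, a megabase-scale TAD of null features
  would yield several false TAD-local hits (P(|log2FC-hat| ≥ 1) ≈ 3% per
  null feature at these settings), so locus emptiness is planted
  structurally, not left to sampling luck.
- **TAD plans tile chromosomes fully**, making boundary truth the set of
  internal TAD-TAD transitions; chromosome-edge "boundaries" sit inside
  the insulation margin and are unrecoverable by construction.
- **Planted candidates draw baselines from the upper half of the range**
  so that 4-fold-down candidates stay above the detection floor.

The generator does *not* emulate read-level noise (FASTQ), sequence
content, isoforms, batch effects beyond the patient term, distance-
dependent Hi-C dispersion beyond Poisson, or annotation edge cases like
overlapping gene bodies. Passing recovery tests therefore demonstrates
correctness of the estimators and calling logic under the stated model,
not robustness to every artefact of real tissue data.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; GTF is written 1-based
  closed and BED 0-based half-open. TSS = `start` on +, `end - 1` on −.
- One RNG stream is forked per generator output, so adding an output never
  perturbs earlier ones; identical configurations give byte-identical
  files (date-stamped GTF comment headers are stripped).
- Wald statistics use unit GLM dispersion explicitly; the default
  `summary.glm` quasi-dispersion at 2 residual df was the single largest
  source of miscalibration found during development.
- One-condition-all-zero features are refit on counts + 0.5 and flagged
  `pseudo_count`; non-converged fits report p = 1 and a flag, never an
  exception; undetected features carry NA statistics and are excluded
  from BH ranking.
- Zero-variance expression vectors are skipped (with counts logged) in
  PCC pairing; all-grey module sets and empty TAD sets are valid results
  with warnings, not errors.
- Problem sizes in the test-suite recovery checks — 2000 features × 5
  seeds for DE, 350 features for modules, 20 seeds × 2 chromosomes for
  boundaries — were chosen as the smallest sizes at which the binomial /
  Monte-Carlo error of the measured rates is well inside the asserted
  margins.

## Known limitations

- The common dispersion trades per-feature adaptivity for calibration;
  strongly heteroskedastic data deserve the per-feature option plus a
  larger design.
- The static tree cut with kME refinement approximates, but is not,
  dynamic tree cut; very unequal module sizes may split or merge.
- The insulation caller is a generic square-window method with declared
  parameters, not a replication of any specific browser's TAD calls; at
  contrast below ~2 its boundary recall degrades gracefully but
  substantially.
- Sub-TAD localization at half window width is coarse (±2 bins in
  simulation).
- With three pairs, WGCNA-style module detection on real data is at the
  edge of identifiability; the module stage is best treated as
  descriptive there.
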