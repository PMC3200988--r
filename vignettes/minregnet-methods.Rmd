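---
title: "Methods: from two-class expression data to a minimal regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-class expression data to a minimal regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minregnet)
```

`minregnet` reconstructs a *minimal* transcription-factor (TF) regulatory
network from a two-class (tumour versus non-malignant control) expression
study. The pipeline has five stages: quality preprocessing, stable
differential-expression (DEG) selection by an iterative SAM framework,
TF-target interaction prediction by promoter scanning, network assembly
and pruning, and cross-condition comparison. A synthetic-data generator
plants known DEGs, outlier samples and regulatory edges so that every
stage has a parameter-recovery test. This vignette documents the models,
the tunable parameters, and the design choices made where the design was
genuinely open.

## Preprocessing and quality review

Inputs are MAS5-style probe-by-sample signal matrices with
Present/Marginal/Absent detection flags, a tumour/control class label per
sample, and a probe-to-gene annotation.

* **Absent-probe filter.** Probes flagged `A` in *every* sample carry no
  signal and are removed; one `P` or `M` call anywhere retains the probe.
* **z-normalization.** Each probe row is standardized to mean 0, sd 1.
  We use the population (divide-by-`n`) standard deviation; the choice is
  arbitrary but fixed and documented — it rescales all probes by the same
  factor relative to the `n-1` convention and has no effect on clustering
  topology or downstream calls. Constant rows cannot be standardized; they
  are set to zero (with a warning) rather than dropped, so probe sets stay
  aligned across datasets.
* **Outlier removal.** Samples are clustered by UPGMA (average linkage,
  `stats::hclust`) on Euclidean distances between z-score profiles. The
  tree is cut into two groups at the root, and tumour samples falling in
  the cluster that holds the majority of controls are removed, after which
  z-normalization is repeated on the survivors. Historically this call was
  made by visual inspection of a dendrogram; a root cut is the closest
  deterministic proxy, and an exactly even split of controls across the
  two clusters is refused with an error rather than guessed at. Controls
  are never removed.

## SAM: moderated statistic, permutation FDR, delta rule

For probe $i$ with tumour/control means $\bar{x}_{i1}, \bar{x}_{i2}$ and
pooled standard error $s_i$,

$$d_i = \frac{\bar{x}_{i1} - \bar{x}_{i2}}{s_i + s_0},$$

computed on log2 signal. The fudge factor $s_0$ is chosen by the classic
procedure: candidates are the 0, 5, ..., 100th percentiles of the $s_i$
distribution, and the candidate minimizing the coefficient of variation of
$d$ across quantile windows of $s$ (window spread measured by MAD) is
kept. We use one window per 25 probes (at most 100 windows): smaller
windows make the MAD too noisy to compare candidates at a few hundred
probes. On exactly homoscedastic data the criterion legitimately drifts to
an extreme percentile — there is no heteroscedasticity to correct, and a
large $s_0$ merely makes $d$ proportional to the numerator — so tests
assert the argmin property rather than a central location.

The null distribution permutes class labels: all label assignments are
enumerated when there are no more than `n_perm` of them, otherwise
`n_perm` random draws are used (class sizes like 22 vs 15 make balanced
permutation schemes impractical, so full label permutation is used). For
each permutation the ordered $d$ values are recomputed ($s_i$ under the
relabelling, $s_0$ fixed) and averaged rank-wise into $\bar{d}_{(i)}$, the
expected order statistics.

**Calls and FDR.** At threshold $\delta$, the probe at sorted rank $i$ is
called when $|d_{(i)} - \bar{d}_{(i)}| \ge \delta$. Each permutation
contributes one FDR value — its own exceedance count divided by the
observed call count, capped at 100% — giving an FDR *distribution* whose
90th percentile drives the selection rule. The candidate grid is 200 even
steps from 0 to the largest observed $|d_{(i)} - \bar{d}_{(i)}|$.

**Delta selection.** The zero-FDR deltas form a terminal interval: FDR
falls as $\delta$ rises and stays at zero once reached. The selected
$\delta$ is the boundary of that terminal run — the smallest $\delta$ at
which the 90th percentile of the FDR distribution reaches and remains
zero, subject to at least one call. This is the unique reading under which
"significant at FDR = 0" yields a usable gene list; taking the largest
zero-FDR delta instead degenerates to the grid maximum and a one-gene
call set. Because the rule targets FDR exactly zero, a $\pi_0$ (true-null
proportion) correction is immaterial and not applied.

**Fold filter.** Calls additionally require a two-fold linear change,
$\bar{S}_{i1}/\bar{S}_{i2} \ge 2$ or $\le 0.5$, computed on *unlogged*
group means of the signal-scale values (the SAM convention), never on
z-scores. The fold filter is part of the significance definition: under a
pure-noise null the observed maximum of $|d - \bar d|$ exceeds the 90th
percentile of the permutation maxima about 10% of the time by
exchangeability, so the delta rule alone must make spurious calls in
roughly that fraction of null datasets; the combined rule is quiet (the
type-I experiment in the test suite measures exactly this).

**Gene collapse.** Significance is decided per probe. A gene is a DEG
when at least one of its probes is called and no probe of the gene is
called in the opposite direction; conflicting genes are dropped and
logged. The representative fold change comes from the probe with the
largest $|d|$.

## Iterative training/test DEG selection

The tumour cohort is split in half at random. The training half is
re-randomized into two subgroups in a 2:1 ratio (22:11 at a 33-sample
training arm; `round(n * 2/3)` and the remainder elsewhere, minimum 3 per
subgroup), SAM is run on each subgroup against the same control set, and
gene-level calls are intersected requiring direction agreement (the
stricter reading of "significant in both"). After `n_iter = 10`
iterations the running intersection is the *training signature*. A single
SAM on the held-out half then retains only signature genes recapitulated
with the same direction — the final DEG set. We intersect across all
iterations (rather than reporting per-iteration consensus counts), the
stricter of the two defensible readings; the provenance table records how
often each gene was called anyway. One master seed spawns per-iteration
child seeds, so extending `n_iter` never changes earlier iterations. The
same control set is reused throughout — an acknowledged limitation of the
design being reproduced, not an accident.

## Promoter analysis: PWM scanning and interaction p-values

TFs among the DEGs are identified by a user-supplied gene-to-PWM mapping
table. Each PWM is a 4×L count matrix (JASPAR count format); counts are
smoothed with a pseudocount of 0.5 and scored as log2 odds against a
background base composition (uniform by default). Every window of a
promoter is scored on both strands — minus-strand sites via the
reverse-complemented matrix, reported at forward coordinates — and windows
scoring at least `threshold_frac = 0.8` of the maximum attainable score
are sites. The 0.8 fraction is a convention, configurable; overlapping
sites all count (no greedy masking). Windows containing `N` are skipped.

A TF-target pair is scored by over-representation: with $n$ sites
observed among the $2(\ell - L + 1)$ windows of the target's promoter, the
p-value is the upper-tail binomial probability of $\ge n$ hits at the
background site rate. That rate is estimated empirically by scanning
first-order-Markov resamples of all candidate promoters (10 per promoter,
pooled; dinucleotide composition preserved in expectation), with half a
pseudo-hit added so the rate is strictly positive. One shuffled set is
generated per run and shared across all PWMs. Pairs with $p < 0.005$
become predicted interactions; TF-TF edges arise when the target is
itself a TF, and self-pairs are skipped. This reproduces the *interface*
of genome-scale promoter-analysis services (TF, target, p-value at a
fixed cutoff) with a deliberately simpler single-genome scoring model —
no phylogenetic footprinting — so equivalence with any particular service
is neither claimed nor testable.

## Network assembly, minimal pruning, enrichment

Predicted interactions restricted to pairs where both genes are DEGs form
the regulatory network; each node carries its expression direction and
fold change as an overlay. (The looser reading — keeping edges where only
one endpoint is a DEG — is noted but not used: the networks of interest
contain only DEGs.) The *minimal network* keeps only target genes
regulated by at least two distinct TFs. Pruning iterates to a fixed
point: dropping under-regulated targets can orphan a TF, whose removal is
also cascaded; TF nodes are exempt from the in-degree rule and survive
while they touch any edge. Pruning is idempotent and only ever removes
edges. Edge identity is the ordered (regulator, target) pair; p-values
are attributes.

Pathway over-representation of the minimal-network gene list uses the
upper-tail hypergeometric test within a stated gene universe;
Benjamini–Hochberg q-values are reported alongside but no selection is
applied — the correction is offered, the cutoff left to the user.

## Cross-condition comparison

Networks from several datasets of one condition are pooled by edge union
(duplicates keep the smallest p-value; conflicting node directions are
flagged). A focal-network edge is *common* when the same directed gene
pair appears in at least one comparison network and *specific* otherwise;
the two classes partition the focal edges exactly. Matching ignores
p-values and expression direction, following the "relationship between
two genes" definition. TF nodes are classified analogously.

## The synthetic-data generator

The generator emulates the study design the pipeline targets, with
defaults chosen once as the package's standard test conditions:

| parameter | default | meaning |
|---|---|---|
| `n_tumor`, `n_control` | 40, 10 | cohort sizes (a 4:1 ratio as in typical tumour/control designs) |
| `n_genes`, `probes_per_gene` | 1000, 1–3 | gene universe; many-to-one probe mapping |
| `frac_deg`, `deg_fold` | 0.10, 4 | planted DEG fraction and linear fold change |
| `frac_up` | 0.25 | up-regulated fraction of planted DEGs |
| `noise_sd` | 0.3 | per-probe log2 noise |
| `n_tfs`, `edges_per_tf` | 6, 4 | planted network scale (six-TF core) |
| `promoter_length`, `motif_length` | 1000, 10 | promoter and motif sizes |
| `motif_sites_per_edge` | 2 | planted sites per regulatory edge |
| `frac_absent`, `n_outliers` | 0.05, 2 | uninformative probes; mislabeled tumours |

Expression is log2-normal: Gaussian on the log2 scale, exponentiated to
signal scale, so planted fold changes are exact at `noise_sd = 0`. All
probes of a DEG gene carry the same shift (real probes disagree; the
simplification keeps collapse rules testable). Absent probes are drawn
from non-DEG genes so recovery metrics stay interpretable. Outlier
tumours are drawn from the control distribution, so they segregate with
controls under clustering and exercise the outlier-removal rule. Motifs
have one dominant base per column (85 of 100 counts, about 1.15
bits/column), detectable but not degenerate. Planted sites are sampled
from the PWM's column distributions *conditioned on scoring above the
scan threshold* (rejection sampling): unconditioned draws from a motif of
this sharpness fail the 0.8-of-maximum threshold often enough that the
generator would violate its own site-recovery contract. Planted targets
each receive exactly two regulators (cyclic TF pairing), making the
planted network minimal by construction, so end-to-end recovery can be
scored after pruning. Effect-size distributions for real tumour DEGs are
unknown; these defaults are conventions, not estimates.

What passing recovery tests does **not** show about real data: real
probes of one gene disagree, fold changes vary continuously, promoters
have structured (non-Markov) background and motif clustering, and real
TF-target truth is unknown. The generator validates the machinery, not
the biology.

## Numerical and reproducibility choices

* Seeds: one master seed spawns labelled child streams
  (`child_seed`), so stages are independently reproducible; all outputs
  are byte-identical under a fixed configuration.
* Delta grid: 200 even steps; FDR values capped at 100%; `0/0` call
  ratios treated as FDR 0.
* Degenerate inputs: constant probes are zeroed with a warning; an all-`s`
  tie fixes `s0` at that value; empty intersections or empty significant
  sets propagate as warnings, not errors; a 50/50 control split during
  outlier review is an error demanding manual inspection.
* Problem sizes in the routine test suite are scaled (hundreds of genes,
  tens of samples, 30–50 permutations) so the full recovery experiments
  run comfortably on a laptop; the acceptance experiments use the default
  conditions above.

## Known limitations

The promoter model is a stand-in: single genome, binomial
over-representation, published-threshold conventions. The comparison
stage performs no significance test on network overlap (none is defined
for it here). Chip-level quality metrics (RawQ, scaling factors, 3'/5'
ratios) require probe-level data and are treated as upstream concerns.
The pipeline starts from summarized signal matrices; summarization
algorithms and CEL handling are out of scope.
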