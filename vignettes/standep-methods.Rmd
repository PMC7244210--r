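---
title: "Cluster-specific thresholding of enzyme expression: model, choices, limits"
author: "standep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-specific thresholding of enzyme expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standep)
```

## What the method computes

Given a genes × contexts abundance matrix (FPKM/TPM-like, nonnegative,
linear scale) and a genome-scale metabolic model's GPR rules, the package
derives, per context, a core set of reactions supported by expression
evidence, plus the tailored inputs of six model-extraction methods. The
chain is: GPR → enzymes (DNF), gene → enzyme expression (min over
AND-clause genes), enzyme → binned log10 profile, profiles → hierarchical
clusters, clusters → data-dependent thresholds, thresholds → active calls →
core reactions → MEM inputs.

The premise worth stating explicitly: a single dataset-wide threshold
confounds *level* with *consistency*. An enzyme at 3 FPKM in every context
carries strong evidence of constitutive function, while an enzyme at
300 FPKM in two contexts out of forty is context-specific. Clustering
enzymes by their cross-context distribution and thresholding each cluster
against its own distribution separates the two regimes.

## The threshold equations and their behaviour

For cluster $c$ with pooled log10 mean $\mu_c$ and SD $\sigma_c$, and
dataset mean $M$ and SD $\Delta$:

$$\theta_c = \frac{\sigma_c - \Delta}{\max_c(\sigma_c - \Delta)}
           - (\mu_c - M), \qquad
  \Theta_c = \frac{(\theta_c - \min\theta)\cdot 100}{\max(\theta - \min\theta)}$$

$\Theta_c$ is read as a *top percentile of the cluster's own pooled values*:
the cutoff is the quantile at probability $(100-\Theta_c)/100$ (linear
interpolation between order statistics), and a member enzyme is active where
its log10 value strictly exceeds the cutoff. $\Theta_c = 100$ is
special-cased to the dataset mean $M$.

Two behaviours follow that a user should know about:

* **The sign of the $f$ denominator.** When every cluster is tighter than
  the pooled dataset ($\sigma_c < \Delta$ for all $c$, the usual situation
  when between-cluster spread dominates), $\max_c(\sigma_c-\Delta)$ is
  negative and $f$ *rewards* tight clusters, which is what lets a low-mean,
  low-variance housekeeping-like cluster earn a high $\Theta$. The package
  preserves the formula's sign as written and warns when this regime is
  active.
* **The $\Theta=100$ special case is a cliff.** The cluster with the
  largest $\theta$ always maps to $\Theta=100$ and takes the dataset mean
  as its cutoff. If that cluster's members lie below $M$ — typical for the
  very lowest-expression cluster — none of them can be active. The
  lowest-expression cluster is therefore often *dead*, and the
  second-lowest, tight cluster is the one that benefits from
  cluster-specific thresholding. This matters when interpreting results and
  when constructing test fixtures (below).

Degenerate inputs are handled explicitly: all $\sigma_c=\Delta$ collapses
$f$ to 0 (warning); a constant $\theta$ vector maps every cluster to
$\Theta=100$, i.e. a global dataset-mean threshold (warning); zeros are
excluded from every log10 statistic, bin count and quantile pool, and a
zero-expression enzyme is never active.

## Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| bins | 60 uniform log10 bins over the positive range | resolves ~8 decades of abundance at ~0.13 decades/bin; the binning span is fixed by the data, the count is a resolution choice |
| distance, linkage | Euclidean, complete | the method's standard configuration; alternatives are accepted by argument |
| N selection | smallest N with mean core-list Jaccard to N+1 above 0.90, persisting through the scanned range | increasing N splits weak clusters while strong ones persist; the core list stabilises |
| global threshold | top 25th percentile | the conventional single-threshold baseline |
| localT1/localT2 percentiles | 75 (lower), 25 (upper) | the conventional local-threshold baselines |
| MBA band | ±10% around the cutoff, linear scale | "percent of the threshold value" reads as a multiplicative margin on abundance; a `scale = "log"` flag bands the log cutoff instead |
| zero floor for distances | log10(min positive) − 1 decade | zero expression needs a finite log10 stand-in for the distance matrix; one decade below the observed floor keeps it strictly worst |
| Gini cutoff | 0.24 normalized | the agreement point of housekeeping calls between two large independent compendia |

"Top X percentile" uniformly means the type-7 (linearly interpolated)
quantile at probability $(100-X)/100$, with strict `>` qualifying active.
Percentile ranks are invariant under monotone transforms, so computing the
baselines on log10 values is observationally equivalent to linear-scale
percentiles; the package keeps everything on log10 for internal
consistency.

Choices the sources left genuinely open, decided here: quantile pools for
cluster cutoffs are the cluster's *pooled enzyme × context positive values*
(not per-enzyme means, and pooled across contexts); the localT1 description
exists in two contradictory published forms, so both are implemented behind
`variant =` with the operational ("methods") form as default; min(D) in the
ubiquity formula is the most negative entry of the whole matrix, the only
reading that guarantees $U\in[0,1]$; the D = 0 boundary gets $U = 1$;
enzyme weights for INIT/GIMME are left unclipped after isoenzyme summation;
both-empty sets compare as Jaccard 1; duplicate gene rows reduce by max;
enzymes touching unmeasured genes are dropped (not zero-imputed) by
default, mirroring the practice of restricting to genes present in both
model and data.

## The synthetic fixture: what it emulates, and what it does not

`generateFixture()` plants clusters of genes whose log10 expression is
i.i.d. Normal per context with per-cluster dropout (zeros), wired into a
toy catalog (default 300 reactions: 20% AND-complexes, 15% isoenzyme pairs,
5% gene-free). The default four clusters emulate the structure that
separates cluster-specific from global thresholding:

* a housekeeping-like cluster (mean −0.3 log10, sd 0.10, no dropout) about
  one decade below the dataset mean;
* a slightly lower, sparser cluster (mean −0.6, sd 0.12, 20% dropout) —
  this is the cluster that takes the $\Theta=100$ dead slot, so that the
  housekeeping cluster lands at $\Theta\approx 94$ and is captured; without
  it the housekeeping cluster itself would take the dataset-mean cutoff and
  be lost, a direct consequence of the equations discussed above;
* a tight mid cluster (1.5, sd 0.20) and a broad high cluster (3.0,
  sd 0.80) providing the bulk of the dataset's spread. With these defaults
  the planted partition is recovered exactly (ARI = 1) and StanDep captures
  the housekeeping enzymes in ~94% of contexts while the global top-25%
  captures none. The two low clusters sit only ~3 of their sd apart in
  log-expression — they cannot be further separated without pushing the
  housekeeping cluster's $\Theta$ below 90 — but their profiles remain
  separable through the second cluster's dropout; the mid and high
  clusters are 9+ sd from everything else.

Complex subunits are *co-expressed*: genes of one AND-complex share a
per-context latent profile plus small independent noise (sd 0.05 log10).
This mirrors the co-regulation of complex members and is also what makes
the planted labels meaningful — with independent subunits, min-over-AND
systematically shifts every complex enzyme below its cluster and no
clustering method could (or should) recover the gene-level planting.

What the fixture does **not** emulate: count noise (no negative-binomial
read simulation), between-sample normalisation artefacts, correlated
contexts, realistic GPR nesting depth, or genome-scale dimensions. Passing
tests on the fixture therefore demonstrates the *mechanism* — low, tight
clusters are captured by cluster-specific thresholds and missed by global
ones — not performance on any real dataset.

A second fixture exists for exercising cluster-count selection (four
well-separated clusters, n = 24/58/59/59, means −0.8/0.4/1.4/2.6, sds
0.06/0.18/0.20/0.22, no dropout). Its shape is dictated by a property of
the selection rule worth recording: the returned N jumps whenever the
$\theta$-extreme clusters split, because the affine normalisation re-anchors
every cluster's $\Theta$ and whole subclusters flip into or out of the
core. Keeping the extreme clusters small and internally homogeneous (so the
tree splits the middle clusters first) makes the rule settle at N within one
of the planted K. At realistic scale (hundreds to thousands of enzymes,
dozens of contexts) each flip is proportionally small and the trace is much
smoother; the toy-scale jumpiness is a property of the rule, not of the
implementation.

## Numerical conventions

Quantiles: type 7 (R default), matched in tests against an independent
sort-and-interpolate oracle at 1e-9. SDs: sample (n−1) convention
throughout. Binning: right-closed last bin, values at the lower edge fall
in the first bin. Agglomeration ties follow `stats::hclust`'s deterministic
input-order behaviour; leaf order is not part of any contract. DNF
expansion is capped at 256 clauses per reaction (configurable) with a hard
error beyond, and DNF equivalence to the source rule is verified
exhaustively in tests for rules up to 12 genes. The hypergeometric
enrichment population is the set of reactions carried by clustered enzymes;
because isoenzymes of one reaction can sit in different clusters, a
reaction may count in several clusters — membership is attributed per
enzyme.

## Scope and limitations

The six extraction algorithms themselves, flux-consistency checking, FBA,
exometabolomic constraint construction and gene-essentiality simulation are
out of scope: the package produces the *inputs* those steps consume.
Problem sizes used in the test suite and acceptance script (40 contexts,
200 genes, 300 reactions; 100 randomized oracle instances of up to 50
enzymes × 10 contexts) were chosen so the full suite runs in seconds while
still exercising every code path at sizes where brute-force oracles are
exact. The method itself presumes a dataset diverse enough for expression
patterns to form distinct clusters; on small or homogeneous datasets a
global threshold remains the more defensible choice, and the cluster-count
rule will warn rather than fabricate stability.
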