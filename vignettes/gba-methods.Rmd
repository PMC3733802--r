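---
title: "Guilt-by-association candidate prioritization: model and methods"
author: "gbaNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association candidate prioritization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbaNet)
```

## The model

`gbaNet` ranks candidate disease proteins by how strongly they associate
with known disease proteins (*seeds*) inside a weighted protein–protein
interaction (PPI) network. The premise — guilt by association — is that
interacting proteins tend to share function and phenotype, so a protein
connected to many seeds through reliable interactions, and functionally
similar to them, is a plausible disease protein itself.

The disease-specific network is the set of seeds plus their direct
interaction neighbors (*candidates*), i.e. one-step nearest-neighbor
expansion of the global PPI graph. Multi-hop expansion is deliberately
out of scope: the score below is a single-pass neighborhood aggregation,
not a diffusion process.

Every edge carries two weights on $[0,1]$:

* $C(i,j)$ — the interaction confidence inherited from the interaction
  database (STRING-style combined scores divided by 1000 on ingestion);
* $F(i,j)$ — a functional similarity computed from Gene Ontology
  annotation (below).

With $N(i)$ the neighbors of $i$ in the **full source graph** and
$I(j) \in \{0,1\}$ the indicator of membership in the disease network,
the disease relevance score is

$$S(i) \;=\; \sum_{j \in N(i)} \bigl(\alpha\, C_{ij} + \beta\, F_{ij}\bigr)\, I(j)
\;-\; \sum_{j \in N(i)} \bigl(\alpha\, C_{ij} + \beta\, F_{ij}\bigr)\,\bigl(1 - I(j)\bigr).$$

The second sum penalizes promiscuous connections leading outside the
disease network. The algebraic combination is intentionally the
*minimal* form consistent with the method's verbal definition (additive
over neighbors, $\alpha$ weighting confidence, $\beta$ weighting
functional similarity, indicator-gated, promiscuity subtracted); it is
isolated behind a single pluggable interface (`scoreParams(formula =
"plugin")`), so an alternative algebraic form is a one-function change
and every ranking and evaluation layer is agnostic to it. Two useful
consequences of the default linear form:

* scores are linear in $(\alpha,\beta)$, so grid search re-weights
  cached per-candidate aggregates instead of re-summing neighborhoods;
* $(c\alpha, c\beta)$ rescales all scores by $c$ and leaves every
  ranking unchanged, so the grid's diagonal cells are redundant by
  construction — the tests assert this.

Seeds are scored (for the seed-versus-candidate comparison) but never
ranked among candidates. Ties are broken by identifier lexicographic
order so output is deterministic across platforms.

## Functional similarity

Similarity is information-content (IC) based. After propagating direct
annotations to all ancestors (true-path rule), a term's IC is
$-\ln(n(t)/N)$, with $n(t)$ the number of genes whose propagated set
contains $t$ and $N$ the number of annotated genes in the term's
namespace. Term-level similarity defaults to Lin,
$2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$,
with Resnik (min–max normalized by the corpus maximum IC so all
measures share the $[0,1]$ contract) and the relevance measure as
alternatives. Gene-level similarity combines the term matrix over the
two genes' direct annotations by best-match average (symmetric) or
maximum.

Defaults — biological process namespace, Lin, best-match average,
natural logarithm, `is_a` edges only, no evidence-code filtering — are
explicit package choices, selected because they are the most widely
used $[0,1]$-bounded convention; each is one configuration switch away
(`similarityConfig()`, `readOBO(includePartOf=)`,
`readGAF(excludeEvidence=)`). Conventions at the degenerate corners:
a root–root pair has IC sum zero and similarity 0; terms never reached
by an annotation have undefined IC and are skipped; a gene with no
usable annotation in the active namespace contributes the fallback
similarity (default 0). When several common ancestors tie for maximal
IC the lexicographically smallest id is reported — the similarity value
is identical by definition.

## Network construction choices

With the default `induced` policy the disease network keeps **all**
source-graph edges among seeds and candidates, including
candidate–candidate edges; `seed_incident` keeps only edges touching a
seed. The induced subgraph is the conventional reading of "keep all
interaction relationships of the seed proteins", and the score's
membership indicator only distinguishes in/out of the node set, but the
alternative is preserved as a policy because real edge counts cannot
adjudicate between the readings. Seeds absent from the interaction data
are dropped with a warning rather than an error — disease genes without
interaction evidence are a fact of life — but an entirely absent seed
set is an error.

Identifiers are opaque, case-sensitive tokens. Whether they are gene
symbols or protein accessions is a property of the data (the bundled
cardiomyopathy fixtures carry both), not of the logic: the bundled
lists include cases where several gene symbols share one protein
accession, which token-level treatment handles without special-casing.
The bundled dilated (DCM) and arrhythmogenic right ventricular (ARVC)
lists share two members (DSP, DSG2); the overlap report simply reports
what the lists contain.

## Evaluation

Leave-one-out cross-validation removes each seed in turn, rebuilds the
network from the remaining seeds (the held-out protein joins the
candidate pool if it neighbors any remaining seed), re-scores, and
records the held-out rank $R$ among $M$ candidates. A held-out seed
with no remaining-seed neighbor cannot re-enter the network; it
receives the sentinel worst rank ($M{+}1$ of $M{+}1$), which penalizes
non-recoverable seeds instead of silently dropping folds (dropping is
available via `dropAbsent = TRUE` and changes the AUC).

The ROC sweeps rank-ratio thresholds — every achievable $k/M_f$ across
folds — because fold candidate lists differ in size. At threshold $r$,
sensitivity is the fraction of folds with the held-out seed in the top
$\lfloor r M_f \rfloor$; 1 − specificity is the proportion of non-test
candidates in the same top slice, pooled across folds (micro) by
default with per-fold (macro) averaging behind a flag. Sweeping only
the observed ranks' ratios would interpolate across large gaps and
misstate the area for extreme rankings (a worst-case ranking must reach
the $(1,0)$ corner, which only intermediate thresholds expose); the
full sweep makes the limits exact: all-rank-1 folds give AUC
$\approx 1$, all-rank-last give $\approx 0$, uniform ranks give
$\approx 0.5$. The AUC is the trapezoidal integral.

Enrichment of a top list uses the upper-tail hypergeometric probability
$P(X \ge k)$ with a fixed 0.05 significance flag on raw p-values by
default; a Benjamini–Hochberg column is optional, since the classical
workflow this package follows applies none.

## The synthetic-study generator

`simulateStudy()` emulates exactly the structure the method assumes: of
`nGenes = 200` genes, a planted module of `moduleSize = 25` interacts
with probability `pIn = 0.30` and within-module confidences drawn from
Beta(8, 2) (mean 0.8), against a background edge probability
`pOut = 0.02` with Beta(2, 5) confidences (mean 0.29); a 60-term,
depth-5, single-namespace ontology contains a dedicated 8-term module
subtree from which module genes draw 2–4 direct annotations, while
background genes draw 1–3 terms from the rest; `nSeeds = 10` module
genes, chosen uniformly, are the seeds. Beta-distributed confidences
(bounded, skewable) keep the confidence and similarity channels
separately tunable. One integer seed determines every generated byte,
and `writeStudy()` emits the exact formats the readers consume, so
synthetic runs exercise the same I/O path as real ones. The defaults
are sized so that a full LOOCV plus the 100-cell grid completes in a
few seconds on one CPU; tests and the acceptance script run tens of
studies within desk-scale budgets.

What the generator does **not** emulate: STRING's evidence-channel
structure, the topology statistics of real interactomes (degree
heavy-tails, cliquishness of complexes), real GO's size and multiple
namespaces, and annotation depth bias. Passing tests therefore
demonstrate correctness of the machinery and recoverability of a
planted signal, not performance on any particular real interactome.

### The null configuration

`nullStudyParams()` removes the planted signal for calibration: equal
edge probability everywhere, **one** confidence distribution for all
edges, and no shared module annotations. Two details matter. Equalizing
only the edge probabilities would leave a residual signal in the
confidence channel (module edges would still be drawn from the stronger
Beta), so the null also unifies the confidence distributions. And the
common edge probability is kept at 0.30 rather than 0.02: under a
sparse null most held-out seeds have no remaining-seed neighbor, the
sentinel assigns them the worst rank, and the pooled AUC would measure
seed connectivity rather than ranking calibration. With the dense null,
held-out seeds are almost always recoverable candidates and the pooled
LOOCV AUC sits at chance.

### What recovery can and cannot reach

Seeds are a uniform subset of an exchangeable planted module, so in any
fold the held-out seed is statistically indistinguishable from the
other non-seed module candidates. Even a scorer that separates module
from background perfectly can only place the held-out seed uniformly
among the module candidates; with roughly 15 module competitors in a
candidate list of about 45, the expected rank ratio is bounded away
from zero and the LOOCV AUC has a structural ceiling in the low 0.8s at
the default generator settings. The acceptance checks report the
measured recovery AUC alongside this consideration; the companion
statistic — held-out module genes concentrating in the top 20% of the
ranking — is the calibrated form of the same guarantee (tested as the
median rank ratio of non-seed module genes per study, the natural
reading of a module-recovery guarantee).

## Numerical and format conventions

* Duplicate interaction rows collapse to the **maximum** confidence
  (conservative toward stronger evidence and order-independent, unlike
  first-wins); self-interactions are dropped with a warning.
* All confidences live on $[0,1]$ internally; the `raw_999` scale
  divides by 1000 at ingestion. Absolute score magnitudes depend on the
  input scale, but rankings do not, so the package standardizes on unit
  scale.
* Ontology ingestion topologically checks acyclicity on every load and
  errors listing one concrete cycle.
* Rankings serialize with 6 significant digits and round-trip through
  the reader at that precision.
* Every stochastic routine takes an explicit integer seed and restores
  the caller's RNG state.

## Known limitations

Only direct neighbors of seeds are ranked; true disease proteins two or
more interaction steps away are invisible, as are proteins with no
interaction data at all. The score is sensitive to the completeness of
the annotation corpus through $F$; sparsely annotated genes fall back
to 0 similarity and are penalized relative to well-annotated ones. The
(α, β) grid is integer-valued by design — the selection surface is
flat along scalings, so finer continuous optimization adds nothing
under the default linear form.
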