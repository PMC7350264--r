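---
title: "Methods: from AP-MS purifications to proteoform-aware function prediction"
author: "apmsfun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from AP-MS purifications to proteoform-aware function prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsfun)
```

# Overview

`apmsfun` turns a table of AP-MS purifications (one bait, many identified
preys per experiment) into per-protein Gene Ontology predictions and a
comparison of canonical versus splice-form interactomes. This vignette is
the package's own account of the statistical machinery: the models, the
tunable parameters and their defaults, the numerical decisions, what the
synthetic-data generator does and does not emulate, and the known
limitations.

# Co-occurrence model

Under the **matrix model**, every unordered pair of proteins identified in
the same purification counts as a candidate interaction — bait–prey and
prey–prey alike. The alternative (spoke model, bait–prey only) is out of
scope. For a pair $(i, j)$ let $q$ be the number of purifications
containing both, and $n_i$, $n_j$ the per-protein occurrence counts, with
$r = n_i - q$ and $s = n_j - q$. Two scores are computed:

* the **Dice coefficient** $D(i,j) = 2q / (2q + r + s) \in [0, 1]$, which
  also serves as the edge weight of the final network, and
* the **hypergeometric (Hart) score**: the upper-tail probability
  $P(X \ge q)$ for $X$ hypergeometric with population $N$ (number of
  purifications), $n_i$ successes and $n_j$ draws. The population size and
  margins are the simplest faithful parametrization of "probability of
  co-occurring at random given each protein's total count"; the unit tests
  pin it to exhaustive enumeration for every margin with $N \le 8$.

Pairs that never co-occur ($q = 0$) are never materialized; all
containers are sparse. Before counting, *master form* accessions —
identifications where the specific proteoform cannot be resolved — are
replaced by the gene's canonical accession (`normalize_forms()`); splice
accessions stay distinct.

# Threshold calibration

Interactions are retained when the Dice score is **strictly greater** than
a threshold (or the Hart p-value strictly below it). The threshold is not a
free parameter: `scan_thresholds()` compares candidate networks against a
gold-standard complex catalogue, expanded into all unordered within-complex
pairs (the matrix-model pairization), restricted on both sides to the
shared protein universe. For each grid point it computes
$F_1 = 2\,TP / (2\,TP + FP + FN)$ and returns the maximum ($F_{max}$) and
the corresponding raw score threshold.

Two grid interpretations are supported because they answer different
questions. The default (`type = "quantile"`, 99 evenly spaced quantiles of
the observed score distribution) follows the usual practice of scanning
score quantiles and reporting the raw threshold at the argmax. A raw-value
grid (`type = "value"`) is also available: in the noiseless limit all
materialized scores are exactly 1, every empirical quantile collapses onto
1 and the strict inequality empties the network, so the perfect-separation
property ($F_{max} = 1$ at any raw threshold in $(0,1)$) is only visible on
the value grid. The acceptance suite exercises both.

# GO processing

Annotations are ancestor-propagated (true-path rule) **before** any
filtering, so that support counts do not penalize specific terms twice.
The three-step cascade then applies:

1. evidence filter — keep the experimental codes EXP, IDA, IPI, IMP, IGI,
   IEP (drops IEA-like assignments);
2. support filter — drop terms with fewer than 10 distinct proteins
   (exactly 10 is kept);
3. level filter — drop terms whose level exceeds 10 (BP, CC) or 6 (MF).

"Level" is the **shortest** directed path to the namespace root over
`is_a` and `part_of` edges, the common convention in GO tooling; a
longest-path convention is available behind `convention = "max"`. Each
filter is idempotent, the three commute pairwise on propagated sets, and
each is monotone non-increasing in term count — all asserted as properties
in the test suite.

**Wang semantic similarity** uses the original edge weights (0.8 `is_a`,
0.6 `part_of`), best-path S-values, and zero similarity across namespaces;
set-versus-set comparison is the symmetric best-match average.
**Enrichment** of a target set against a reference uses the raw
hypergeometric upper tail with a stringent cutoff ($p < 10^{-7}$ by
default, mirroring single-list GO enrichment at a fixed significance
level); Benjamini–Hochberg adjustment is available but off by default,
matching the raw-cutoff convention this pipeline style uses.

# Cost-sensitive Hopfield label propagation

Each surviving GO term defines a binary semi-supervised problem on the
Dice-weighted network: proteins annotated with the term are *positive*,
annotated proteins lacking it are *negative*, proteins with no visible
annotation (including the masked uPE1 set) are *unknown*.

**Learning.** Each labeled node $i$ is summarized by the point
$(P_i, N_i)$: its total edge weight to labeled positives and to labeled
negatives. A finite sweep over neuron angles $\alpha \in (0, \pi/2)$ (64
values) and thresholds $\gamma$ selects the linear rule
$\sin\alpha \cdot P_i - \cos\alpha \cdot N_i - \gamma > 0$ maximizing the
F-score on the labeled nodes. Candidate $\gamma$ values are the midpoints
between consecutive projected values (plus sentinels beyond both ends):
midpoints make the same training decisions as data-value cuts but maximize
the geometric margin, which matters when the rule is transferred to unseen
nodes. Ties break toward the larger margin, then the smaller angle. The
asymmetric neuron values ($\sin\alpha$ for positives, $-\cos\alpha$ for
negatives) are the cost-sensitive ingredient: with rare positives the sweep
typically picks a large $\alpha$, letting few positive neighbors outweigh
many negatives.

**Dynamics.** Labeled nodes are clamped and act as a constant external
field. Unknown nodes update asynchronously in a fixed seeded permutation,
node $i$ taking the positive value iff
$\sum_j w_{ij} x_j - \theta_i > 0$, until a full sweep changes nothing.
Thresholds are constant during the run, so the energy
$E(x) = -\tfrac12 \sum w_{ij} x_i x_j + \sum_i \theta_i x_i$ is
non-increasing along every update and a fixed point always exists; the test
suite asserts the energy trace on random instances and convergence on 100
random instances up to 500 nodes.

**Regularization.** The scalar cost $\lambda \ge 0$ enters the threshold
additively, $\theta_i = \gamma + \lambda + c_i$, shifting every decision
toward the negative class. This form uses a single scalar as the method
sketch requires and yields a provable monotonicity: with identical
initialization and update order, raising $\lambda$ can never increase the
number of predicted positives (a coupling argument over the non-negative
weights; asserted across the 12-value decade grid $10^1 \dots 10^{-10}$).
`hopfield_cost_search()` re-draws an 80/20 split of the labeled nodes per
candidate cost, averages per-term held-out F1 jointly across namespaces,
and breaks exact ties toward the smallest cost. The package default is
$\lambda = 10^{-5}$.

**Initialization and field centring — a design decision.** The classic
recipe initializes unknown nodes with random provisional classes in the
labeled class proportion. Implementing exactly that (available as
`init = "proportional"` via `hopfield_init()`, with the proportional
rounding the interface promises), we measured a systematic failure mode on
planted data: pairs of adjacent unknown nodes that both start provisional
positive can hold each other above threshold indefinitely — self-sustaining
false-positive islands — because $\gamma$ is calibrated on labeled-only
fields while the dynamics add unknown-neighbor input on top. Two
package-owned choices address this, both preserving every property above:

* the default initial state of an unknown node is the learned rule's own
  decision on its labeled field (`init = "field"`), so relaxation starts
  from the best labeled-only solution rather than from noise, and
* each node's threshold carries a constant offset
  $c_i = \bar{x} \sum_{j \in U \cap nb(i)} w_{ij}$, where $\bar{x}$ is the
  mean initial unknown state: the dynamics then respond to *deviations*
  from the starting configuration instead of its bulk (`center = TRUE`).

On the planted benchmark in the acceptance suite this raises held-out F1
from below to above the weighted neighbor-vote baseline. The margin between
the two classifiers is small on densely labeled synthetic data (they are
near-equivalent when 80% of every complex is labeled); the Hopfield
machinery is expected to pay off in the sparse-label regime it was designed
for, which the planted benchmark only partially represents.

**Abstention.** A term column abstains entirely when it has fewer than 2
labeled positives (or no negative); an individual cell abstains when its
final activation lies within $\varepsilon$ of the threshold, with
$\varepsilon = 10^{-8}$ times the largest nodewise weight sum — a pure
numerical-indifference band. Every cell is exactly one of
positive/negative/abstained. One binary problem is solved per term; no
hierarchical consistency correction is applied across terms.

# Proteoform analysis

The interactome profile of a protein is its partner set in the thresholded
network; the analysis view keeps profiles with **more than** `min_partners`
(default 10) partners. The divergence of a canonical/splice pair is the
Jaccard distance $1 - |A \cap B| / |A \cup B|$ after removing the two
paired proteins from both sets (so forms are not penalized for binding
each other). "Fraction of common partners" has no canonical normalization;
Jaccard is the default because it is symmetric, with the overlap
coefficient ($|A \cap B| / \min(|A|,|B|)$) selectable. Divergences are
binned into the exclusive intervals $[0,.5)$, $[.5,.75)$, $[.75,.9)$,
$[.9,1]$, which always sum to the pair total.

Functional components connect profiles sharing strictly more than 50% of
partners and take connected components (single linkage — the minimal
reading of "combined into one group"). Size classes: two-protein (2),
micro (3–7), then mini/mid/macro at configurable ascending bounds
(defaults 8–50, 51–500, >500; only the micro range is canonical, the rest
are reported, never hard-coded into outputs). Hubs are nodes with strictly
more than 150 partners. Canonical/splice prediction disagreements are the
per-namespace symmetric differences of predicted-positive term sets,
excluding abstained cells; genes with one form fully abstained are counted
separately rather than compared.

# The synthetic-data generator

`simulate_apms_study()` plants everything the analysis assumes, under a
single seed with deterministically derived per-stage seeds (fixed seed
gives byte-identical artifacts):

* **Complexes** — sizes uniform on `complex_size_range` (default 3–6, the
  typical scale of curated core complexes), drawn from the non-background
  pool; a protein may sit in at most two complexes (curated catalogues
  overlap), and a `background_fraction` (default 0.15) belongs to none and
  models the contaminant pool.
* **Purifications** — one per bait; co-members retained with probability
  $1 - fn$, plus Poisson(`fp_rate`) contaminants drawn uniformly from the
  background. Defaults fn = 0.1, fp = 0.5: mild dropout and sub-one
  contaminant rates typical after stringent identification filtering. The
  contaminant structure of real AP-MS compendia is unknown in detail; the
  Poisson-uniform model is an assumption, chosen as the simplest noise
  model with a tunable mean.
* **GO DAG and annotations** — three namespaces, `dag_depth` levels
  (default 3), occasional double parents (`is_a`/`part_of`). Each complex
  draws two leaf terms per namespace from a shared pool, so terms are
  shared across complexes and the 10-protein support filter is non-trivial;
  members receive them with probability 0.9, everyone picks up background
  terms at rate 0.02, evidence codes are 70% experimental (uniform over the
  six codes) and 30% IEA so the evidence filter bites. Annotations are
  ancestor-closed at generation time.
* **Proteoforms** — `n_proteoform_genes` genes gain a splice accession
  whose complex memberships are the canonical's with a
  `proteoform_divergence` fraction (rounded) resampled to non-overlapping
  complexes; at divergence 1 the forms share no complex. A fraction of
  genes also emits master-form accessions in purifications to exercise the
  master-to-canonical rule.
* **uPE1 mask** — exactly `round(upe1_fraction × n_annotated)` proteins
  sampled without replacement lose all visible annotations; the hidden
  truth is recorded for recovery scoring and never written into any
  visible artifact.

What the generator does **not** emulate: peptide-level identification and
FDR control (inputs are identification tables by construction), bait-count
heterogeneity and batch structure of real compendia, realistic GO DAG depth
(tens of levels) and annotation sparsity, disease metadata on complexes,
and correlated contaminants (CRAPome-style frequent flyers). Green tests
therefore certify the pipeline's internal correctness and its behavior
under controlled noise — not performance on real AP-MS data.

# Numerical choices and reproducibility

* Strict inequalities everywhere a cutoff is named ("greater than",
  "more than", "less than" semantics); ties drop.
* Degenerate inputs: an all-zero Dice denominator errors; empty
  purification tables produce empty counts (not an error); learning with
  all-identical points falls back to $\alpha = \pi/4$ and the median
  projection; non-convergent dynamics (never observed within the
  100-sweep cap in testing) return the last state flagged.
* Seeds: a single global seed derives per-stage seeds through an affine
  hash modulo $2^{31}-1$, so any stage can be re-run in isolation; per-term
  seeds mix the term identifier, keeping columns independent yet
  reproducible. Two runs with equal seeds produce byte-identical artifacts,
  asserted at file level.
* Problem sizes in the test and acceptance suites (a few hundred proteins,
  tens of complexes, DAGs of ~60 terms, networks up to 500 nodes for the
  dynamics properties) were chosen so the full validation narrative —
  exhaustive oracles, 100-instance convergence sweeps, five-point
  dose–response, double pipeline runs — completes in minutes on one core
  while every property remains non-trivially exercised.

# Known limitations

* The Hart parametrization is one reasonable reading of a hypergeometric
  co-occurrence test; other choices (e.g., bait-aware margins) exist.
* The Hopfield cost enters as an additive threshold penalty; other
  regularizer forms are conceivable and would change the cost grid's
  meaning.
* On densely labeled networks the Hopfield classifier and a weighted
  neighbor vote perform within a few F1 points of each other; claims about
  real uPE1 data require the sparse-label regime and real networks.
* The divergence analysis compares network neighborhoods, not binding
  interfaces; co-complex resampling in the generator is a coarse proxy for
  biological proteoform rewiring.
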