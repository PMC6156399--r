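---
title: "Sparse-neighbourhood prediction of miRNA-disease associations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-neighbourhood prediction of miRNA-disease associations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snmda)
```

## The problem

Experimentally validated miRNA-disease associations are catalogued in
curated databases, but the catalogue is sparse: most diseases and most
miRNAs have only a handful of known links, and the degree distributions of
the bipartite association network are heavy-tailed. `snmda` scores every
unobserved disease-miRNA pair by combining three ingredients:

1. a **learned similarity** for miRNAs and for diseases, reconstructed from
   the association network itself by sparse-neighbourhood coding;
2. **precomputed similarities** — miRNA functional similarity and
   DAG-derived disease semantic similarity — fused with the learned ones;
3. **label propagation** of the known associations on both fused similarity
   networks.

The input is a binary matrix $A \in \{0,1\}^{n_d \times n_m}$ with
$A_{ij} = 1$ when disease $i$ is known to be associated with miRNA $j$.

## Disease semantic similarity

Diseases are organised in a directed acyclic graph of increasingly general
terms. For a disease $d$ with ancestor closure $T(d)$, each $t \in T(d)$
contributes $\Delta_d(t) = \delta^{\ell(t)}$, where $\ell(t)$ is the
shortest ascending path length from $d$ to $t$ and $\delta$ is the semantic
decay (default 0.5; the contribution of $d$ to itself is 1). Equivalently
$\Delta_d(t)$ satisfies the recursion
$\Delta_d(t) = \max_{t' \in \mathrm{children}(t) \cap T(d)}
\delta\,\Delta_d(t')$ — with a uniform decay the two forms coincide, and the
test suite checks the implementation against an exhaustive path-enumeration
oracle. The semantic value is $DV(d) = \sum_{t \in T(d)} \Delta_d(t)$ and
the pairwise similarity is

$$S(a,b) = \frac{\sum_{t \in T(a) \cap T(b)}
  \big(\Delta_a(t) + \Delta_b(t)\big)}{DV(a) + DV(b)},$$

which is symmetric, lies in $[0,1]$, and equals 1 on the diagonal. The
decay is exposed as a parameter (`decay`) for sensitivity analyses but the
conventional value 0.5 is the default. When a precomputed disease
similarity matrix is available this module is bypassed; both entry paths
produce the same matrix type.

A note on merging: a disease with several positions in the source
classification is assumed to arrive as one already-merged DAG; the loader
does not merge multiple DAGs per term.

## Sparse-neighbourhood reconstruction

Each miRNA is described by its *interaction profile*, its column of $A$
(and each disease by its row). Entity $i$ is then coded against the
dictionary $D_{-i}$ of all other entities' profiles by the penalized lasso

$$\min_w \; \lVert D_{-i} w - x_i \rVert_2^2 + \lambda \lVert w \rVert_1 ,$$

the penalized relaxation of the equality-constrained basis-pursuit program
$\min \lVert w\rVert_1 \ \text{s.t.}\ x = Dw$. The relaxation is the form
actually computed by the standard L1 least-squares solvers, and it remains
well defined when the equality system is infeasible. The solver is exact
cyclic coordinate descent (soft-threshold updates, compiled code),
deterministic for fixed inputs; the tests verify its objective against an
independent convex solver (`glmnet`, with the penalty mapped to glmnet's
scaling) to $10^{-6}$ relative.

The *sparse neighbourhood* of entity $i$ is the index set
$\{j : w_j > \varepsilon\}$. Coefficients are clipped at zero before
thresholding — a similarity cannot be negative, and the strict threshold
discards them anyway; the `nonneg` option solves the nonnegative program
directly instead. The surviving weights fill row $i$ of a coefficient
matrix $W$ (diagonal exactly 0, because the dictionary excludes the sample
itself), and the reconstructed similarity is the symmetrization
$(W + W^\top)/2$ — the downstream fusion and propagation steps presuppose a
symmetric similarity. $W$ is not rescaled to $[0,1]$: the fusion step
averages raw values and the propagation normalization absorbs the scale.

Parameter choices, both exposed in `sparse_config()`:

* $\lambda$ defaults to $0.01 \cdot \max_j |d_j^\top x_i|$ *per sample*
  (`lam = 0.01`, `lam_scale = "relative"`). Relative scaling keeps the
  effective shrinkage comparable between dense hub profiles and the many
  near-empty profiles of a heavy-tailed network. $\lambda$ is the knob that
  controls neighbourhood size; the method's source publication does not
  report a value, so this default is this package's engineering choice.
* $\varepsilon$ defaults to $10^{-4}$ (also unreported upstream);
  $\varepsilon = 0$ keeps every strictly positive coefficient.

An entity with an all-zero profile (no known associations) cannot be
reconstructed; its row of $W$ stays zero and a warning is emitted. Its
eventual scores come entirely from the precomputed similarities and the
label-injection term.

## Similarity fusion

With $RMS$ the reconstructed miRNA similarity and $MFS$ the precomputed
functional similarity (same index),

$$FMS(x,y) = \begin{cases} RMS(x,y) & \text{if } MFS(x,y) = 0\\
 \big(RMS(x,y) + MFS(x,y)\big)/2 & \text{otherwise,}\end{cases}$$

and identically for the disease side ($RDS$, $DSS$, $FDS$). The zero test
is exact (no epsilon): an exactly-zero prior is treated as *missing*
information rather than evidence of dissimilarity. Because the
reconstruction diagonal is 0 and the prior diagonal is 1, the fused
diagonal is 0.5; this is a documented consequence of the definitions, and
it is harmless because the normalization treats the diagonal like any
other entry. Equal-weight averaging is the method's definition; weighted or
learned fusion is out of scope.

## Label propagation

The fused similarity is symmetrically degree-normalized,
$MS = Dg^{-1/2}\, FMS \, Dg^{-1/2}$ with $Dg$ the diagonal of row sums,
which bounds the spectral radius by 1. (The normalization is stated in the
upstream description with one exponent flipped, $D^{-1/2} F D^{+1/2}$; that
form is similar to $F$ itself and does not bound the spectrum, so the
convergence guarantee only holds for the symmetric form implemented here —
the form used throughout the label-propagation literature it cites.)
Zero-degree rows are left all-zero rather than divided.

Propagation iterates
$$F(t+1) = \alpha\, MS\, F(t) + (1-\alpha)\, Y, \qquad F(0) = Y,$$
with $Y = A^\top$ (miRNA $\times$ disease) on the miRNA network and
$Y' = A$ on the disease network — the initial labels are the known
associations on both sides. The iteration contracts geometrically at rate
$\le \alpha$ and converges to the closed form
$(1-\alpha)(I - \alpha MS)^{-1} Y$, which the default `closed_form` mode
computes directly (exact, and faster at the problem sizes this method
targets, a few hundred entities per side; the iterative mode with `tol`
$10^{-6}$ max-norm and `max_iter` 1000 is available and agrees to
$10^{-8}$ in the tests). The final score matrix is

$$F = \beta F_M + (1-\beta) F_D^\top \quad (\text{miRNA} \times \text{disease}).$$

$\beta = 0.5$ is the documented upstream choice; $\alpha$ is unreported
upstream and defaults to 0.5 here. Orientation is fixed in one place:
$A$ is disease $\times$ miRNA, scores are miRNA $\times$ disease, and every
transpose is explicit in the code.

## Cross-validation harness

* **Global LOOCV**: each known association is masked in turn and re-scored;
  the held-out scores are pooled against the scores of all never-known
  pairs and summarised by the tie-aware rank AUC. Negatives are scored once
  from the full-data model; each positive from its own holdout model — the
  standard construction when held-out ranks are compared against all
  unconfirmed pairs.
* **Local LOOCV**: the same holdout scores, but each positive is compared
  only with the unconfirmed pairs of its own disease; it contributes its
  tie-aware win fraction $u$ within that candidate list, and the local AUC
  is the mean of the $u$ values (each held-out association weighted
  equally). Diseases with no unconfirmed pairs are skipped with a warning.
  Local is the harder criterion — no credit for inter-disease score
  calibration — and is expected to sit at or below the global AUC.
* **Repeated k-fold**: known associations are partitioned uniformly at
  random (no stratification) into $k$ disjoint subsets; each is masked in
  turn; one pooled AUC per repetition, final value the mean. The partition
  stream is fully determined by the seed. With $k = N$ and one repetition
  this reduces bit-for-bit to global LOOCV, which the tests assert.

Masking modes: `cv_mode = "full"` (default) re-runs the entire pipeline —
reconstruction included — on every masked network, the only fully
leakage-free protocol; the tests instrument the pipeline entry point to
verify that no masked edge is ever visible. `cv_mode = "fast"` reconstructs
and fuses once on the full data and only re-propagates the masked label
matrix per fold (exactly, via the closed form). Fast mode lets the
reconstruction see the held-out edges and is therefore mildly optimistic;
it is the practical choice when the full protocol (one pipeline run per
known association) is too expensive, and the benchmark suite uses it at the
60 x 80 scale. A `null_cv()` baseline replaces the model by a
uniform-random scorer under the same pooling, as a calibration control.

## Synthetic data

Real inputs (association catalogue, functional similarity, semantic
similarity) require downloads, so the package generates structurally
analogous stand-ins:

* `planted_network()` — a planted-block bipartite network: entities split
  into blocks, association probability `p_within` inside a block against a
  `p_noise` background, and similarity priors carrying `prior_strength`
  block signal plus symmetric uniform noise (unit diagonal, clipped to
  $[0,1]$). The defaults — 60 diseases x 80 miRNAs, 4 blocks, 0.35/0.02,
  prior strength 0.7, seed 7 — are the package's standard recoverability
  benchmark: strong but noisy community structure whose masked edges a
  working implementation must rank far above chance. On this benchmark the
  global-LOOCV AUC lands in the high 0.8s (seed-dependent), the
  reconstruction-only variant higher still, and the uniform-random control
  at 0.5.
* `powerlaw_bipartite()` — degrees drawn from a truncated discrete power
  law and matched by a configuration-model pairing, collapsed to a simple
  graph (realised degrees can fall below drawn ones); emulates the sparse,
  heavy-tailed degree regime of real catalogues.
* `figure2_fixture()` — a frozen 5 x 5 network whose first miRNA profile is
  $(1,1,0,1,0)$ and first disease profile $(1,0,1,0,0)$; the 16 cells not
  pinned by those two vectors are arbitrary frozen constants.
* `toy_dag()` — a rooted tree with optional extra cross-parents (always
  pointing at strictly shallower levels, so acyclicity is guaranteed by
  construction).

What the generators do *not* emulate: curation biases, the exact degree
statistics of any real catalogue, similarity matrices estimated from
shared-disease evidence (the priors here are block indicators plus noise),
or identifier semantics. Passing the planted-network tests demonstrates
that the machinery recovers recoverable structure without leakage; it does
not certify performance on any real catalogue. Reproducing published
real-data AUCs requires the original association and similarity files,
which the harness accepts through the same readers (see the README).

## Numerical choices and degenerate inputs

* Coordinate descent stops when the largest coefficient update falls below
  $10^{-12}$ (or at 10,000 sweeps); objective accuracy in the oracle tests
  is well below the $10^{-6}$ relative band.
* Entity name order is radix-sorted (C locale) everywhere, so results do
  not depend on the platform locale; file row order never matters.
* Ranking ties (prediction lists, AUC) use the average-rank convention.
* Similarity asymmetry up to $10^{-8}$ on file read is repaired by
  averaging; larger asymmetry is an error, as is any negative or
  non-finite entry.
* Propagation validates the spectral-radius bound before iterating and
  reports the residual if the iteration budget is exhausted.
* Problem sizes: unit tests run on 5-14 entities per side; the end-to-end
  benchmark on 60 x 80 with fast-mode cross-validation; these sizes were
  chosen so the full suite exercises every code path at interactive
  speeds.

## Known limitations

* Dense matrices throughout — appropriate for a few hundred entities per
  side, not for genome-scale catalogues.
* Fast-mode cross-validation is mildly optimistic (see above); full mode
  costs one pipeline run per fold.
* Equal-weight fusion and the unreported upstream parameters
  ($\alpha, \lambda, \varepsilon$) are fixed by this package's defaults;
  all are exposed for sensitivity analysis.
* Entities absent from the association matrix at prediction time are not
  imputed; isolated entities are retained with zero profiles and scored
  from priors and label injection only.
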