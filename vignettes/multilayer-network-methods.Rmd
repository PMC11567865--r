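---
title: "Multilayer signed partial-correlation networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer signed partial-correlation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptnet)
```

## The scientific problem

Cognitive decline in aging emerges from interdependent processes:
presynaptic molecular machinery (the SNARE interactome quantified as
targeted-proteomics peptide abundances), amyloid and tau pathological
peptides, cellular pathology (plaques, neurofibrillary tangles), and
protective lifestyle factors such as physical activity. `synaptnet`
models these jointly as a **multilayer Gaussian graphical model**: a
signed, weighted, undirected network over 71 variables in four layers
(48 synaptic peptides, 4 SNARE protein-protein interaction measures, 14
pathological peptides, 5 cellular pathology densities) whose edges are
partial correlations — conditional dependencies controlling for every
other variable in the network.

The cohort data this design targets are access-controlled, so the
package ships a first-class synthetic generator with planted ground
truth; every methodological claim the test suite makes is a statement
about recovery of known truth under study-realistic conditions, not a
reproduction of the original cohort estimates.

## Estimation model

Observed abundances are non-normal; we assume a Gaussian copula
(nonparanormal) model. Each column is Gaussianized by the shrunken
empirical CDF: a value with average rank $k$ among $m$ observed values
maps to $\Phi^{-1}(k/(m+1))$, rescaled to unit sample standard
deviation. This estimator is invariant under strictly increasing
marginal distortions (verified in the tests with $\exp$ and cube) and
avoids infinite quantiles without tuning; the Winsorized-ECDF
("truncation") variant is available via `variant = "truncation"`.

Missing values are handled by **pairwise deletion**: each correlation
uses the jointly observed rows (at least 10 required per pair). We
transform first, columnwise on available values, then correlate
pairwise; the reverse order is a sensitivity option a user can emulate
by subsetting before transforming. Pairwise deletion routinely yields
indefinite matrices, so the correlation matrix is repaired by clipping
eigenvalues at $10^{-8}$ and re-normalizing the diagonal, with a loud
message; the effective sample size is conservatively the minimum
pairwise-complete count.

The sparse precision matrix $\Theta$ maximizes
$\log\det\Theta - \mathrm{tr}(R\Theta) - \lambda\sum_{i\neq j}|\Theta_{ij}|$
(graphical lasso, penalty on off-diagonals only), solved by block
coordinate descent in compiled code with warm starts along a
log-spaced path of 100 penalties from
$\lambda_{\max} = \max_{i\neq j}|R_{ij}|$ down to
$0.01\,\lambda_{\max}$, to a tolerance of $10^{-6}$. The model is
selected by the extended BIC,
$-2L + |E|\log n + 4\gamma|E|\log p$ with $\gamma = 0.5$, the value
known to give parsimonious graphs with good sensitivity and
specificity. $|E|$ is the support of the penalized $\Theta$ (no
refitting); edges are reported as partial correlations
$w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. A pure-R
proximal-gradient solver of the same objective serves as an
independent oracle in the test suite; it is never used in the
pipeline.

One practical consequence of EBIC($\gamma=0.5$) worth knowing: an edge
is detectable only when roughly
$|w| \gtrsim \sqrt{2(\log n + 4\gamma\log p)/n}$ — about 0.27 for
$p = 71$, $n = 440$ and 0.31 at $n = 220$. Networks estimated from a
few hundred subjects are therefore sparse by construction, and weak
hub spokes are the first edges lost.

## Topology conventions

* **Strength** $s_i=\sum_j |w_{ij}|$ uses absolute weights; **expected
  influence** $EI_i=\sum_j w_{ij}$ keeps signs (the two coincide on
  all-positive networks, an identity the tests assert).
* Path-based measures use edge lengths $1/|w_{ij}|$ (stronger edge =
  shorter path), Dijkstra/Brandes via igraph. **Closeness** is the
  reciprocal of the total distance to reachable nodes within a node's
  component (isolated nodes score 0); the harmonic variant is a flag.
  **Betweenness** gives fractional credit to tied shortest paths.
* **Hubs** are nodes with betweenness above the mean plus two *sample*
  standard deviations.
* **Diameter** is the maximum finite shortest-path distance under the
  $1/|w|$ convention; an unweighted hop-count convention is available
  (`convention = "hops"`) because the two answer different questions
  and printed diameters in the literature do not always state which
  was used.
* **Global connectivity** is the sum of $|w|$ over unordered pairs and
  decomposes exactly into intra- plus inter-layer sums (a partition
  identity the tests check).
* The **scale-free** check fits a continuous power law to node
  strength by the Clauset–Shalizi–Newman recipe ($x_{\min}$ by KS
  minimization, tail exponent by MLE, at least five tail points) with
  a semiparametric bootstrap p-value; large p means "consistent with a
  power law". Applied to strength because the graphs are weighted; a
  binary-degree mode would need only passing a degree vector.

## Communities, balance, equivalence

Module detection runs on a **re-estimated synaptic-only network** (48
peptides), not on the synaptic block of the multilayer fit, so that
module structure is not distorted by conditioning on pathology
variables. The signed spinglass model (Reichardt–Bornholdt Potts
Hamiltonian with configuration-model null; negative edges penalize
within-module placement) is annealed via igraph's negative-edge
implementation inside a restart loop (default 20 restarts, spins
capped at 25, $\gamma^+=\gamma^-=1$); the package evaluates the signed
Hamiltonian itself and keeps the best-energy partition, so the restart
winner is well-defined and deterministic given the seed. Labels are
canonicalized by descending module size. Modularity is reported both
as the signed (Gómez) decomposition
$Q = (2m^+Q^+ - 2m^-Q^-)/(2m^+ + 2m^-)$ and as the positive-part
Newman value, since published "modularity" figures rarely say which
was computed. Transitivity is the unweighted global clustering
coefficient on the edge support.

Structural balance classifies each closed triangle by the product of
its edge signs: $(+,+,+)$ and $(+,-,-)$ balanced, $(+,+,-)$ and
$(-,-,-)$ unbalanced. Only signs matter (magnitude-weighted balance
indices are out of scope), absent edges break triangles, and the
census is validated against exhaustive enumeration. Structural
equivalence correlates two nodes' edge-weight profiles to all third
nodes (own entries excluded) and reports pairs above 0.95 — a default
on the strict side, since the question is whether two peptides are
redundant measurements.

## Two-group comparison

Subjects are split at the **median of average daily activity counts**;
ties go to the lower-activity group (a deterministic rule the
strictly-above/below wording of a median split leaves open). The
comparison re-runs the *entire* estimation pipeline — nonparanormal
transform, pairwise-complete correlation, EBIC-glasso — independently
per group, and builds the null by pooling subjects, reshuffling labels
with group sizes preserved, and re-estimating both networks per
permutation. Anything less than full re-estimation inflates type-I
error. Two-sided p-values use absolute differences with the $+1$
correction $p = (1 + \#\{|T^{perm}| \ge |T^{obs}|\})/(B+1)$. Holm
correction is applied per family: all union-support edge tests as one
family, centrality differences as a second, inter-layer connectivity
differences as a third. A failed permutation (degenerate resample) is
redrawn and counted; more than 1% failures aborts.

**Permutation granularity.** The smallest achievable p-value is
$1/(B+1)$, so a Holm-corrected edge discovery at level $\alpha$ is
*arithmetically impossible* unless the family size is below
$\alpha(B+1)$. At the published scale ($B = 10^4$) this is harmless;
at desk scale it dictates the experiment design. The validation suite
therefore calibrates type-I error at $B = 100$ (where only the single
global-connectivity test is in play) but runs the planted-edge power
experiment at $B = 1000$ on a compact 10-node two-layer study model
with the planted group-unique edge at partial correlation $-0.4$ and
$n = 220$ per group — the same effect size and sample size as the full
design, at a family size where detection is possible at all.

## Network-informed regressions

Module scores are per-subject means of member columns (missing values
skipped). Module–cognition associations fit one OLS model per module,
`cognition ~ score + age + sex + education`, with listwise deletion.
The moderation model regresses tangle burden on two p-tau peptides, a
synaptic module score and continuous activity, with all implied
two-way products and both three-way products; predictors are
mean-centered before products are formed (lower-order terms then read
as average-level effects; the three-way coefficients are
centering-invariant, which the tests verify numerically). No extra
covariates are included by default; pass `covariates =` to adjust.

## The synthetic generator

`synthetic_config()` encodes the study conditions: two groups of 220
subjects; 71 nodes in layers 48/4/14/5; six synaptic modules of 5–12
nodes (within the 2–14 range of the motivating design); a
betweenness hub in the synaptic layer (`STXBP1_6`, spokes into five
distinct modules) and one in the pathological layer (`tau_AT8_s202`);
a planted unbalanced $(+,+,-)$ triad among the two p-tau nodes and the
tangle node; one negative synaptic-to-p-tau edge (`CPLX2_2` to
`tau_AT8_s202`, partial correlation $-0.4$) present **only** in the
low-activity group; monotone non-normal marginals (identity, exp,
cube, cycling); 5% MCAR missingness; lognormal activity counts
matched to mean 1.94, SD 1.14; cognition loading 0.55/1.68 on modules
1/2 plus small age and education effects and unit noise; and tangle
burden following the moderation model with main effects 1.08, −0.97,
−1.11 and three-way coefficient 0.65.

Design choices that deserve justification:

* **SPD by diagonal dominance** (diagonal $=1+$ row absolute sum)
  rather than eigenvalue bumping, so the sign pattern of the true
  partial-correlation matrix is exactly the designed pattern. The
  group-unique entry is calibrated by a fixed-point iteration so the
  *implied partial correlation* equals the requested $-0.4$ despite
  the diagonal's dependence on it.
* **Edge magnitudes.** Precision off-diagonals of 2–3.2 within
  modules (spanning chain plus extras at probability 0.12) put typical
  true partial correlations at 0.25–0.45 — strong enough that
  EBIC($\gamma = 0.5$) recovers the graph at the study's sample sizes
  (per-group F1 ≈ 0.8 at $n = 220$), weak enough to remain plausible
  for peptide data. Hub spokes (precision 4–4.5) land near the
  detection boundary, which is exactly the behavior real hubs show.
* **Noise scale of tangle burden** (SD 0.36) is set so the three-way
  coefficient's standard error is ≈ 0.33 at $n = 440$, matching the
  uncertainty scale of the motivating analysis; 95% CI coverage of the
  planted 0.65 is 0.95 across replicates.
* The generator does **not** emulate SRM measurement-noise physics,
  batch effects, informative missingness, or longitudinal actigraphy
  structure. Passing tests therefore demonstrate statistical
  correctness of the pipeline under a Gaussian-copula world with MCAR
  gaps — not robustness to assay artifacts.

## Problem sizes used in validation

The suite's simulation experiments use: 10 random SPD instances
($p\le10$) for the unpenalized-glasso oracle; 20 seeds of a 20-node
sparse model at $n=440$ for EBIC recovery (mean F1 ≥ 0.8); 50 random
signed graphs with $p\le6$ (centralities) and $p\le8$ (balance)
against brute-force oracles; 10 seeds each for the planted-partition
spinglass checks; 200 null runs at $B=100$ and 20 power runs at
$B=1000$ for the permutation test; 500 coverage and 300 null
replicates for the moderation model; and one full 71-node
simulate-then-analyze run with $B=100$. Deeper single-checks (71-node
recovery, hub flagging, module ARI) run once per suite at fixed seeds.

## Known limitations

* Joint estimation of all 71 variables is assumed; per-layer
  estimation is available by composing `subnetwork()` /
  `select_model()` but is not the default reading.
* No bootstrapped edge-stability intervals, no mixed or ordinal
  graphical models, no covariate-adjusted network comparison, at most
  two comparison groups.
* The hub rule (mean + 2 SD of betweenness) is scale-free but brittle
  in small networks where betweenness ties at zero.
* Printed diameters depend on an unstated length convention; both
  conventions are implemented and reported explicitly.
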