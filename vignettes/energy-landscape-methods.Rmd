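---
title: "Methods: pairwise maximum-entropy energy landscapes and state-transition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise maximum-entropy energy landscapes and state-transition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and design choices behind
energyScape: what is computed, under which assumptions, with which defaults,
and where the genuinely open decisions were made.

## 1. The pairwise maximum-entropy model

The data are binary multivariate time series: at each time point the system
occupies one of $2^N$ states $V = (\sigma_1,\dots,\sigma_N)$,
$\sigma_i \in \{0,1\}$. Continuous signals are binarized at a threshold
(default 0, the natural choice after mean-centering such as global-signal
regression); a value exactly at the threshold maps to 0, a fixed convention
that keeps runs reproducible — for mean-centered continuous data exact
zeros are measure-zero, so the convention is immaterial in practice.

The maximum-entropy distribution constrained to match the empirical first
moments $\langle\sigma_i\rangle$ and second moments
$\langle\sigma_i\sigma_j\rangle$ is the Boltzmann distribution
$p(V) \propto e^{-E(V)}$ with

$$E(V) = -\sum_i H_i\sigma_i - \sum_{i<j} J_{ij}\sigma_i\sigma_j .$$

The model treats samples as exchangeable: temporal order carries no
information beyond state frequencies. Real recordings are autocorrelated;
the synthetic module therefore offers both i.i.d. (`sampleExact`) and
temporally correlated (`sampleGibbs`) inputs so analyses can be stress-tested
against that assumption.

### Fitting

`fitPairwiseMEM` iterates multiplicative log-ratio updates,

$$H_i \leftarrow H_i + \alpha_g \log\frac{\langle\sigma_i\rangle}
{\langle\sigma_i\rangle_m},\qquad
J_{ij} \leftarrow J_{ij} + \alpha_g \log
\frac{\langle\sigma_i\sigma_j\rangle}{\langle\sigma_i\sigma_j\rangle_m},$$

recomputing the model moments $\langle\cdot\rangle_m$ by full enumeration at
every iteration. Key choices:

* **Convergence test.** The "gradient" tested against the tolerance is the
  maximum absolute value of the log-ratio terms themselves — exactly the
  quantities the updates add — with default `tol = 1e-5`. A model matching
  its targets is a fixed point ($\log 1 = 0$).
* **Learning rate.** `aG = 0.1` (units: log-moment-ratio per iteration).
  The exact-enumeration likelihood is concave in $(H, J)$, so the fixed
  small step converges reliably; typical N = 6–10 problems converge in
  $10^3$–$10^4$ iterations.
* **Initialization.** $H$ at the independent (logit) solution, $J = 0$:
  the exactly solvable first-order model is the natural starting point, and
  an `init` argument allows warm restarts.
* **Iteration cap.** `maxIter = 5e5`; hitting the cap flags
  `converged = FALSE` in the `FitResult` instead of raising, since a
  near-converged model is still usable and the caller can inspect the final
  gradient.
* **Boundary moments.** Log-ratio updates diverge when a target moment is
  exactly 0 or 1; moments estimated from $T$ samples are clipped to
  $[1/(2T),\,1-1/(2T)]$ (`clipMoments`), half the resolution of the
  estimator.
* **Numerics.** The Boltzmann distribution is always computed through a
  log-sum-exp shift, so arbitrarily large $|E|$ cannot overflow.
* **Enumeration limit.** All exact operations require $N \le 20$
  ($2^{20} \approx 10^6$ states). No pseudo-likelihood or mean-field
  fallback is provided: beyond the enumeration limit the quantities
  downstream (exact minima, exact barriers) would no longer be exact, and
  that exactness is the point of the package.

### Fit-quality metrics

With $p_N$ the empirical distribution, $p_1$ the fitted independent model
and $p_2$ the fitted pairwise model, `fitMetrics` computes Kullback–Leibler
divergences $D_k = \sum_l p_N \log (p_N / p_k)$ (terms with $p_N = 0$
contribute zero), entropies $S_k$, the empirical entropy $S_N$, and

$$r_D = \frac{D_1 - D_2}{D_1},\qquad
r_S = \frac{S_1 - S_2}{S_1 - S_N},\qquad ER = r_S / r_D.$$

Natural logarithms are used throughout: every reported metric is a ratio of
same-base quantities, so the base cancels. The reliability $ER$ relates the
divergence-based and entropy-based improvement measures; it equals 1 when
the pairwise model reproduces the empirical distribution exactly. Whether
$ER$ should combine $r_S$ and $r_D$ as a ratio or a product is ambiguous on
its face (both equal 1 in the error-free case); the ratio is the default and
`erMode = "product"` exposes the alternative. $r_D$ is undefined when the
empirical distribution is already first-order ($D_1 = 0$), and $r_S$ when
$S_1 = S_N$; both raise informative errors rather than returning NaN.

## 2. Energy landscape

Two states are neighbors iff their Hamming distance is exactly 1 (no
diagonal moves). A **local minimum** has strictly lower energy than all $N$
neighbors; ties therefore disqualify, and any exact energy tie between
neighbors triggers a warning because downstream tie-breaking then depends on
code order. A consequence worth noting: two adjacent states can never both
be minima, so a transition path always has at least one interior state
unless it is degenerate.

### Barriers

The pair threshold $E_{th}(i,j)$ is the minimax (bottleneck) energy: the
minimum over all single-flip paths of the maximum energy en route. The
production algorithm is an **energy-ascending union-find filtration**:
states are inserted in increasing energy order (ties by code) and merged
with previously inserted neighbors; the threshold for a minima pair is the
energy of the state whose insertion first joins their components. This is
provably equivalent to the descriptive procedure of repeatedly finding a
shortest connecting path, thresholding at its maximum energy, and deleting
higher-energy states until disconnection — that literal loop is retained as
`pairThresholdOracle` and the equivalence is itself asserted in the test
suite on randomized systems. (The literal loop needs one amendment to
terminate under exact ties: when a deletion pass removes nothing, the states
attaining the threshold — never the endpoints — are removed.)

Barriers follow as $E_B(i,j) = E_{th} - \max(E_i, E_j)$ for the symmetric
pair barrier and $E_{th} - E_i$ for the directed barrier from $i$; the pair
barrier equals the smaller directed one. The transition rate is
$e^{-E_B}$, transition-state theory with unit prefactor.

The **disconnectivity tree** is the single-linkage merge structure of the
threshold matrix. Bottleneck thresholds are ultrametric
($E_{th}(i,k) \le \max(E_{th}(i,j), E_{th}(j,k))$), so the tree's cophenetic
heights reproduce the matrix exactly; this is asserted rather than assumed.

### Pathways

`minimaxPath` returns, among all paths confined to states with energy
$\le E_{th}$ (all of which attain the bottleneck), the shortest one, with
remaining ties broken by the lexicographically smallest code sequence —
a total order, so path extraction is deterministic. Pairs are oriented from
the higher-energy minimum (source) to the lower (equal-energy pairs:
smaller code first). The rate-determining transition state (TS) is the
highest-energy state on the path; if several tie, the one nearest the
source. Interior path states that are themselves minima are reported as
intermediate states.

## 3. State-transition networks

* **STN-FS.** Every consecutive state pair on every pathway becomes a
  directed edge carrying the whole pathway's rate $e^{-E_B}$ (the rate is a
  property of the pathway, not the step). When pathways share a step edge,
  the larger rate is kept and a multiplicity counter records the sharing —
  deduplication is otherwise underdetermined.
* **STN-GM.** The restriction to the $m-1$ pathways whose target is the
  global minimum.
* **STN-LM.** Nodes are the minima plus distinct TSs; each pathway
  contributes source→TS and TS→target edges at the pathway rate, parallel
  contributions keeping the maximum. Because adjacent minima cannot exist
  under the strict-minimum rule, the TS never coincides with an endpoint in
  practice; a defensive direct-edge branch handles it regardless (logged).
* **Degrees** are computed on the collapsed undirected simple graph
  (reciprocal and parallel edges merged) — the natural reading of a degree
  histogram for a pathway network. Nodes above mean + 2 SD are flagged as
  hub candidates; the flag is reported, never asserted, since hubness is a
  descriptive notion.
* `removeStateAndReroute` deletes one named state (never a minimum under
  analysis) and re-extracts every pathway on the remaining state space;
  thresholds can only rise, and pairs left unconnected are flagged.
  Multi-state removal composes through `additionalExcluded`.

## 4. Grouping and statistics

`clusterLocalMinima` represents each minimum by its row of pairwise values —
energy barriers, or rates $e^{-E_B}$ — with self-entry 0, and applies UPGMA
(average-linkage) to the Euclidean distances between these feature vectors.
Pairing UPGMA with a Euclidean metric only makes sense on vectors, hence the
row representation as default; `directDissimilarity = TRUE` instead treats
the pairwise matrix itself (1 − rate in rate mode) as the dissimilarity for
comparison. The default cut is two groups, matching the two complementary
families the two-community phenomenology produces; the cut is configurable.

Pearson correlations (`correlatePearson`) report two-sided p-values from the
t-distribution with $n-2$ degrees of freedom — the standard approximation;
no permutation test is attempted. `analyzeGroupTransitions` tabulates both
directions of every pathway (directed barriers differ by endpoint energies)
tagged intra-/inter-group, which feeds the Hamming-distance/barrier and
Hamming/path-length analyses.

`sweepAlpha` rescales all couplings $\alpha J$ over a grid (default 0.0–5.0
in steps of 0.1) and summarizes each perturbed landscape; both weakening and
strengthening the couplings tends to prune stable states relative to the
fitted $\alpha = 1$ system. `permuteParameters` provides the randomized
controls (shuffled $H$, shuffled couplings, redrawn values).

## 5. The synthetic generator

The generator emulates the statistical regime the analysis assumes:
10–20 binary channels sampled from the Boltzmann distribution of a pairwise
model whose couplings are mostly organized into two communities (positive
within, negative between), yielding a multistable landscape whose minima
occur in complementary pairs separated by a high barrier.

Two design choices deserve explanation because the naive construction fails
to produce that phenomenology:

* **Baseline fields are centered on the flip-symmetric point**
  $H_i = -\tfrac12\sum_j J_{ij} + \mathcal N(0, \text{hScale})$ for the
  structured topologies. At that point the equivalent $\pm1$ spin system has
  zero external field, the landscape is (nearly) invariant under global
  activity inversion, and minima therefore occur in complementary pairs.
  With fields drawn independently of the couplings the symmetry is absent
  and complementary pairs essentially never arise. `hScale` (default 0.05)
  sets how strongly the symmetry is broken; the random topology draws
  $H_i \sim \mathcal N(0, \text{hScale})$ directly.
* **Couplings are sparse** (each pair coupled with probability `density`,
  default 0.6). A fully coupled two-community model is gauge-equivalent to a
  homogeneous ferromagnet — flipping one community's spins makes all
  couplings positive — and such a system has exactly two stable states.
  Missing and weak links carry the domain substructure on which additional
  minima (and their complements) appear, the regime heterogeneous empirical
  couplings actually occupy.

Defaults (nRegions = 10, jScale = 0.5, hScale = 0.05, density = 0.6) were
frozen after a coarse design scan as the smallest system that robustly shows
several complementary minima pairs, a two-family UPGMA split, and the
inverted-U response of the minima count under coupling scaling. They are the
package's study condition, not tuning knobs.

What the generator does **not** emulate: hemodynamics or any forward model,
spatial maps, inter-subject variability, scanner noise (except the additive
Gaussian of `sampleSurrogateContinuous`), and the slow autocorrelation of
real recordings beyond what single-site Gibbs dynamics produces. Passing
tests on synthetic data therefore demonstrate algorithmic correctness and
statistical consistency, not that any particular empirical system satisfies
the pairwise-model assumptions.

Samplers: `sampleExact` inverts the enumerated CDF (i.i.d.); `sampleGibbs`
runs sequential single-site sweeps with
$p(\sigma_i = 1 \mid \text{rest}) = \text{logistic}(H_i + \sum_j J_{ij}
\sigma_j)$, default burn-in 1000 sweeps; sweep order is fixed (sites
$1..N$), so chains are reproducible given the seed.

## 6. Problem sizes and determinism

The shipped tests run the full machinery at N = 5–10 with series up to
$10^6$ samples and randomized-model sweeps of up to 100 systems — sizes at
which every reference quantity is computable exactly by an independent
oracle (brute-force neighbor scans, literal-loop thresholds, counting-pass
histograms), which is what makes them informative. All randomness flows
through explicit integer seeds; model generation, sampling and permutation
save and restore the caller's RNG state. Rebuilding any result from the
same configuration and seed yields byte-identical tabular, JSON and GraphML
outputs (provenance records, which carry wall-clock timestamps, are the one
exception).

## 7. Known limitations

* Exact enumeration bounds everything at $N \le 20$; memory for the
  $2^N \times N$ state matrix is the practical ceiling.
* The union-find filtration is pure R; at $N = 20$ a full barrier matrix
  takes minutes. Typical published analyses ($N \le 19$, a dozen minima)
  are well within reach.
* No temporal model is estimated: transition rates derive from barriers
  (transition-state theory), not from observed dwell times or a Markov
  chain over consecutive samples.
* The degree, hub and clustering conventions above are reasonable defaults
  for pathway networks, but alternative readings (directed degrees, other
  linkages) are legitimate; the accessors expose the underlying igraph
  object so users can apply their own.
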