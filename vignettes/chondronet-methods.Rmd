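---
title: "Models and methods in chondronet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chondronet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondronet)
```

chondronet studies regulatory switches such as the SOX9/RUNX2 switch of
growth-plate chondrocytes from two directions: simulating a curated signed
network as a logical model, and reverse engineering the network from
expression data.  This vignette is the package's account of the underlying
models, the choices that were genuinely open, and what the shipped tests do
and do not establish.

## The additive logical model

### Semantics

Every node carries two variables in [0, 1]: a *fast* one standing for protein
activity and a *slow* one standing for gene expression.  The node's **total
activity** is always the product of the two — a gene that is transcribed but
whose protein is inactive contributes nothing, and vice versa.

A variable is updated from the totals of its regulators through the
normalized additive input

$$ s_i \;=\; \frac{\sum_{j \in \mathrm{act}(i)} w_{ji}\,x_j \;-\;
               \sum_{j \in \mathrm{inh}(i)} w_{ji}\,x_j}{\sum_j w_{ji}}
   \;\in\; [-1, 1], $$

restricted to the incoming edges of the variable's kinetics class.
Normalizing by the total incoming weight keeps $s$ comparable across nodes
regardless of in-degree.  A node with no incoming edge of a class holds its
current value: nodes without any regulation act as external inputs (growth
factors, stimuli) whose level is set by the experimenter.

Edges are partitioned into **priority classes**: fast edges model
post-translational regulation, slow edges transcriptional regulation.  One
macro-step of the scheduler (i) relaxes all fast variables by random-order
asynchronous updates until no fast variable moves by more than the
convergence tolerance — a quasi-steady-state reading of "fast reactions have
higher priority" — and then (ii) updates exactly one randomly chosen slow
variable.  Asynchronous single-variable updates are the standard choice for
logical GRNs because they avoid the spurious synchronous artefacts of
parallel updating.

### Activation function

The literature on this model family specifies the additive input but not the
shape of the response, so the package makes the choice explicit and
configurable:

* `activation = "logistic"` (default): $f(s) = 1/(1 + e^{-k s})$ with
  steepness $k$ (default 10).  This provides the multi-valued resolution —
  any value between 0 and 1 — that distinguishes the model from a Boolean
  network.
* `activation = "step"`: the infinite-steepness limit; $s > 0$ switches the
  variable on, $s < 0$ off, and $s = 0$ holds the current value.  With unit
  weights this recovers Boolean threshold dynamics exactly, which is what the
  test suite exploits: on every generated network of up to four nodes the
  step-activation stable states are checked against a brute-force Boolean
  fixed-point enumeration over all $2^n$ states.

### Stable states, basins, perturbations

`find_stable_states()` simulates from a battery of initial conditions — all
Boolean corners of the unclamped nodes when there are at most
`n_initial_states` of them, uniform random states otherwise — and certifies
every endpoint with a fixed-point check: re-evaluating each variable must
move it by no more than `convergence_tol`.  The basin fraction of a state is
the share of initial conditions that reached it; interpreted biologically, a
larger basin means the corresponding phenotype is easier to reach.

Perturbations clamp a node: knockout fixes fast = slow = 0, over-activation
fixes both at 1, and `dose_response()` clamps the slow variable at
intermediate levels (with the protein fully active), so that a dose of 0
coincides with the knockout and a dose of 1 with the over-activation.
Clamped nodes are removed from the update schedule entirely, which makes
clamp dominance (the total never deviates) structural rather than numerical.
A marker state is labelled "M+" when marker M's total exceeds 0.5 and every
rival marker is at or below 0.5, mirroring the SOX9+/RUNX2+ dichotomy.

### Numerical choices

* `convergence_tol = 1e-6` is the fixed-point certificate tolerance;
  `fast_relaxation_max_iters = 1000` bounds each quasi-steady-state
  relaxation; the macro-step budget defaults to $10 n^2$.  All are
  conservative for the tens-of-nodes networks this model family targets.
* Endpoint grouping uses a separate tolerance of $10^{-4}$: two trajectories
  entering the same attractor each stop within `convergence_tol` of the fixed
  point, so their mutual distance is only bounded by a multiple of it.
* State initialization: the slow variable carries the requested initial
  level and fast starts at 1, except for nodes regulated *only* through fast
  edges, where fast carries the level.  This keeps the initial total equal to
  the requested level in every kinetics configuration, and makes an all-fast
  network reduce exactly to the Boolean case.
* A fast relaxation that fails to converge (a limit cycle within the fast
  class) aborts the trajectory, which is then reported as non-converged
  rather than consuming the full step budget; basin fractions therefore sum
  to at most 1.

## Network inference

All methods consume a genes × samples matrix of normalized log-scale
expression and emit a confidence matrix; `rank_edges()` turns confidences
into a ranked edge list with average-rank ties.  Defaults follow common
practice where the choice is not scientifically loaded:

* **Mutual information** uses equal-frequency binning with
  `floor(sqrt(n_samples))` bins and the plug-in estimator in bits —
  parameter-light and adequate at the sample sizes of microarray
  compendia.  Constant genes cannot be binned and are refused by name.
* **CLR** z-scores each MI value against both genes' background MI
  distributions and combines the positive parts in quadrature.
* **ARACNE** prunes each triangle by the data-processing inequality with
  tolerance 0.15 (the conventional default); tolerance 1 disables pruning.
* **MRNETB-style scoring** uses greedy forward-selection
  maximum-relevance/minimum-redundancy on the MI matrix; the pairwise
  confidence is the larger directed score, floored at 0.
* **Tree-ensemble importance** fits one random regression forest per target
  (ranger, impurity importance, per-target normalization to sum 1).
* **Stability selection** fits lasso paths on randomized half-sample
  resamples with predictor reweighting uniform on [0.4, 1]; a regulator is
  selected when it is among the first $L = \lceil 0.2\,p \rceil$ variables to
  *enter* the path.  Entry order was chosen over "the largest path point with
  at most $L$ nonzero coefficients" because the latter depends on the
  resolution of the lambda grid, which itself changes with penalty factors —
  making runs at different prior strengths incomparable.
* **Partial correlation** inverts a correlation matrix shrunk toward the
  identity with the Schafer–Strimmer analytic intensity; shrinkage
  guarantees invertibility when samples are scarce, at the price of a small
  upward bias on indirect partial correlations when profiles are strongly
  collinear.
* **Bayesian scoring** is an exhaustive parent-set enumeration under a BDeu
  metric (equivalent sample size 1, uniform structure prior), gated to at
  most 15 genes and 3 parents; the edge confidence is the posterior-weighted
  frequency of parent sets containing the regulator.  An exhaustive scorer
  was preferred over an MCMC structure sampler as an honest desk-scale scope.

### Consensus

`consensus_rank()` is rank-based voting: each method's output is collapsed to
an undirected ranking over all unordered gene pairs (the stronger of the two
directed scores carries the pair, since "an interaction exists between two
components" is an existence claim), converted to average-tie ranks, and the
consensus score of a pair is its mean rank.  Missing pairs take the worst
possible rank — absence of evidence is ranked last.  Because only ranks
enter, the consensus is invariant to method order and to any strictly
monotone rescaling of a method's scores.  Ties in the final list are ordered
lexicographically for determinism.

## Prior-weighted inference

Curated knowledge enters as a square sign matrix over the gene set; the
packaged growth-plate prior holds nine known directed interactions among the
13 transcription factors.  Inside the stability selection, the penalty of
regulator $r$ for target $t$ is divided by $1 + g\,|\mathrm{prior}(r,t)|$:
prior-supported regulators are cheaper to select, with $g$ the single
strength dial.  Three properties anchor the design:

* $g = 0$ (or an all-zero prior) reproduces the no-prior method bit for bit
  at equal seed — the random resamples and reweightings are drawn before and
  independently of the penalties.
* Prior signs act only through their absolute value during selection; the
  fitted coefficient's sign is reported next to the prior sign but never
  constrained, since nothing in the mechanism justifies a hard sign
  constraint.
* Expression is gene-wise standardized before regression so that a given $g$
  has comparable leverage across targets.

`compute_ssr()` reports the sum of squared residuals between the
standardized data and the fitted linear predictions; with all-zero
coefficients it equals $(n_\mathrm{samples}-1) \times n_\mathrm{genes}$.
`g_scan()` repeats the fit over a grid of $g$ values with the same seed and
scores each directed ranking against the directed prior network; the scan
shows whether the prior can be adopted without sacrificing data fit.  The
directed reading is deliberate: the prior is a directed sign matrix and the
method scores each orientation separately (the StoT/TtoS columns of the
pair report).  Collapsing to undirected pairs before scoring is also
possible, but near the performance ceiling the two-orientation maximum
concentrates false-positive selection mass and can make the scan
non-monotone in $g$ — a ceiling artefact of the collapse, not of the prior
mechanism (every prior-supported directed edge's selection frequency is
itself non-decreasing in $g$ on data generated from the prior network).

## Evaluation

`label_predictions()` completes a ranking over the full candidate-pair
universe of the gold network's node set (unranked pairs appended at score
$-\infty$), labels each pair by the gold standard — in undirected mode an
edge in either direction counts — and excludes self-pairs, which no method
in scope scores.  The ROC curve steps once per tied score block and its
trapezoidal area equals the Mann–Whitney probability of correct ordering
with ties counted one half; the test suite asserts this equality against a
brute-force pair-counting oracle on random tied instances.  The AUPR is the
non-interpolated step sum (average precision), the standard in GRN
benchmarking; a ranking with all gold edges first scores exactly 1.  Because
appending negatives at the bottom of a ranking moves the pair-average AUROC
toward its asymptote, only the AUPR is invariant to padding a ranking with
trailing false predictions — one reason both curves are always reported.
`precision_at_k()` is available where only the leading predictions matter.

## The synthetic-data generator

The generator emulates the design of the published growth-plate microarray
compendium from a known ground truth, so that recovery can be measured
exactly.  `generate_network()` samples a signed directed graph (default: 13
genes, edge probability 0.15 per ordered pair, half activating, weights
uniform on [0.5, 1], no self-loops, isolated nodes resampled away).
`simulate_expression()` solves the steady state $x = Wx + p + \varepsilon$
per sample, with $W$ the signed weighted adjacency rescaled to spectral
radius 0.8 (guaranteeing a unique solution), $p$ a design-dependent
perturbation and $\varepsilon$ Gaussian noise (default sd 0.25):

* *multifactorial* — every gene mildly perturbed in every sample
  (replicate/patient-style data; default 60 samples, perturbation sd 1);
* *knockout* — one gene clamped to exactly 0 per sample, cycling;
* *zones* — the network's input genes shifted along an ordered gradient over
  the growth-plate zones (resting, proliferating, maturing, hypertrophic;
  two replicates each by default), monotone in the drivers when noise-free;
* *treatment* — a balanced treated/control contrast on the input genes.

`simulate_growth_plate_study()` concatenates five such studies
(12 + 8 + 15 + 12 + 18 samples) with per-study metadata, mirroring the mix
of treatment and zonal designs in the published compendium.

The generator is linear-Gaussian by design: it gives analytically
controllable signal for inference benchmarking, and a second route — sampling
states from the logical model — is available through the simulator itself for
cross-module checks.  What passing tests on these data show is that the
pipeline recovers *linear steady-state* dependency structure at realistic
sample sizes; they do not show robustness to microarray probe artefacts,
normalization residue, saturating (strongly nonlinear) regulation, or hidden
confounders, none of which the generator emulates.

## Problem sizes used by the shipped checks

The test suite runs the statistical properties at the scale the package's
defaults define: 13-gene networks with 60 multifactorial samples; 20
generator seeds for the consensus-recovery check (consensus mean AUROC at
least matches the weakest member and exceeds chance, with a frozen
regression bound); 20 seeds × four prior strengths
($g \in \{0, 1, 5, 10\}$) for the monotone-adherence check; and the full
$2^n$-state Boolean oracle on batteries of networks with up to four nodes.

## Known limitations

* The additive scheduler is a faithful-in-spirit reconstruction of the
  priority-class model family, not a bit-exact port of any published
  implementation; the original update formula lives in cited work that does
  not specify it completely.
* The full curated chondrocyte network of the source model family is
  published only as a figure; the package therefore ships the 13-gene node
  list and the nine-interaction prior as in-package fixtures, plus a toy
  bistable switch as the simulator's worked example.  Claims that depend on
  the full topology (which factors are required for the hypertrophic state
  in the real network) are out of reach of the shipped fixtures.
* Whether the original bidirectional confidences are posterior probabilities
  or selection frequencies is not documented; the package defines them as
  selection frequencies.
* Exhaustive Bayesian scoring is exponential in the parent bound and gated
  to small gene sets; the shrinkage partial correlation inherits the usual
  small-sample bias of analytic shrinkage under strong collinearity.
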