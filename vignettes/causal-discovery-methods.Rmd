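---
title: "Causal discovery from perturbed single-cell signaling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal discovery from perturbed single-cell signaling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocausal)
```

## The analysis problem

Multiplexed single-cell perturbation studies — gated mass-cytometry panels
are the motivating case — measure a handful of phosphoprotein markers in
thousands of cells under a crossed design: an extracellular **activator**
applied or withheld, an **inhibitor** titrated over a ladder of dosage
indices, the whole plate layout repeated across inhibitors, and everything
stratified by gated cell **subpopulation**. Two structural features of this
design carry causal information:

1. the activation indicator is *exogenous* — it is set by the experimenter
   and cannot be caused by any intracellular marker; and
2. inhibitor dosages act as *shift interventions with unknown targets* —
   each dosage adds noise of unknown location and magnitude while leaving
   the wiring between markers intact.

`cytocausal` implements two complementary estimators that exploit these
features, an exact Bayesian scoring scheme for checking predictions in
independent data, a ranked-precision evaluation against a directed pathway
ground truth, and a synthetic-data generator that reproduces the study
layout from a known linear causal model so that the whole pipeline is
testable end to end.

## The generative model

All components share one model class. For markers $x \in \mathbb{R}^p$,

$$ x = Bx + aA + c + \varepsilon, $$

where $B$ is the connectivity matrix ($B_{ij} \neq 0$ exactly when marker
$j$ directly causes marker $i$, $\operatorname{diag}(B) = 0$), $A \in
\{0,1\}$ is the exogenous activation indicator with direct-effect vector
$a$, $c$ is the shift intervention of the current environment
(mean zero, *diagonal* covariance $\Sigma_c^e$), and $\varepsilon$ is noise
with covariance $\Sigma_\varepsilon$ whose off-diagonal entries encode
latent confounding. Cycles are allowed; the observed cells are equilibrium
draws $x = (I-B)^{-1}(aA + c + \varepsilon)$, which exist whenever the
spectral radius of $B$ is below one (enforced by the model validity check).
The implied covariance,

$$ \Sigma_x^e = (I-B)^{-1}\,(\Sigma_\varepsilon + \Sigma_c^e +
   \operatorname{var}(A)\, a a^\top)\,(I-B)^{-\top}, $$

is available in closed form (`populationCovariance()`) and serves as the
oracle for most of the test suite.

### What the generator emulates — and what it does not

`makeStudyDesign()` defaults mirror the motivating study class: 14
phosphoprotein markers, 11 activators, 27 inhibitor plates with 8 dosage
indices each, dose zero carrying no intervention on any plate (so the 27
dose-zero plates are true replicates), and per-condition cell counts drawn
log-uniformly between 8 and 300 — real gated subpopulations range from
fewer than ten cells to a few hundred, and the generator must exercise the
small-table code paths. Inhibitor schedules raise the intervention variance
linearly with dosage index on a small random target set, and activator
effects are positive mean shifts (activation increases phosphorylation) of
magnitude 0.8–1.5 on an arcsinh-like analysis scale.

Deliberately *not* modeled: raw ion counts and their transformation
(data are generated directly on the analysis scale, since gated exports are
already preprocessed), heavy-tailed or zero-inflated marker noise, gating
error, bead normalization and batch drift. Passing tests therefore
demonstrate correctness of the estimators *under the linear-Gaussian
equilibrium model*, not robustness to those real-data pathologies — the
motivating studies themselves report substantial unexplained variation even
between technical replicates.

Coefficient magnitudes are drawn from $|b| \in [0.3, 0.9]$ by default; the
floor keeps near-cancellation (faithfulness violations) improbable, which
matters because the trio tests interpret *absence* of dependence
structurally. One master seed determines everything; per-condition seeds
are derived deterministically from the condition key, so studies are
reproducible byte for byte.

## Conservative local causal discovery (CLCD)

For a trio (activation $A$; candidate cause $S$; candidate effect $T$) the
chain $A \to S \to T$ is, among all three-variable structures with $A$
constrained to be a source — *even allowing latent confounders* — the only
one implying exactly the pattern: all pairs dependent, $S$ and $T$
dependent given $A$, $S$ and $A$ dependent given $T$, and $A \perp T \mid
S$. `evaluateTrio()` tests all six statements:

| statement | test |
|---|---|
| $S$–$A$, $T$–$A$ marginal | Welch two-sample t |
| $S$–$T$, $S$–$T \mid A$ | Fisher z on the (partial) correlation |
| $S$–$A \mid T$, $T$–$A \mid S$ | logistic likelihood ratio, $\chi^2_1$ |

Two thresholds make the rule conservative: dependence is asserted only when
$p < \alpha$ (default $10^{-3}$) and independence only when $p > \beta$
(default $0.15$); anything between is *uncertain* and blocks the call.
Raising $\beta$ therefore removes predictions (the required independence
becomes harder to accept) while raising $\alpha$ adds them —
`thresholdSensitivity()` re-applies the decision rule over a grid using
p-values computed once.

A prediction is emitted only when the same chain direction holds in at
least `minSupport` (default 10) of the dose-zero replicate plates (default
27), and conditions with fewer than 20 cells are never tested. If both
directions independently reach support the trio is discarded as
conflicting. Design choices worth stating: the t-test is the Welch variant
because per-condition cell counts and variances differ; conditioning on $A$
in the Fisher z-test includes $A$ as a 0/1 regressor (rather than
stratifying and pooling); the logistic test is likelihood-ratio based with
a Wald variant behind a flag; and both orderings of every pair are always
evaluated, with replicate support counted per ordering.

## Connectivity estimation from dosage environments

With at least three environments $e$ (dosage indices of one inhibitor
context), the model implies

$$ (I-B)\,\Sigma_x^e\,(I-B)^\top = \Sigma_\varepsilon + \Sigma_c^e, $$

with the right-hand side the sum of an environment-invariant part and a
diagonal part. Differencing each sample covariance against the pooled
average cancels $\Sigma_\varepsilon$, leaving matrices that $(I-B)$
simultaneously diagonalizes. `jointDiagonalize()` minimizes the summed
squared off-diagonals with a multiplicative first-order update scheme
(identity initialization, per-pair 2×2 linear solves, step cap 0.9,
backtracking so each sweep is monotone, tolerance $10^{-10}$, at most 1000
sweeps). The diagonalizer is then only determined up to row permutation and
scale; `resolveScalePermutation()` fixes the permutation by a linear sum
assignment maximizing $\sum_i \log |W_{\sigma(i),i}|$ and rescales rows to
unit diagonal, giving $\hat B = I - W$. Intervention variances are
recovered as the diagonal of $(I-\hat B)\Sigma_x^e(I-\hat B)^\top$ minus
its environment-wise minimum, clipped at zero.

Identifiability needs care: three environments give exactly as many
off-diagonal constraints as $W$ has free parameters, so the sample
residual is numerically zero and the estimate absorbs sampling noise
entirely. Accuracy then hinges on the *conditioning* of the design — for
every marker pair the centered intervention-variance profiles across
environments must be far from proportional. The package's reference
three-environment design uses profiles $(0,0,0)$, $(5,0.1,1)$,
$(0.1,5,2.5)$ for exactly that reason; single-inhibitor dosage ladders
whose targets scale together are the canonical *weakly identified* case,
which is why many real contexts yield empty or unsuccessful fits. With four
or more environments the system is overdetermined and the residual itself
becomes a model-violation diagnostic: `diagnoseModel()` compares the
observed residual against a parametric bootstrap from the fitted model and
flags failure when it exceeds the bootstrap 95th percentile (hidden
intervention targets and correlated interventions are detected this way).

`stabilitySelect()` guards the edge set: the estimator is refit on 100
half-subsamples of every environment, each refit keeps its $q$
largest-magnitude coefficients with
$q = \lfloor\sqrt{E(V)\,(2\pi_{thr}-1)\,p(p-1)}\rfloor$ (the standard
expected-false-selection bound solved for $q$; $E(V)=5$, $\pi_{thr}=0.75$,
so $q = 21$ for $p = 14$), and only edges selected in more than
$\pi_{thr} \cdot 100$ refits survive. The whole result is discarded when
fewer than 75 of 100 refits diagonalize successfully. Note the $E(V)$
guarantee is across datasets: within one dataset, when $q$ exceeds the
number of real edges the spare slots are filled by that dataset's largest
noise coefficients, which can be individually stable — the control is on
their expected number, verified empirically under $B = 0$.

## BGe consistency scoring

CLCD predictions can be checked in independent data sets measuring the same
markers and activators. All twelve DAGs over $\{A, S, T\}$ with $A$
source-constrained are scored exactly with the Bayesian Gaussian-equivalent
(BGe) marginal likelihood, computed from Normal–Wishart subset marginal
likelihoods so that Markov-equivalent structures score identically (the
suite checks equality to $10^{-8}$). A prediction is *consistent* when the
chain $A \to S \to T$ is the unique argmax, *conflicted* when the selected
network contains the reversed edge $T \to S$, and *other* otherwise — exact
ties are conservatively *other*, which is also what happens when activation
has no effect and the $S$/$T$ orientation is an equivalence tie.
`consistencyAnalysis()` compares the observed consistent fraction against
stratified random predictions (same count per activator × subpopulation
stratum, 10 iterations) with a one-tailed t-test.

Hyperparameters are not dictated by the method's sources: this package uses
prior mean = sample mean, $\alpha_\mu = 1$, $\alpha_w = p + 2 = 5$ and an
identity prior scale, all configurable through `bgePrior()`. The binary $A$
is scored as a 0/1-valued variable inside the Gaussian framework — a
pragmatic convention (no conditional-Gaussian variant is used), flagged
here because it makes the $A$-marginal terms formally misspecified while
leaving the comparisons between candidate networks, which is all the
verdict uses, well behaved in practice.

## Evaluation against a pathway ground truth

`loadTruth()` accepts a two-column edge list or minimal KGML (relation
subtypes activation / inhibition / phosphorylation, all treated as directed
cause → effect: direction, not sign, is what is evaluated), maps aliases,
and closes the relation set transitively over the digraph — ancestry, not
adjacency, is the unit of validation, and cycles are permitted.
`precisionAtRank()` reports forward and reversed precision of the
frequency-ranked unique pairs (`rankPredictions()`, lexicographic
tie-break), and `randomBaselineTest()` compares overall precision against
random prediction sets of identical (per-stratum) size with a one-sided
z-test. For a 14-marker panel there are $14 \times 13 = 182$ ordered pairs;
a truth covering 56 of them makes $56/182 \approx 0.31$ the chance line.
Live pathway-database downloads are out of scope by design — database
content is version-dependent, so the ground truth is an input artifact.

## Numerical and degenerate-input conventions

* Tables with fewer than 20 cells are skipped (with a message), matching
  the minimum-cell rule of the motivating analysis; environments need at
  least $p + 1$ cells and no constant marker.
* Degenerate trio tests (zero variance, separation, collinearity) propagate
  as *uncertain* outcomes rather than aborting a study-wide run.
* Perfect separation in the logistic test is an error unless
  `allowSeparation = TRUE`, which reports $p = 0$.
* Equal BGe scores at the argmax ("ties") are resolved away from
  *consistent*; equality is declared at relative tolerance $10^{-9}$.
* The diagonalizer's residual is scale-normalized (off-diagonal over total
  squared norm), so "success" thresholds transfer across marker scales.
* All stochastic procedures take explicit seeds; study generation derives
  per-condition seeds from the master seed by a deterministic string hash.

## Problem sizes used by the test suite

The suite and the acceptance script regenerate everything from code at
sizes chosen to make each property decisive yet quick: trio recovery runs
50 independent 27-replicate studies at 1000 cells per condition (the
observed precision is 1.0, and emission rates under pure-noise and
confounded models are 0); test calibration uses 10,000 null replicates at
$n = 500$; connectivity identifiability uses 10 studies of three
10,000-cell environments (max-norm error below 0.05, exactly zero error
with population covariances); BGe selection uses 100 trios at $n = 2000$
(≥ 95% argmax recovery); and false-positive control refits 100 subsamples
on each of 20 null studies of a 14-marker panel (mean stable-edge count
well below $E(V) = 5$).

## Known limitations

* Linear-Gaussian everything: no nonlinear effects, no non-additive
  interventions, no heavy tails. Signaling saturation violates this.
* CLCD's conservativeness trades recall for precision; with weak activator
  effects or few replicates it is silent rather than wrong.
* Three-environment connectivity estimates are exactly identified, hence
  noise-sensitive; prefer more dosage levels when available, and trust the
  diagnostics only from four environments upward.
* The BGe verdicts inherit the 0/1-as-Gaussian convention for $A$.
* Ranked-precision evaluation treats the ground truth as complete; absent
  pathway edges count as errors even where the database is merely silent.
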