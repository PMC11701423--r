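---
title: "Multi-context causal discovery: perturbation graphs, pruning, and invariant prediction"
author: "pgicp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-context causal discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pgicp` works with the linear Gaussian structural equation model on a
directed graph $\mathcal{G} = (V, E)$, $|V| = m$:

$$X_t = \sum_{s \ne t} \beta_{ts} X_s + \varepsilon_t,
  \qquad \varepsilon_t \sim N(0, \sigma_t^2),$$

with mutually uncorrelated noises and $\beta_{ts} \ne 0$ exactly when
$s \to t \in E$. Collecting the coefficients in $B$ (with $B[t,s] =
\beta_{ts}$), the implied distribution is Gaussian with

$$\mu = (I - B)^{-1} m_\varepsilon, \qquad
  \Sigma = (I - B)^{-1} \Psi (I - B)^{-\top},$$

which `implied_moments()` evaluates. Acyclic graphs are the main case;
cyclic coefficient matrices are accepted when their spectral radius is
below 1 and are then read at the equilibrium $X = (I-B)^{-1}
\varepsilon$ — the same eigenvalue condition under which feedback loops
in nodewise output are interpretable.

Data come from *contexts*: a nominal regime label $C$, with $C =
\mathtt{obs}$ for pure observation. Two intervention types are modelled
(`intervention()`):

* **hard** (replacement): the targets' structural equations are deleted
  and each target is replaced by an external
  $W \sim N(\mu_W, \sigma_W^2)$ — incoming edges are cut;
* **soft** (shift): a constant is added to the target's noise mean
  and/or variance, incoming edges intact.

Conditional-independence reasoning uses d-separation computed by the
three-step ancestral-moralization construction (restrict to the
ancestral closure, marry co-parents, drop directions); the test suite
checks it against an independent path-blocking oracle on every 3-node
DAG and on random 4–5-node DAGs.

## Perturbation graphs and the pooled-correlation fallacy

A perturbation graph draws $s \to t$ whenever intervening on $s$
changes the distribution of $t$; such an edge certifies a directed
*path* $s \to \dots \to t$, not a direct cause.
`build_perturbation_graph()` tests each (source, target) pair with a
two-sample Kolmogorov–Smirnov test (default; Welch's t on request,
since mean comparisons are common in the gene-network literature)
against the observational context, applying a per-source Holm
correction across the $m - 1$ targets. The multiplicity rule is this
package's choice — the level-.05-per-context convention that motivated
it does not fix one — and is switchable (`none`, `holm`,
`bonferroni`).

The pooled *conditional correlation* $r_{ts\|\{\mathtt{obs},s\}}$ is a
plain Pearson correlation over the union of the observational and
intervention-on-$s$ rows. It is a mixture-distribution quantity:
pooling is licensed exactly when the per-context correlations are equal
(*marginal invariance*, tested by `marginal_invariance_test()` with
Fisher's z), in which case both equal the pooled value. The converse
fails, and the package ships the counterexample as a fixture: for the
fork `s <- u -> t` with a hard intervention on `s`, the observational
correlation is about .5, the interventional one about 0, yet the pooled
correlation is markedly non-zero (about .22 under the package's unit
coefficients). A non-zero pooled correlation is therefore *not*
evidence of a directed path; per-context correlations are. Pooling
unequal context sizes triggers a warning because the mixture reading
assumes contexts of equal probability.

## Transitive reduction and its counterexample

For standardized (unit-variance) acyclic models, a correlation
decomposes over directed paths into products of path coefficients
(`wright_path_correlation()`; topologies with a common-cause backdoor
between the endpoints are refused and routed to `implied_moments()`).
This motivates the pruning heuristic implemented by
`tr_criterion_keep()`: remove $s \to t$ when some alternative directed
path has

$$\min\{|\rho_{s v_1}|, \dots, |\rho_{v_k t}|\} > |\rho_{st}|,$$

all quantities pooled conditional correlations. The heuristic is sound
when every direct effect dominates its indirect routes, and the test
suite verifies exact recovery in that regime. It is **not consistent**:
in the four-node fixture `fig3b` (two indirect paths at −.2 each, true
direct edge at −.1) the direct contribution partially cancels the
indirect ones, $\rho_{st} = .08 - .10 = -.02$, the criterion fires at
population weights, and a true parent is deleted. This is a permanent
regression test, not a tolerance issue.

Numerical choices: the criterion uses the strict inequality as printed
(exact ties keep the edge); `transitive_reduce_weighted()` evaluates
every edge against the *original* edge set in a single pass, because
iterative re-pruning makes the output depend on edge order (an
`iterate = TRUE` mode is provided for comparison); path enumeration is
capped at 6 edges by default with an explicit warning when the cap
binds, since path counts grow exponentially on dense graphs.

## Invariant causal prediction

A set $S$ is *conditionally invariant predictive* for target $t$ when
the regression of $X_t$ on $X_S$ has the same coefficients and residual
distribution in every context. `icp_fit()` enumerates all $S \subseteq
V \setminus \{t\}$ up to `max_set_size` (default $\min(m-1, 6)$;
exhaustive search — a greedy fallback is deliberately out of scope),
tests each at level $\alpha$, and returns the **intersection of the
accepted sets** as the parent estimate. If the true parent set is
accepted (probability $\ge 1 - \alpha$), the intersection is contained
in it, which gives the $\ge 1 - \alpha$ coverage that the suite
verifies over 500 simulated replicates. Confidence intervals are the
union over accepted sets of each set's $(1-\alpha)$ OLS interval, with
accepted sets that exclude a variable contributing $\{0\}$; only a
variable present in every accepted set can be bounded away from zero.

Two invariance tests are provided. `ks_residual` (default, the choice
matching survey-type applications) fits one pooled OLS and compares
each context's residuals against the remaining rows by two-sample KS;
`chow` compares, per context against the rest, the regression
coefficients (Chow F) and the residual variances (variance-ratio F).
Component p-values are Bonferroni-combined; with exactly two contexts
the two context-vs-rest comparisons coincide and the single distinct
comparison is used without a context factor, keeping the combined test
at its nominal level (the coefficient and variance components are
near-independent, so the two-fold Bonferroni loses almost nothing:
$1-(1-\alpha/2)^2 \approx .049$ at $\alpha = .05$).

Calibration has one subtlety worth knowing: the residual-KS test is at
its nominal level when the conditioning covariates are identically
distributed across contexts, and *conservative* when a member of $S$
is itself shifted (the pooled fit is orthogonal to the covariates and
absorbs part of the between-context difference; empirically type-I
drops to about .03 at $\alpha = .05$ in the chain-with-shift design).
Conservatism is the safe direction for an intersection estimator — it
widens acceptance, never narrows coverage — and the suite asserts the
nominal level under the identical-context null and coverage under the
shifted one.

Design decisions made explicit:

* Contexts in which members of $S$ were intervened on are **included**
  in the test — interventions on parents do not disturb
  $X_t \mid X_S$, and that invariance is the method's engine.
* A context that intervenes on the *target* breaks the target's own
  mechanism; `icp_fit()` keeps such contexts unless told otherwise
  (a fully perturbed target then yields `model_rejected`, itself
  informative), while the nodewise `icp_graph()` excludes them per
  target, using the design if given or the label-equals-variable
  convention otherwise.
* The empty set is always tested; accepting it yields an empty
  estimate without `model_rejected`.
* Identifiability: with hard mean-shifted interventions on every
  predictor, the estimate converges to exactly the true parents
  (verified at $n = 5000$ per context). Intervening on fewer variables
  is conservative rather than wrong. In the four-node design
  $t \leftarrow u \to s \to t \to v$ with an intervention on $u$ only,
  the estimate converges to $\{u\}$, a strict subset of the true
  parents $\{u, s\}$: regressing $t$ on the exogenous $u$ alone
  absorbs the whole total effect (the intercept is identically zero in
  every context), so $\{u\}$ is itself invariant and survives the
  intersection, while no tested set can reject it. Identifying $s$
  requires perturbing $s$ (directly or via an upstream non-confounded
  cause).
* A rejected model, or dependence between residuals and predictors
  from unobserved confounding, downgrades the causal reading of
  retained predictors from parents to possible ancestors; the print
  method says so. Formal hidden-confounder estimation and
  instrumental-variable constructions are out of scope.

## Sequential ICP for time series

`seq_icp_fit()` treats consecutive blocks of a multivariate series as
contexts — a block boundary standing in for an unannounced regime
change — and runs the same subset search on a lagged design: concurrent
candidate variables, their lags $1..L$, and the target's own lags as an
always-included autoregressive baseline. Invariance uses the Chow-type
test (coefficient equality plus normalized residual variance), and the
parent estimate is reported at the variable level. Defaults are $L = 1$
and two equal blocks; the source application (a 1478-point,
four-variable momentary-assessment series) does not pin either, so both
are package choices, overridable per call (`blocks` accepts explicit
ranges, e.g. around a known tapering point).

## Synthetic generators: what they emulate, and what not

`random_sem()` draws DAGs by a random topological order with
independent edge coin-flips and coefficient magnitudes uniform in
$[0.3, 0.9]$ — bounded away from zero so that faithfulness holds
numerically (zero partial correlations coincide with d-separations, a
tested invariant).

`likert_survey_generator()` emulates the *design* of a perturbation
survey: one observational context plus one soft mean-shift context per
variable (12 contexts for $m = 11$, with the attitude names of the
motivating survey), discretized to a 1–7 scale by equal-probability
thresholds of the observational latent marginal — thresholds the source
design does not state, chosen so the observational margins are
symmetric, matching the unimodality/symmetry check that justifies
treating Likert responses as continuous. The default shift is 3 latent
SDs with 200 rows per context. It does not emulate item-level
structure, fat-handed scenario effects, or missingness; passing tests
on it show the pipeline works under the stated model, not that real
scenario interventions are single-target.

`regime_timeseries_generator()` produces a stable VAR(1) with a chain
transition structure and an innovation mean shift in one variable from
`break_at` onward (defaults $m = 4$, $n = 1478$ mirroring the
motivating series; tests run shorter series). It does not emulate
sum-score construction, circadian sampling, or tapering dynamics.

## Problem sizes and numerical conventions

The shipped tests use: exhaustive 3-node plus random 4–5-node graphs
for the d-separation and reduction oracles; 100 random standardized
models for the path-rule/implied-covariance agreement at $10^{-10}$;
500 coverage replicates at 300 rows per context and 30 identifiability
replicates at 5000; 2000-replicate calibration runs at 500 rows per
context, where the two-sample KS sits at its nominal .05 (at smaller
sizes its discrete attainable levels fall visibly below). Correlations
with $|r| \ge 1 - 10^{-12}$ are treated as degenerate for Fisher's z.
All sampling is locally seeded (`sample_contexts()` restores the
caller's RNG state), context order follows the design, and files are
written with sorted edges at 10 significant digits so identical
commands reproduce identical bytes.

One convention deserves a note: the sufficient-experiment bound is
implemented as $\lceil \log_2 m \rceil$ (so 2 experiments suffice for
$m = 3$ and 4 for $m = 10$), which matches the standard worked
examples; the frequently quoted "$\log(m) + 1$" form disagrees with
those examples unless read with this ceiling convention. For $m = 1$
the bound is 0 — nothing to orient.

## Limitations

Causal sufficiency is assumed throughout; hidden confounding weakens
conclusions to ancestor relations, as flagged in the output. Wright's
general tracing rules (bidirected or backdoor segments) are not
implemented — `wright_path_correlation()` refuses those topologies
rather than silently mis-decomposing. Noise is Gaussian and structural
equations linear; the KS-based tests remain valid beyond Gaussianity,
but the Chow variant and the confidence intervals do not. Exhaustive
subset search limits nodewise ICP to modest $m$ (the intended regime of
survey-scale designs); no screening step is provided.
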