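# pgicp

Causal discovery from combined observational and interventional data:
**p**erturbation **g**raphs and **i**nvariant **c**ausal **p**rediction.

Experimental designs in psychology (and gene-perturbation screens in
biology) produce one observational data set plus a collection of
interventional ones, each perturbing a single variable. `pgicp` is a
toolkit for analysing such multi-context data under a linear Gaussian
structural model

    X_t = sum_{s != t} beta_ts X_s + eps_t,   eps_t ~ N(0, sigma_t^2),

with contexts indexed by a nominal variable `C` (`C = obs` for
observation; hard interventions replace a variable by an external
`W`, soft interventions shift its noise). It is aimed at researchers who
want to go beyond "intervening on s moved t" (an ancestor relation) to
"s is a direct cause of t".

The package implements, end to end:

* **Simulation** — population moments `mu = (I-B)^{-1} m`,
  `Sigma = (I-B)^{-1} Psi (I-B)^{-T}` under any intervention, Wright
  path-rule correlation decompositions, and seeded multi-context
  sampling (`sem_model()`, `implied_moments()`,
  `wright_path_correlation()`, `sample_contexts()`).
* **Perturbation graphs** — per-context and pooled ("conditional")
  correlations `r_{ts||{obs,s}}`, Kolmogorov–Smirnov / Welch
  distribution-change tests, Fisher-z marginal-invariance tests, and
  the edge-decision rule (`build_perturbation_graph()`).
* **Transitive reduction** — the minimum-coefficient pruning heuristic
  `min |rho(path)| > |rho(s,t)|` for removing putative indirect edges,
  together with the counterexample machinery showing the heuristic is
  **not consistent** (`transitive_reduce_weighted()`).
* **Invariant causal prediction** — nodewise subset search with
  residual-KS or Chow-type invariance tests, the
  intersection-of-accepted-sets parent estimator with >= 1 - alpha
  coverage, union confidence intervals, and a sequential variant for
  time series split into regime blocks (`icp_fit()`, `icp_graph()`,
  `seq_icp_fit()`).
* **Graph utilities and I/O** — d-separation via ancestral
  moralization, graph-theoretic transitive reduction, CSV/JSON/DOT
  formats, and a command-line front end (`inst/cli/pgicp`).

## Worked example: why pruning fails and invariance does not

The model: four standardized variables with paths `s -> v -> t` and
`s -> w -> t` (path coefficients −.2 each) **plus a true direct edge**
`s -> t` with coefficient −.1.

```r
library(pgicp)
m <- fixture("fig3b")
w <- wright_path_correlation(m, "s", "t")
# s -> v -> t : 0.04
# s -> w -> t : 0.04
# s -> t      : -0.1
w$correlation
# [1] -0.02
```

The two indirect paths contribute +.08 and the direct edge −.10, so the
correlation between `s` and `t` is a mere −.02 — *smaller in magnitude
than every coefficient along the indirect paths*. The pruning criterion
therefore deletes the genuine direct edge:

```r
red <- transitive_reduce_weighted(population_perturbation_graph(m))
attr(red, "log")
#   source target weight  kept triggering_path
# 1      s      v -0.200  TRUE            <NA>
# 2      s      w -0.200  TRUE            <NA>
# 3      s      t -0.020 FALSE         s->v->t
# 4      v      t -0.188  TRUE            <NA>
# 5      w      t -0.188  TRUE            <NA>
```

This happens at *population* weights: no amount of data fixes it.
Conditional invariant prediction, which regresses on candidate parent
sets instead of comparing pairwise correlations, keeps the edge. With
hard interventions on `s`, `v`, `w` (5000 rows per context):

```r
dat <- sample_contexts(m, single_target_design(c("s", "v", "w"), n = 5000),
                       seed = 101)
icp_fit(dat, "t")
# invariant causal prediction for target 't' (alpha = 0.05, method = ks_residual)
# accepted sets: {s,v,w}
# parent estimate (intersection): s, v, w
# confidence intervals:
#  variable      lower       upper includes_zero
#         s -0.1150114 -0.09260931         FALSE
#         v -0.2129737 -0.19237847         FALSE
#         w -0.2159006 -0.19524401         FALSE
```

The estimate is exactly the true parent set `{s, v, w}`, and each
interval covers the generating coefficient (−.1, −.2, −.2).

## Command line

```sh
pgicp simulate --fixture fig3a --n 1000 --seed 7 -o data.csv
pgicp pgraph   --data data.csv -o pgraph.csv
pgicp reduce   --graph pgraph.csv -o reduced.csv
pgicp icp      --data data.csv --target t --alpha 0.05
pgicp seqicp   --data series.csv --target V2 --lags 1 --blocks 2
pgicp benchmark --m 5 --n 2000 --seed 1
```

See the vignette (`vignettes/multi-context-causal-discovery.Rmd`) for
the model, the tests, their assumptions, and known limitations.
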