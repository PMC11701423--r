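test_that("implied moments solve the structural equations", {
  g <- digraph(c("s", "t"), "s->t")
  b <- 0.7
  m <- sem_model(g, beta = b)
  mom <- implied_moments(m)
  expect_equal(mom$mean, c(s = 0, t = 0))
  expect_equal(mom$cov, matrix(c(1, b, b, b^2 + 1), 2,
                               dimnames = list(c("s", "t"), c("s", "t"))))

  # hard intervention on the chain head propagates the replacement mean
  ch <- fixture("fig2_chain")
  mi <- implied_moments(ch, intervention("hard", "s",
                                         replacement_mean = 2,
                                         replacement_var = 1))
  expect_equal(mi$mean, c(s = 2, u = 2, t = 2))

  # hard intervention on a fork leaf decouples it from the other leaf
  fk <- fixture("fig2_fork")
  mf <- implied_moments(fk, intervention("hard", "s"))
  expect_equal(mf$cov["s", "t"], 0)
  expect_gt(implied_moments(fk)$cov["s", "t"], 0)
})

test_that("cyclic models require spectral radius < 1 and sample at equilibrium", {
  g <- digraph(c("a", "b"), c("a->b", "b->a"))
  expect_error(sem_model(g, beta = c(1.1, 1.0)), "spectral radius")
  m <- sem_model(g, beta = c(0.5, 0.5))
  mom <- implied_moments(m)
  expect_equal(mom$cov, t(mom$cov))
  expect_true(all(eigen(mom$cov, only.values = TRUE)$values > 0))
  d <- context_design(list(list(label = "obs",
                                intervention = intervention("none"),
                                n = 50)))
  expect_silent(sample_contexts(m, d, seed = 1))
})

test_that("coefficient pattern must match the edge set", {
  g <- digraph(c("s", "t"), "s->t")
  B <- matrix(0, 2, 2)
  B[1, 2] <- 0.5 # wrong orientation: t->s coefficient
  expect_error(sem_model(g, B), "pattern")
  expect_error(sem_model(g, beta = 0.5, noise_var = 0), "> 0")
})

test_that("standardization yields unit variances, keeps correlations, idempotent", {
  g <- digraph(c("s", "t"), "s->t")
  m <- sem_model(g, beta = 0.5)
  ms <- standardize(m)
  expect_equal(ms$B["t", "s"], 0.5 / sqrt(1.25))
  expect_equal(diag(implied_moments(ms)$cov), c(s = 1, t = 1))
  m2 <- random_sem(5, edge_prob = 0.5, seed = 7)
  s2 <- standardize(m2)
  expect_equal(diag(implied_moments(s2)$cov),
               setNames(rep(1, 5), graph_nodes(m2$graph)))
  expect_equal(cov2cor(implied_moments(s2)$cov),
               cov2cor(implied_moments(m2)$cov))
  s3 <- standardize(s2)
  expect_equal(s3$B, s2$B, tolerance = 1e-12)
})

test_that("path-rule correlation matches the worked decompositions", {
  a <- fixture("fig3a")
  wa <- wright_path_correlation(a, "s", "t")
  expect_equal(wa$correlation, 0.08)
  expect_equal(sort(wa$contributions), c(0.04, 0.04))
  b <- fixture("fig3b")
  wb <- wright_path_correlation(b, "s", "t")
  expect_equal(wb$correlation, -0.02)
  expect_equal(sort(wb$contributions), c(-0.10, 0.04, 0.04))
  g <- digraph(c("s", "t"), "s->t")
  ms <- standardize(sem_model(g, beta = 0.6))
  ws <- wright_path_correlation(ms, "s", "t")
  expect_equal(ws$correlation, ms$B["t", "s"])
  expect_length(ws$paths, 1)
  # backdoor topologies are refused
  conf <- standardize(sem_model(
    digraph(c("u", "s", "t"), c("u->s", "u->t", "s->t")),
    beta = c(0.4, 0.4, 0.4)))
  expect_error(wright_path_correlation(conf, "s", "t"), "backdoor")
})

test_that("path rule equals implied covariance on random supported models", {
  for (k in 1:100) {
    sp <- random_supported_pair(seed = 5000 + k)
    w <- wright_path_correlation(sp$model, sp$s, sp$t)$correlation
    R <- cov2cor(implied_moments(sp$model)$cov)
    expect_equal(w, R[sp$s, sp$t], tolerance = 1e-10)
  }
})

test_that("zero partial correlations coincide with d-separations", {
  # faithfulness: with coefficients bounded away from 0, the implied
  # Gaussian has a zero partial correlation exactly where the graph
  # d-separates
  set.seed(404)
  for (rep in 1:25) {
    m <- random_sem(4, edge_prob = 0.5, coeff_range = c(0.3, 0.9),
                    seed = 600 + rep)
    S <- implied_moments(m)$cov
    nodes <- graph_nodes(m$graph)
    prs <- utils::combn(nodes, 2L)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1L, i]; b <- prs[2L, i]
      rest <- setdiff(nodes, c(a, b))
      subsets <- c(list(character()), as.list(rest), list(rest))
      for (C in subsets) {
        pc <- pcor_from_cov(S, a, b, C)
        expect_identical(abs(pc) < 1e-8, d_separated(m$graph, a, b, C))
      }
    }
  }
})

test_that("multi-context sampling is reproducible and matches its moments", {
  ch <- fixture("fig2_chain")
  d <- single_target_design("s", n = 100)
  x1 <- sample_contexts(ch, d, seed = 42)
  x2 <- sample_contexts(ch, d, seed = 42)
  expect_identical(x1, x2)
  x3 <- sample_contexts(ch, d, seed = 43)
  expect_false(identical(x1, x3))

  # degenerate replacement clamps the intervened column
  dd <- context_design(list(
    list(label = "obs", intervention = intervention("none"), n = 10),
    list(label = "s", intervention = intervention("hard", "s",
                                                  replacement_mean = 2,
                                                  replacement_var = 0),
         n = 10)))
  xc <- sample_contexts(ch, dd, seed = 1)
  expect_equal(xc$s[mcd_context(xc) == "s"], rep(2, 10))

  # large-sample convergence to the implied moments (4-SE tolerance)
  n <- 1e5
  dobs <- context_design(list(list(label = "obs",
                                   intervention = intervention("none"),
                                   n = n)))
  X <- mcd_matrix(sample_contexts(ch, dobs, seed = 9))
  mom <- implied_moments(ch)
  for (v in colnames(X)) {
    se <- sqrt(mom$cov[v, v] / n)
    expect_lt(abs(mean(X[, v]) - mom$mean[[v]]), 4 * se)
  }
  emp <- cov(X)
  expect_equal(emp, mom$cov, tolerance = 0.05)

  expect_error(sample_contexts(ch, context_design(list(
    list(label = "obs", intervention = intervention("none"), n = 0))),
    seed = 1), "sample sizes are 0")
})

test_that("sampling leaves the caller's RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(sample_contexts(fixture("fig2_chain"),
                            single_target_design("s", n = 10), seed = 3))
  expect_identical(.Random.seed, before)
})
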