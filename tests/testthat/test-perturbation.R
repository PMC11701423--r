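# small helper: observation + one hard intervention on `on`, n each
two_context_data <- function(model, on, n, seed,
                             replacement_mean = 2) {
  d <- single_target_design(on, n = n,
                            replacement_mean = replacement_mean)
  sample_contexts(model, d, seed = seed)
}

test_that("per-context correlation handles exact and degenerate cases", {
  x <- seq_len(20)
  dat <- multi_context_data(cbind(a = x, b = 2 * x + 1, c = -x),
                            rep("obs", 20))
  expect_equal(context_correlation(dat, "a", "b", "obs")$r, 1)
  expect_equal(context_correlation(dat, "a", "c", "obs")$r, -1)
  expect_equal(context_correlation(dat, "a", "b", "obs")$n, 20)
  small <- multi_context_data(cbind(a = 1:3, b = 3:1), rep("obs", 3))
  expect_error(context_correlation(small, "a", "b", "obs"), "at least 4")
  flat <- multi_context_data(cbind(a = rep(1, 5), b = 1:5), rep("obs", 5))
  expect_error(context_correlation(flat, "a", "b", "obs"),
               "zero variance")
  expect_error(context_correlation(dat, "a", "b", "nope"), "not present")
})

test_that("observational correlation on the chain matches the implied value", {
  ch <- fixture("fig2_chain")
  dat <- two_context_data(ch, "s", n = 1e5, seed = 31)
  R <- cov2cor(implied_moments(ch)$cov)
  est <- context_correlation(dat, "s", "t", "obs")$r
  expect_equal(est, R["s", "t"], tolerance = 0.01)
  expect_equal(R["s", "t"], 1 / sqrt(3))
})

test_that("pooled correlation matches the two-component mixture oracle", {
  ch <- fixture("fig2_chain")
  iv <- intervention("hard", "s", replacement_mean = 2,
                     replacement_var = 1)
  dat <- two_context_data(ch, "s", n = 2e4, seed = 32)
  mix <- mixture_moments(list(implied_moments(ch),
                              implied_moments(ch, iv)))
  r_oracle <- mix$cov["s", "t"] / sqrt(mix$cov["s", "s"] *
                                       mix$cov["t", "t"])
  expect_equal(conditional_correlation(dat, "s", "t", "s"), r_oracle,
               tolerance = 0.02)

  # two identical contexts: pooled equals per-context correlation
  d2 <- context_design(list(
    list(label = "obs", intervention = intervention("none"), n = 5000),
    list(label = "s", intervention = intervention("soft", "s",
                                                  shift_mean = 0,
                                                  extra_var = 0),
         n = 5000)))
  same <- sample_contexts(ch, d2, seed = 33)
  expect_equal(conditional_correlation(same, "s", "t", "s"),
               context_correlation(same, "s", "t", "obs")$r,
               tolerance = 0.03)

  uneq <- multi_context_data(cbind(a = rnorm(30), b = rnorm(30)),
                             rep(c("obs", "s"), c(20, 10)))
  expect_warning(conditional_correlation(uneq, "a", "b", "s"),
                 "unequal")
})

test_that("the fork counterexample: pooled correlation misleads", {
  fk <- fixture("fig2_fork")
  dat <- two_context_data(fk, "s", n = 1e4, seed = 34)
  r_obs <- context_correlation(dat, "s", "t", "obs")$r
  r_int <- context_correlation(dat, "s", "t", "s")$r
  r_pool <- conditional_correlation(dat, "s", "t", "s")
  expect_gt(r_obs, 0.3)          # strong association without intervention
  expect_lt(abs(r_int), 0.05)    # none under intervention on s
  expect_gt(abs(r_pool), 0.1)    # yet the pool looks associated
  expect_gt(abs(r_pool - r_int), 0.1)
  # and the invariance test detects the discrepancy
  mi <- marginal_invariance_test(dat, "s", "t", "s")
  expect_lt(mi$p, 0.001)
  expect_identical(mi$decision, "not marginally invariant")
})

test_that("marginal invariance holds on the chain (mechanism untouched)", {
  # intervening on s leaves the s -> t mechanism intact, so the two
  # context correlations are equal and rejections stay at the test level
  ch <- fixture("fig2_chain")
  rej <- 0L
  reps <- 60
  for (k in seq_len(reps)) {
    dat <- two_context_data(ch, "s", n = 1000, seed = 3500 + k)
    mi <- marginal_invariance_test(dat, "s", "t", "s")
    rej <- rej + (mi$p <= 0.05)
  }
  expect_lt(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  x <- seq_len(10)
  perf <- multi_context_data(cbind(a = c(x, x), b = c(2 * x, 2 * x)),
                             rep(c("obs", "s"), each = 10))
  expect_error(marginal_invariance_test(perf, "a", "b", "s"),
               "Fisher z")
})

test_that("distribution-change test behaves on identical and shifted data", {
  x <- rnorm(50)
  dat <- multi_context_data(cbind(t = c(x, x), s = rnorm(100)),
                            rep(c("obs", "s"), each = 50))
  expect_equal(distribution_change_test(dat, "t", "s"), 1)
  ch <- fixture("fig2_chain")
  big <- two_context_data(ch, "s", n = 500, seed = 36)
  expect_lt(distribution_change_test(big, "t", "s"), 0.05)
  expect_lt(distribution_change_test(big, "t", "s", method = "welch"),
            0.05)
})

test_that("perturbation graph equals the descendant relation at scale", {
  ch <- fixture("fig2_chain")
  d <- single_target_design(c("s", "u", "t"), n = 4000)
  dat <- sample_contexts(ch, d, seed = 37)
  pg <- build_perturbation_graph(dat, d)
  expect_setequal(paste0(pg$graph$edges$from, "->", pg$graph$edges$to),
                  c("s->u", "s->t", "u->t"))
  fk <- fixture("fig2_fork")
  datf <- sample_contexts(fk, single_target_design(c("s", "u", "t"),
                                                   n = 4000), seed = 38)
  pgf <- build_perturbation_graph(datf)
  expect_setequal(paste0(pgf$graph$edges$from, "->", pgf$graph$edges$to),
                  c("u->s", "u->t"))
  # evidence carries the full picture for every tested pair
  expect_identical(nrow(pg$evidence), 6L)
  expect_true(all(c("r_obs", "r_int", "r_pooled", "p_change",
                    "p_invariance") %in% names(pg$evidence)))

  obs_only <- multi_context_data(cbind(a = rnorm(10), b = rnorm(10)),
                                 rep("obs", 10))
  expect_error(build_perturbation_graph(obs_only),
               "intervention context")
})

test_that("population perturbation graph is the strict descendant relation", {
  for (seed in 1:10) {
    m <- random_sem(5, edge_prob = 0.4, seed = 900 + seed)
    pg <- population_perturbation_graph(m)
    R <- closure_matrix(m$graph)
    want <- which(R, arr.ind = TRUE)
    got <- paste0(pg$graph$edges$from, "->", pg$graph$edges$to)
    expect_setequal(got, paste0(rownames(R)[want[, 1]], "->",
                                colnames(R)[want[, 2]]))
  }
})
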