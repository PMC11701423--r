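test_that("OLS fit recovers exact linear structure", {
  n <- 50
  x <- rnorm(n); z <- rnorm(n)
  y <- 2 + 3 * x - 1.5 * z
  dat <- multi_context_data(cbind(x = x, z = z, y = y), rep("obs", n))
  f <- ols_fit(dat, "y", c("x", "z"))
  expect_equal(unname(f$coefficients), c(3, -1.5), tolerance = 1e-10)
  expect_equal(f$intercept, 2, tolerance = 1e-10)
  # empty set: residuals are the centred target
  f0 <- ols_fit(dat, "y", character())
  expect_equal(f0$residuals, y - mean(y))
  # duplicated predictor column is rank deficient
  dup <- multi_context_data(cbind(x = x, x2 = x, y = y), rep("obs", n))
  expect_error(ols_fit(dup, "y", c("x", "x2")), "rank")
  expect_error(ols_fit(dat, "y", "y"), "target")
})

test_that("invariance test accepts blocking sets and rejects the empty set", {
  ch <- fixture("fig2_chain")
  d <- single_target_design("s", n = 150)
  # S = {u} d-separates t from the intervened s: calibrated acceptance
  rej <- 0L
  reps <- 80
  for (k in seq_len(reps)) {
    dat <- sample_contexts(ch, d, seed = 7000 + k)
    rej <- rej + (invariance_pvalue(dat, "t", "u") <= 0.05)
  }
  expect_lt(rej / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  # S = {} sees the full mean shift 2 * beta_tu * beta_us
  big <- sample_contexts(ch, single_target_design("s", n = 2000),
                         seed = 71)
  expect_lt(invariance_pvalue(big, "t", character()), 1e-6)
  expect_lt(invariance_pvalue(big, "t", character(), method = "chow"),
            1e-6)
  one <- multi_context_data(cbind(a = rnorm(10), b = rnorm(10)),
                            rep("obs", 10))
  expect_error(invariance_pvalue(one, "a", "b"), ">= 2 contexts")
})

test_that("both the mediator set and the full set are invariant (mediated design)", {
  # v -> s -> u -> t with an intervention on s: conditioning on u, or on
  # {s, u}, both block the intervened path
  m <- fixture("fig4a")
  dat <- sample_contexts(m, single_target_design("s", n = 4000),
                         seed = 72)
  expect_gt(invariance_pvalue(dat, "t", "u"), 0.05)
  expect_gt(invariance_pvalue(dat, "t", c("s", "u")), 0.05)
  expect_lt(invariance_pvalue(dat, "t", character()), 0.01)
  # an intervention on the mediator u breaks every set that omits it
  dat_u <- sample_contexts(m, single_target_design("u", n = 4000),
                           seed = 720)
  expect_lt(invariance_pvalue(dat_u, "t", "s"), 0.01)
  expect_gt(invariance_pvalue(dat_u, "t", "u"), 0.05)
})

test_that("ICP estimates the chain parent set (and is conservative without u-intervention)", {
  ch <- fixture("fig2_chain")
  dat <- sample_contexts(ch, single_target_design(c("s", "u"), n = 2000),
                         seed = 73)
  r <- icp_fit(dat, "t")
  expect_false(r$model_rejected)
  expect_identical(r$parent_estimate, "u")
  acc <- vapply(r$accepted, function(a) paste(a$S, collapse = ","), "")
  expect_setequal(acc, c("u", "s,u"))

  # only an s-intervention: {s}, {u}, {s,u} all invariant, intersection
  # empty -- the conservative answer when predictors are not all perturbed
  dat2 <- sample_contexts(ch, single_target_design("s", n = 2000),
                          seed = 74)
  r2 <- icp_fit(dat2, "t")
  acc2 <- r2$tests$set[r2$tests$accepted]
  expect_true(all(c("s", "u", "s,u") %in% acc2))
  expect_false("{}" %in% acc2)
  expect_length(r2$parent_estimate, 0)
  expect_false(r2$model_rejected)
})

test_that("a directly perturbed target rejects every set", {
  ch <- fixture("fig2_chain")
  dat <- sample_contexts(ch, single_target_design("t", n = 1500),
                         seed = 75)
  r <- icp_fit(dat, "t") # the t-intervention context is kept
  expect_true(r$model_rejected)
  expect_length(r$parent_estimate, 0)
  expect_null(r$ci)
  expect_error(icp_confidence_intervals(dat, "t", list()),
               "model_rejected")
})

test_that("confidence intervals take the union over accepted sets", {
  m <- fixture("fig4a")
  dat <- sample_contexts(m, single_target_design(c("v", "s", "u"),
                                                 n = 3000), seed = 76)
  r <- icp_fit(dat, "t")
  expect_identical(r$parent_estimate, "u")
  ci <- r$ci
  u_row <- ci[ci$variable == "u", ]
  expect_false(u_row$includes_zero)        # true coefficient 1
  expect_gt(u_row$lower, 0.8)
  expect_true(ci[ci$variable == "s", ]$includes_zero)
  expect_true(ci[ci$variable == "v", ]$includes_zero)
  # a single accepted set reproduces its own OLS intervals
  one <- r$accepted[[1]]
  ci1 <- icp_confidence_intervals(dat, "t", list(one), alpha = 0.05)
  row_u <- ci1[ci1$variable == "u", ]
  expect_equal(row_u$lower, unname(one$ci_low["u"]), tolerance = 1e-10)
  expect_equal(row_u$upper, unname(one$ci_high["u"]), tolerance = 1e-10)
})

test_that("nodewise ICP recovers the chain and flags 2-cycles", {
  ch <- fixture("fig2_chain")
  d <- single_target_design(c("s", "u", "t"), n = 2500)
  dat <- sample_contexts(ch, d, seed = 77)
  ig <- icp_graph(dat, design = d)
  expect_setequal(paste0(ig$graph$edges$from, "->", ig$graph$edges$to),
                  c("s->u", "u->t"))
  expect_identical(nrow(ig$cycles), 0L)

  # two near-duplicate measurements of one quantity whose scale changes
  # across contexts: each looks like an invariant parent of the other,
  # the empirical signature behind feedback loops in nodewise output
  set.seed(99)
  n <- 300
  s1 <- rnorm(n); s2 <- rnorm(n, 0, 2)
  twin <- multi_context_data(
    cbind(s = c(s1, s2),
          t = c(s1 + 0.05 * rnorm(n), s2 + 0.05 * rnorm(n))),
    rep(c("obs", "c2"), each = n))
  expect_message(ig2 <- icp_graph(twin), "2-cycle")
  expect_identical(nrow(ig2$cycles), 1L)

  single <- multi_context_data(cbind(a = rnorm(20), b = rnorm(20)),
                               rep("obs", 20))
  expect_error(icp_graph(single), ">= 2 contexts")
})

test_that("interventions on one exogenous cause identify it, and only it", {
  # t <- u -> s -> t -> v with an intervention on u alone: regressing t
  # on the exogenous u absorbs the whole total effect (intercept stays 0
  # in every context), so {u} itself is invariant and the intersection
  # is {u} -- a strict, covered subset of the true parents {u, s}
  m <- fixture("peters_nonnecessity")
  dat <- sample_contexts(m, single_target_design("u", n = 5000),
                         seed = 78)
  r <- icp_fit(dat, "t")
  expect_false(r$model_rejected)
  expect_identical(r$parent_estimate, "u")
  expect_true(all(r$parent_estimate %in% c("u", "s")))
  acc <- vapply(r$accepted, function(a) paste(a$S, collapse = ","), "")
  expect_true("u,s" %in% acc || "s,u" %in% acc ||
              any(vapply(r$accepted, function(a)
                setequal(a$S, c("s", "u")), TRUE)))
})

test_that("ICP keeps the direct parent that weighted reduction deletes", {
  truth <- fixture("fig3b")
  dat <- sample_contexts(truth,
                         single_target_design(c("s", "v", "w"), n = 3000),
                         seed = 79)
  r <- icp_fit(dat, "t")
  expect_true("s" %in% r$parent_estimate)
})
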