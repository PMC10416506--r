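# Small-scale data for bootstrap machinery checks: estimation at this n
# takes well under a second, keeping B-replicate loops fast.
boot_data <- function(n = 300, seed = 1) {
  sample_ising(make_preset("npiq_like")$params, n, seed = seed)
}

test_that("the nonparametric bootstrap is reproducible and records
           flagged replicates", {
  dat <- boot_data()
  r1 <- nonparametric_bootstrap(dat, B = 6, seed = 99, n_lambdas = 40)
  r2 <- nonparametric_bootstrap(dat, B = 6, seed = 99, n_lambdas = 40)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$centrality, r2$centrality)
  expect_equal(nrow(r1$edges), 6 * 66)
  # every replicate used the estimator settings of the original fit
  expect_equal(r1$settings$gamma, r1$original$gamma)
  # rare items go constant in resamples of a tiny dataset: flagged, kept
  rare <- boot_data(40, seed = 2)
  rr <- nonparametric_bootstrap(rare, B = 8, seed = 5, n_lambdas = 30)
  expect_equal(sort(unique(rr$edges$replicate)), 1:8)
})

test_that("edge CIs use the stated percentile rule", {
  run <- fake_np_run(list("A--B" = as.numeric(1:100),
                          "A--C" = rep(2, 100)), B = 100)
  ci <- edge_ci_table(run)
  ab <- ci[ci$item_a == "A" & ci$item_b == "B", ]
  # independent quantile computation (type 7): h = (n-1)p + 1
  expect_equal(ab$lower, 3.475)
  expect_equal(ab$upper, 97.525)
  expect_equal(ab$boot_mean, 50.5)
  # degenerate replicate distribution: zero-width interval at the value
  ac <- ci[ci$item_a == "A" & ci$item_b == "C", ]
  expect_equal(ac$lower, 2)
  expect_equal(ac$upper, 2)
  # narrower level nests inside the wider one
  ci50 <- edge_ci_table(run, level = 0.5)
  expect_true(all(ci50$lower >= ci$lower & ci50$upper <= ci$upper))
  # CIs refused for B = 1 and for a case-dropping run
  run1 <- fake_np_run(list("A--B" = 1), B = 1)
  expect_error(edge_ci_table(run1), "at least 2")
  cd <- fake_casedrop_run(tibble::tibble(proportion = 0.1, replicate = 1,
                                         index = "strength",
                                         correlation = 1),
                          proportions = 0.1, B = 1)
  expect_error(edge_ci_table(cd), "nonparametric")
})

test_that("case-dropping at a vanishing proportion reproduces the full
           sample", {
  dat <- boot_data()
  run <- case_dropping_bootstrap(dat, proportions = 1e-9, B = 2,
                                 seed = 3, n_lambdas = 40)
  expect_true(all(run$correlations$correlation == 1))
  # reproducibility
  run2 <- case_dropping_bootstrap(dat, proportions = 1e-9, B = 2,
                                  seed = 3, n_lambdas = 40)
  expect_identical(run$correlations, run2$correlations)
})

test_that("undersized subsamples are refused with a warning", {
  dat <- boot_data(60)
  expect_warning(
    run <- case_dropping_bootstrap(dat, proportions = c(0.2, 0.9),
                                   B = 2, seed = 1, n_lambdas = 30),
    "3p")
  expect_equal(run$refused, 0.9)
  expect_equal(run$proportions, 0.2)
  expect_error(
    suppressWarnings(case_dropping_bootstrap(dat, proportions = 0.99,
                                             B = 2, seed = 1)),
    "grid")
})

test_that("the CS coefficient reproduces hand-computable fixtures", {
  grid <- seq(0.1, 0.75, by = 0.05)
  B <- 100
  mk_cors <- function(f) {
    dplyr::bind_rows(lapply(grid, function(q) {
      tibble::tibble(proportion = q, replicate = seq_len(B),
                     index = "strength", correlation = f(q))
    }))
  }
  # all correlations 1 at every proportion: CS is the grid maximum
  all1 <- fake_casedrop_run(mk_cors(function(q) rep(1, B)), grid, B)
  expect_equal(cs_coefficient(all1)$cs, 0.75)
  # no proportion qualifies: CS = 0
  all0 <- fake_casedrop_run(mk_cors(function(q) rep(0, B)), grid, B)
  expect_equal(cs_coefficient(all0)$cs, 0)
  expect_match(cs_coefficient(all0)$band, "untrustworthy")
  # 96% of replicates at 0.9 up to q = 0.4, 50% beyond: CS = 0.4
  mixed <- fake_casedrop_run(mk_cors(function(q) {
    if (q <= 0.4) c(rep(0.9, 96), rep(0.1, 4))
    else c(rep(0.9, 50), rep(0.1, 50))
  }), grid, B)
  got <- cs_coefficient(mixed)
  expect_equal(got$cs, 0.4)
  # brute force over the definition, independently of the implementation
  brute <- max(c(0, Filter(function(q) {
    x <- mixed$correlations
    mean(x$correlation[x$proportion == q] >= 0.7) >= 0.95
  }, grid)))
  expect_equal(got$cs, brute)
  # monotone in the correlation threshold
  expect_lte(cs_coefficient(mixed, r_threshold = 0.95)$cs, got$cs)
  expect_gte(cs_coefficient(mixed, r_threshold = 0.05)$cs, got$cs)
})

test_that("difference tests are symmetric, conventional and monotone in
           the CI level", {
  B <- 50
  drift <- seq(-0.01, 0.01, length.out = B)
  run <- fake_np_run(list(
    "A--B" = 0.5 + drift,    # exceeds A--C by 0.2 in every replicate
    "A--C" = 0.3 + drift,
    "B--D" = 0.3 - drift     # difference with A--C symmetric around 0
  ), B = B)
  dt <- difference_tests(run, targets = "edges")
  self <- dt[dt$target_a == dt$target_b, ]
  expect_true(all(!self$significant))
  expect_true(all(self$lower == 0 & self$upper == 0))
  pick <- function(a, b) dt[dt$target_a == a & dt$target_b == b, ]
  expect_true(pick("A--B", "A--C")$significant)
  # symmetric conclusion with mirrored interval
  expect_true(pick("A--C", "A--B")$significant)
  expect_equal(pick("A--B", "A--C")$lower, -pick("A--C", "A--B")$upper)
  # replicate-wise differences symmetric around zero: not significant
  expect_false(pick("A--C", "B--D")$significant)
  # widening the level never creates significance
  dt99 <- difference_tests(run, targets = "edges", level = 0.99)
  m <- merge(as.data.frame(dt), as.data.frame(dt99),
             by = c("target_a", "target_b"))
  expect_true(all(!(m$significant.y & !m$significant.x)))
})

test_that("centrality difference tests run on bootstrap output", {
  dat <- boot_data()
  run <- nonparametric_bootstrap(dat, B = 10, seed = 42, n_lambdas = 40)
  dt <- difference_tests(run, targets = "strength")
  expect_equal(nrow(dt), 144)
  sym <- merge(as.data.frame(dt),
               as.data.frame(dt)[, c("target_a", "target_b",
                                     "significant")],
               by.x = c("target_a", "target_b"),
               by.y = c("target_b", "target_a"))
  expect_true(all(sym$significant.x == sym$significant.y))
})
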