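test_that("the penalty grid starts at the KKT boundary", {
  d <- random_logistic_data(200, 3, seed = 1)
  lam <- lambda_grid(d$X, d$y, n_lambdas = 25)
  expect_equal(length(lam), 25)
  expect_true(all(diff(lam) < 0))
  # independent re-derivation of the same formula
  lmax <- max(abs(t(d$X) %*% (d$y - mean(d$y)))) / nrow(d$X)
  expect_equal(lam[1], lmax, tolerance = 1e-12)
  expect_equal(lam[25], lmax * 0.01, tolerance = 1e-10)
  # fitting at lambda_max leaves every slope exactly zero
  f <- fit_l1_logistic(d$X, d$y, lam[1])
  expect_identical(as.numeric(f$slopes), rep(0, 3))
  expect_equal(f$intercept, qlogis(mean(d$y)), tolerance = 1e-9)
  # single-point grid
  expect_equal(lambda_grid(d$X, d$y, n_lambdas = 1), lmax)
  expect_error(lambda_grid(d$X, rep(1, 200)), "constant")
})

test_that("the penalized solver matches an independent Newton-Raphson
           fit at lambda = 0", {
  for (s in 1:10) {
    d <- random_logistic_data(300, 3, seed = 200 + s)
    f <- fit_l1_logistic(d$X, d$y, 0)
    nr <- newton_logistic(d$X, d$y)
    expect_equal(f$intercept, nr[1], tolerance = 1e-5)
    expect_equal(as.numeric(f$slopes), nr[-1], tolerance = 1e-5)
  }
})

test_that("the penalized path matches glmnet at matched penalties", {
  skip_if_not_installed("glmnet")
  pre <- make_preset("npiq_like")
  dat <- sample_ising(pre$params, 2000, seed = 3)
  m <- symptomnet:::as_symptom_matrix(dat)
  X <- m[, -1]
  y <- m[, 1]
  lam <- lambda_grid(X, y, n_lambdas = 25)
  f <- fit_l1_logistic(X, y, lam)
  g <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(as.matrix(g$beta)), unname(f$slopes),
               tolerance = 1e-4)
  expect_equal(unname(g$a0), f$intercept, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the penalized objective is invariant to duplicating rows", {
  d <- random_logistic_data(150, 3, seed = 77)
  lam <- 0.05
  f1 <- fit_l1_logistic(d$X, d$y, lam)
  f2 <- fit_l1_logistic(rbind(d$X, d$X), c(d$y, d$y), lam)
  expect_equal(f1$slopes, f2$slopes, tolerance = 1e-6)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-6)
})

test_that("EBIC reduces to BIC and matches frozen arithmetic", {
  expect_equal(ebic(-123.4, 0, 500, 11, gamma = 0.25), 246.8)
  expect_equal(ebic(-50, 4, 200, 7, gamma = 0),
               100 + 4 * log(200))
  # hand-computed: 200 + 3 ln 1000 + 2 * 0.25 * 3 ln 11
  expect_equal(ebic(-100, 3, 1000, 11, gamma = 0.25), 224.3201087,
               tolerance = 1e-6)
})

test_that("nodewise selection is the exact EBIC argmin over the path", {
  pre <- make_preset("npiq_like")
  dat <- sample_ising(pre$params, 1500, seed = 5)
  for (j in c(1, 4, 8)) {
    f <- fit_node(dat, j)
    # brute force re-evaluation of the criterion at every path point
    brute <- ebic(f$path$loglik, f$path$df, n = nrow(dat), p_pred = 11,
                  gamma = 0.25)
    expect_equal(f$path$ebic, brute)
    expect_equal(f$ebic, min(brute))
    expect_equal(f$lambda, f$path$lambda[which.min(brute)])
    # ties (if any) break toward the larger penalty
    expect_equal(which.min(brute),
                 min(which(brute == min(brute))))
  }
})

test_that("the selected model size is approximately monotone along the path", {
  pre <- make_preset("npiq_like")
  dat <- sample_ising(pre$params, 1500, seed = 6)
  f <- fit_node(dat, 2)
  expect_equal(f$path$df[1], 0L)
  # nonzero count non-decreasing as lambda falls, bar tolerance flips
  drops <- diff(f$path$df)
  expect_true(all(drops >= -1))
  expect_lte(sum(pmax(-drops, 0)), 2)
})

test_that("a constant response yields a flagged unestimable node", {
  m <- cbind(A = rep(1L, 30), B = rbinom(30, 1, 0.5),
             C = rbinom(30, 1, 0.5))
  m[1, "B"] <- 0L; m[2, "B"] <- 1L
  f <- fit_node(m, "A")
  expect_false(f$estimable)
  expect_warning(net <- assemble_network(list(f, fit_node(m, "B"),
                                              fit_node(m, "C"))),
                 "Unestimable")
  expect_equal(net$unestimable, "A")
  expect_true(all(net$weights["A", ] == 0))
})

test_that("edge assembly follows the OR and AND rules exactly", {
  f1 <- fake_fit("A", c("B", "C"), c(0.6, 0))
  f2 <- fake_fit("B", c("A", "C"), c(0, 0))
  f3 <- fake_fit("C", c("A", "B"), c(0, 0))
  or_net <- assemble_network(list(f1, f2, f3), rule = "OR")
  expect_equal(or_net$weights["A", "B"], 0.3)  # (0.6 + 0) / 2
  expect_equal(or_net$weights["B", "A"], 0.3)
  and_net <- assemble_network(list(f1, f2, f3), rule = "AND")
  expect_equal(and_net$weights["A", "B"], 0)
  # both coefficients zero: no edge under either rule
  expect_equal(or_net$weights["B", "C"], 0)
  expect_equal(and_net$weights["B", "C"], 0)
  # symmetric output with zero diagonal
  expect_equal(or_net$weights, t(or_net$weights))
  expect_equal(diag(or_net$weights), setNames(rep(0, 3), c("A", "B", "C")))
})

test_that("nodewise regression recovers the true conditional slope", {
  pr <- ising_parameters(c(-0.5, 0.2),
                         matrix(c(0, 0.8, 0.8, 0), 2, 2),
                         labels = c("A", "B"))
  dat <- sample_ising(pr, 50000, seed = 8)
  f <- fit_node(dat, "A", n_lambdas = 50)
  expect_lt(abs(f$slopes[["B"]] - 0.8), 0.1)
})

test_that("a node regressed on independent items selects the null model", {
  ind <- make_preset("independent")
  hits <- vapply(1:40, function(s) {
    dat <- sample_ising(ind$params, 10000, seed = 300 + s)
    f <- fit_node(dat, 1)
    sum(f$slopes != 0) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("network estimation is permutation-equivariant and OR covers AND", {
  pre <- make_preset("npiq_like")
  dat <- sample_ising(pre$params, 800, seed = 12)
  net <- estimate_network(dat, store_fits = FALSE)
  perm <- sample(seq_len(12))
  net_p <- estimate_network(dat[, perm], store_fits = FALSE)
  expect_equal(net_p$weights[net$labels, net$labels], net$weights,
               tolerance = 1e-8)
  # OR-rule network is a supergraph of the AND-rule network
  net_and <- estimate_network(dat, rule = "AND", store_fits = FALSE)
  expect_true(all(net$weights[net_and$weights != 0] != 0))
})

test_that("network summaries count edges correctly", {
  pre <- make_preset("npiq_like")
  dat <- sample_ising(pre$params, 400, seed = 2)
  s <- network_summary(estimate_network(dat, store_fits = FALSE))
  expect_equal(s$possible_edges, 66L)

  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.2
  W[1, 3] <- W[3, 1] <- 0.4
  s2 <- network_summary(fake_network(W))
  expect_equal(s2$retained_edges, 2L)
  expect_equal(s2$mean_retained_weight, 0.3)
  expect_equal(s2$proportion_retained, 2 / 3)
  expect_equal(s2$proportion_positive, 1)

  neg <- fake_network(-W)
  expect_equal(network_summary(neg)$proportion_positive, 0)

  empty <- fake_network(matrix(0, 3, 3))
  se <- network_summary(empty)
  expect_equal(se$retained_edges, 0L)
  expect_true(is.na(se$mean_retained_weight))
  expect_true(is.na(se$proportion_positive))
})

test_that("tidy and glance expose the edge table and summary", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                       c("A", "B", "C")))
  W["A", "B"] <- W["B", "A"] <- 0.5
  W["A", "C"] <- W["C", "A"] <- -0.2
  net <- fake_network(W)
  td <- tidy(net)
  expect_equal(nrow(td), 3)
  expect_equal(td$weight[1], 0.5)  # sorted by |weight|
  expect_equal(sum(td$retained), 2)
  td_r <- tidy(net, retained_only = TRUE)
  expect_equal(nrow(td_r), 2)
  g <- glance(net)
  expect_equal(g$retained_edges, 2L)
  expect_equal(g$n_items, 3L)
})
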