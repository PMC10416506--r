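test_that("ising parameter validation enforces symmetry and zero diagonal", {
  om <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(ising_parameters(c(0, 0), om), "ising_parameters")
  bad <- om
  bad[1, 2] <- 1 + 1e-6
  expect_error(ising_parameters(c(0, 0), bad), "symmetric")
  bad2 <- om
  diag(bad2) <- 0.5
  expect_error(ising_parameters(c(0, 0), bad2), "diagonal")
})

test_that("exact enumeration reproduces closed-form cases", {
  # zero-parameter model: uniform over the four states
  par <- ising_parameters(c(0, 0), matrix(0, 2, 2))
  d <- exact_distribution(par)
  expect_equal(d$probability, rep(0.25, 4))
  # single item: logistic identity P(x = 1) = 3/4 at tau = log 3
  par1 <- ising_parameters(log(3), matrix(0, 1, 1))
  d1 <- exact_distribution(par1)
  expect_equal(d1$probability[d1[[1]] == 1], 0.75, tolerance = 1e-12)
  # probabilities normalize for random parameter draws
  for (s in 1:5) {
    pr <- random_ising(4, seed = 100 + s)
    expect_lt(abs(sum(exact_distribution(pr)$probability) - 1), 1e-10)
  }
})

test_that("enumerated conditionals equal the logistic form", {
  pr <- random_ising(3, seed = 42)
  d <- symptomnet:::ising_joint(pr)
  for (x2 in 0:1) for (x3 in 0:1) {
    sub <- d$states[, 2] == x2 & d$states[, 3] == x3
    p1 <- d$prob[sub & d$states[, 1] == 1] / sum(d$prob[sub])
    eta <- pr$thresholds[1] + pr$couplings[1, 2] * x2 +
      pr$couplings[1, 3] * x3
    expect_equal(unname(p1), plogis(unname(eta)), tolerance = 1e-8)
  }
})

test_that("the exact sampler is seeded and matches the enumeration", {
  pr <- random_ising(3, seed = 7)
  a <- sample_ising(pr, 500, seed = 3)
  b <- sample_ising(pr, 500, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, sample_ising(pr, 500, seed = 4)))

  n <- 100000
  dat <- as.matrix(sample_ising(pr, n, seed = 9))
  joint <- symptomnet:::ising_joint(pr)
  code <- dat %*% 2^(0:2)
  freq <- tabulate(code + 1, nbins = 8) / n
  truth <- joint$prob[order(joint$states %*% 2^(0:2))]
  se <- sqrt(truth * (1 - truth) / n)
  expect_true(all(abs(freq - truth) <= 4 * se))
})

test_that("the Gibbs sampler agrees with the enumeration and is seeded", {
  pr <- random_ising(3, seed = 13)
  truth <- ising_marginals(pr)
  n <- 20000
  dat <- sample_ising(pr, n, method = "gibbs", seed = 21)
  means <- colMeans(as.matrix(dat))
  # thinned Gibbs rows are not exactly independent; allow the same MC
  # band used for the i.i.d. sampler times a small autocorrelation factor
  se <- sqrt(truth * (1 - truth) / n)
  expect_true(all(abs(means - truth) <= 4 * 1.5 * se))
  expect_identical(dat, sample_ising(pr, n, method = "gibbs", seed = 21))

  # independence limit: zero couplings give Bernoulli(sigmoid(tau)) items
  pr0 <- ising_parameters(c(-0.4, 0.2, 0.9),
                          matrix(0, 3, 3), labels = c("a", "b", "c"))
  d0 <- sample_ising(pr0, 20000, method = "gibbs", seed = 2)
  m0 <- colMeans(as.matrix(d0))
  p0 <- plogis(pr0$thresholds)
  expect_true(all(abs(m0 - p0) <= 4 * sqrt(p0 * (1 - p0) / 20000)))
})

test_that("distributional quantities are invariant under item permutation", {
  pr <- random_ising(4, seed = 31)
  perm <- c(3, 1, 4, 2)
  pr_perm <- ising_parameters(pr$thresholds[perm],
                              pr$couplings[perm, perm],
                              labels = pr$labels[perm])
  expect_equal(ising_marginals(pr_perm),
               ising_marginals(pr)[perm], tolerance = 1e-12)
  # state probabilities match after relabeling
  d <- exact_distribution(pr)
  dp <- exact_distribution(pr_perm)
  key <- do.call(paste, as.data.frame(d[, pr$labels]))
  key_p <- do.call(paste, as.data.frame(dp[, pr$labels]))
  expect_equal(dp$probability[match(key, key_p)], d$probability,
               tolerance = 1e-12)
})

test_that("enumeration refuses oversized models and advises Gibbs", {
  pr <- ising_parameters(rep(0, 21), matrix(0, 21, 21))
  expect_error(exact_distribution(pr), "gibbs")
  expect_error(sample_ising(pr, 10), "gibbs")
  expect_silent(sample_ising(pr, 10, method = "gibbs", seed = 1))
})

test_that("presets encode the intended structure", {
  expect_error(make_preset("nope"), "npiq_like")
  ind <- make_preset("independent")
  expect_true(all(ind$params$couplings == 0))

  pre <- make_preset("npiq_like")
  W <- pre$params$couplings
  expect_equal(W["DEL", "HALL"], 1.51)
  expect_equal(W["AGIT", "IRR"], 1.31)
  expect_equal(W["ELAT", "DISN"], 1.21)
  expect_equal(W["HALL", "NITE"], 0.61)
  expect_equal(sum(W[lower.tri(W)] != 0), 57)
  expect_equal(sum(W[lower.tri(W)] == 0.15), 48)

  m <- ising_marginals(pre$params)
  expect_true(m["DEPD"] >= 0.449 && m["DEPD"] <= 0.489)
  expect_true(abs(m["IRR"] - 0.462) <= 0.02)
  expect_true(abs(m["ANX"] - 0.461) <= 0.02)
  expect_true(abs(m["APA"] - 0.458) <= 0.02)

  # disinhibition has the largest true absolute coupling sum
  expect_equal(names(which.max(rowSums(abs(W)))), "DISN")

  # JSON round trip preserves the model
  path <- withr::local_tempfile(fileext = ".json")
  write_preset_json(pre, path)
  back <- read_preset_json(path)
  expect_equal(back$params$couplings, pre$params$couplings)
  expect_equal(back$params$thresholds, pre$params$thresholds)
  expect_equal(back$n, pre$n)
})
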