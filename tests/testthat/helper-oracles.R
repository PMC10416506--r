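# Independent oracles and fixture builders used across the suite.

# Unpenalized logistic regression by straight Newton-Raphson on the
# full Hessian -- independent of the package's coordinate-descent solver.
newton_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  X1 <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X1))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X1 %*% b)
    p <- plogis(eta)
    W <- pmax(p * (1 - p), 1e-12)
    step <- solve(crossprod(X1 * W, X1), crossprod(X1, y - p))
    b <- b + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  b  # (intercept, slopes)
}

# Random small Ising parameters for property loops.
random_ising <- function(p, seed, coupling_sd = 0.7, threshold_sd = 0.8) {
  withr::with_seed(seed, {
    om <- matrix(0, p, p)
    om[lower.tri(om)] <- rnorm(choose(p, 2), sd = coupling_sd)
    om <- om + t(om)
    ising_parameters(rnorm(p, sd = threshold_sd), om,
                     labels = paste0("S", seq_len(p)))
  })
}

# Random binary design with a logistic response, for solver checks.
random_logistic_data <- function(n, p, seed) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * p, 1, runif(p, 0.25, 0.75)[rep(seq_len(p),
                                                          each = n)]),
                n, p)
    colnames(X) <- paste0("X", seq_len(p))
    beta <- rnorm(p, sd = 0.8)
    y <- rbinom(n, 1, plogis(-0.3 + as.vector(X %*% beta)))
    # guard against degenerate draws
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    for (j in seq_len(p)) if (length(unique(X[, j])) < 2) X[1:2, j] <- c(0, 1)
    list(X = X, y = y)
  })
}

# Minimal ising_network object around a given symmetric weight matrix.
fake_network <- function(W, n = 100, rule = "OR", gamma = 0.25) {
  if (is.null(rownames(W)))
    dimnames(W) <- list(paste0("V", seq_len(nrow(W))),
                        paste0("V", seq_len(nrow(W))))
  structure(
    list(weights = W,
         thresholds = setNames(rep(0, nrow(W)), rownames(W)),
         rule = rule, gamma = gamma, labels = rownames(W),
         unestimable = character(0), n = n, fits = NULL),
    class = "ising_network"
  )
}

# Minimal nodewise_fit for assemble_network contract tests.
fake_fit <- function(node, others, slopes, intercept = 0, gamma = 0.25) {
  structure(
    list(node = node, estimable = TRUE, intercept = intercept,
         slopes = setNames(slopes, others), lambda = 0.1, ebic = 0,
         path = NULL, gamma = gamma),
    class = "nodewise_fit"
  )
}

# Case-dropping bootstrap run with fully controlled correlations.
fake_casedrop_run <- function(correlations, proportions, B) {
  net <- fake_network(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  structure(
    list(type = "case_dropping", B = B, seed = 1,
         settings = list(), cor_method = "pearson", original = net,
         proportions = proportions, refused = numeric(0),
         correlations = correlations),
    class = "network_bootstrap"
  )
}

# Nonparametric run with controlled per-replicate edge weights.
# `weights` is a named list: "A--B" -> vector of B replicate values.
fake_np_run <- function(weights, B) {
  pairs <- strsplit(names(weights), "--", fixed = TRUE)
  labels <- unique(unlist(pairs))
  W <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(pairs)) {
    W[pairs[[i]][1], pairs[[i]][2]] <- mean(weights[[i]])
    W[pairs[[i]][2], pairs[[i]][1]] <- mean(weights[[i]])
  }
  net <- fake_network(W)
  # align item_a/item_b naming with the package's pair ordering
  ed <- symptomnet:::node_pairs(labels)
  edges <- dplyr::bind_rows(lapply(seq_len(B), function(b) {
    w <- vapply(seq_len(nrow(ed)), function(k) {
      key1 <- paste0(ed$item_a[k], "--", ed$item_b[k])
      key2 <- paste0(ed$item_b[k], "--", ed$item_a[k])
      v <- weights[[key1]] %||% weights[[key2]]
      if (is.null(v)) 0 else v[b]
    }, numeric(1))
    tibble::tibble(replicate = b, item_a = ed$item_a, item_b = ed$item_b,
                   weight = w)
  }))
  centrality <- dplyr::bind_rows(lapply(seq_len(B), function(b) {
    tibble::tibble(replicate = b, node = labels,
                   strength = 0, expected_influence = 0)
  }))
  structure(
    list(type = "nonparametric", B = B, seed = 1, settings = list(),
         original = net, edges = edges, centrality = centrality,
         flagged = NULL),
    class = "network_bootstrap"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small raw participant table builder for cohort tests.
toy_participant_table <- function() {
  items <- npiq_items()
  base <- tibble::tibble(
    id = paste0("P", 1:6),
    age = c(75, 80, 70, 45, 68, 82),
    cognitive_status = c("MCI", "normal", "dementia", "MCI", "dementia",
                         "dementia"),
    ad_etiology = c("primary", "primary", "non-contributing",
                    "contributing", "primary", "contributing"),
    visit_label = "initial"
  )
  m <- matrix(0L, 6, length(items), dimnames = list(NULL, items))
  m[, "DEPD"] <- 1L         # everyone endorses depression ...
  m[5, ] <- 0L              # ... except row 5: no symptoms at all
  m[6, "ANX"] <- 1L
  m[3, "DEL"] <- 1L
  # row 1 passes everything; row 2 fails status; row 3 fails etiology;
  # row 4 fails age; row 5 fails min symptoms; row 6 has a missing code
  m[6, "MOT"] <- 9L
  dplyr::bind_cols(base, tibble::as_tibble(as.data.frame(m)))
}
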