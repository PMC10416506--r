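# eLasso network estimation: nodewise L1-penalized logistic regressions,
# EBIC penalty selection, OR/AND edge rule, mean-of-coefficients weights.

#' Penalty grid for an L1 logistic path
#'
#' The largest penalty is the smallest value at which all slopes are zero
#' by the KKT condition at the intercept-only fit,
#' \eqn{\lambda_{max} = \max_k |\sum_i x_{ik}(y_i - \bar y)| / n};
#' the grid descends log-linearly to `lambda_max * min_ratio`.
#'
#' @param X Predictor matrix (columns are 0/1 items).
#' @param y Binary response vector (must not be constant).
#' @param n_lambdas Number of grid points (default 100).
#' @param min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @return Strictly decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(X, y, n_lambdas = 100, min_ratio = 0.01) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("Response is constant; no penalized path exists.", call. = FALSE)
  n <- nrow(X)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (n_lambdas < 1) stop("`n_lambdas` must be >= 1.", call. = FALSE)
  if (n_lambdas == 1) return(lambda_max)
  exp(seq(log(lambda_max), log(lambda_max * min_ratio),
          length.out = n_lambdas))
}

#' L1-penalized logistic regression
#'
#' Minimizes \eqn{-\ell(b_0, b)/n + \lambda \lVert b \rVert_1} with an
#' unpenalized intercept by coordinate descent on iteratively reweighted
#' least-squares approximations, warm starting along a decreasing
#' `lambda` sequence. Deterministic given its inputs.
#'
#' @param X Predictor matrix.
#' @param y Binary 0/1 response.
#' @param lambda Non-increasing vector of penalties (a single value is
#'   fine).
#' @param tol Convergence tolerance on the maximum parameter update
#'   (default 1e-7).
#' @param max_iter Outer iteration cap per path point (default 100).
#' @return A list with `lambda`, `intercept` (length L), `slopes`
#'   (p x L matrix), `loglik` (unpenalized log-likelihood at the
#'   solution), `df` (nonzero slope counts), `converged`, `kkt`
#'   (worst KKT violation) and `niter`.
#' @export
fit_l1_logistic <- function(X, y, lambda, tol = 1e-7, max_iter = 100) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (length(unique(y)) < 2)
    stop("Response is constant; the logistic model is degenerate.",
         call. = FALSE)
  lambda <- as.numeric(lambda)
  if (any(diff(lambda) > 0))
    stop("`lambda` must be non-increasing (warm starts descend the path).",
         call. = FALSE)
  # With binary predictors the loss depends on the data only through the
  # distinct (x, y) patterns and their counts, so collapse duplicates
  # into case weights: an exact reformulation that shrinks the row count.
  cw <- rep(1, nrow(X))
  if (ncol(X) <= 30 && all(X %in% c(0, 1))) {
    code <- as.vector(X %*% 2^(seq_len(ncol(X)) - 1)) + y * 2^ncol(X)
    agg <- vapply(split(seq_along(code), code), `[`, integer(1), 1L)
    if (length(agg) * 2 < nrow(X)) {
      cnt <- as.numeric(table(code))
      X <- X[agg, , drop = FALSE]
      y <- y[agg]
      cw <- cnt
    }
  }
  fit <- cd_logistic_path(X, y, cw, lambda, tol, as.integer(max_iter))
  slopes <- fit$beta
  rownames(slopes) <- colnames(X)
  # a path point that exhausts its iteration budget while satisfying the
  # KKT conditions to high precision is converged in every useful sense
  converged <- fit$converged | (fit$kkt < 1e-6 & lambda >= 1e-8)
  bad <- which(!converged)
  if (length(bad) > 0) {
    if (all(lambda[bad] < 1e-8)) {
      warning("No convergence at lambda ~ 0 (likely perfect separation); ",
              "coefficients capped by the iteration budget.", call. = FALSE)
    } else {
      stop("Coordinate descent failed to converge at lambda = ",
           signif(lambda[bad[1]], 4), " (KKT violation ",
           signif(fit$kkt[bad[1]], 4), "). Increase `max_iter` or `tol`.",
           call. = FALSE)
    }
  }
  fit$converged <- converged
  list(lambda = lambda, intercept = as.numeric(fit$intercept),
       slopes = slopes, loglik = as.numeric(fit$loglik),
       df = as.integer(colSums(slopes != 0)),
       converged = as.logical(fit$converged),
       kkt = as.numeric(fit$kkt), niter = as.integer(fit$niter))
}

#' Extended Bayesian Information Criterion
#'
#' \eqn{EBIC = -2\ell + k \log n + 2\gamma k \log p}, where k counts
#' nonzero slopes (the unpenalized intercept is not counted) and p is the
#' number of candidate predictors. Lower is better; `gamma = 0` reduces
#' to the ordinary BIC.
#'
#' @param loglik Unpenalized log-likelihood at the fitted parameters.
#' @param k Number of nonzero slopes.
#' @param n Sample size.
#' @param p_pred Number of candidate predictors.
#' @param gamma EBIC hyperparameter (0.25 recommended for binary
#'   networks).
#' @return The scalar criterion value.
#' @export
ebic <- function(loglik, k, n, p_pred, gamma = 0.25) {
  stopifnot(n >= 1, p_pred >= 1, all(k >= 0))
  -2 * loglik + k * log(n) + 2 * gamma * k * log(p_pred)
}

#' Fit one node's regularized neighbourhood regression
#'
#' Regresses item `node` on all other items over a shared penalty path
#' and selects the path point minimizing the EBIC; ties are broken toward
#' the larger penalty (sparser model). A constant response column yields
#' a flagged unestimable fit rather than an error.
#'
#' @param data Binary symptom data (data frame or matrix of 0/1 columns).
#' @param node Column index or name of the response item.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param n_lambdas,min_ratio Path construction, see [lambda_grid()].
#' @param tol,max_iter Solver controls, see [fit_l1_logistic()].
#' @return An object of class `nodewise_fit`: node label, intercept,
#'   named slopes, selected `lambda`, `ebic` at the selection, and the
#'   full `path` tibble (lambda, df, loglik, ebic).
#' @export
fit_node <- function(data, node, gamma = 0.25, n_lambdas = 100,
                     min_ratio = 0.01, tol = 1e-7, max_iter = 100) {
  m <- as_symptom_matrix(data)
  labels <- colnames(m)
  j <- if (is.character(node)) match(node, labels) else as.integer(node)
  if (is.na(j) || j < 1 || j > ncol(m))
    stop("Unknown node '", node, "'.", call. = FALSE)
  y <- m[, j]
  X <- m[, -j, drop = FALSE]
  others <- labels[-j]
  if (length(unique(y)) < 2) {
    return(structure(
      list(node = labels[j], estimable = FALSE,
           intercept = NA_real_,
           slopes = setNames(rep(NA_real_, length(others)), others),
           lambda = NA_real_, ebic = NA_real_, path = NULL, gamma = gamma),
      class = "nodewise_fit"
    ))
  }
  lambdas <- lambda_grid(X, y, n_lambdas = n_lambdas, min_ratio = min_ratio)
  fit <- fit_l1_logistic(X, y, lambdas, tol = tol, max_iter = max_iter)
  crit <- ebic(fit$loglik, fit$df, n = nrow(m), p_pred = ncol(X),
               gamma = gamma)
  sel <- which.min(crit)  # first minimum = largest lambda among ties
  structure(
    list(node = labels[j], estimable = TRUE,
         intercept = fit$intercept[sel],
         slopes = setNames(fit$slopes[, sel], others),
         lambda = fit$lambda[sel], ebic = crit[sel],
         path = tibble::tibble(lambda = fit$lambda, df = fit$df,
                               loglik = fit$loglik, ebic = crit,
                               converged = fit$converged),
         gamma = gamma),
    class = "nodewise_fit"
  )
}

#' @export
print.nodewise_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("Nodewise fit for", x$node, "(UNESTIMABLE: constant column)\n")
    return(invisible(x))
  }
  cat("Nodewise fit for ", x$node, ": lambda = ", signif(x$lambda, 4),
      ", EBIC = ", round(x$ebic, 2), ", ", sum(x$slopes != 0),
      " nonzero slopes\n", sep = "")
  invisible(x)
}

#' Combine nodewise fits into a weighted network
#'
#' Edge (j, k) is retained under the OR-rule iff either directed
#' coefficient b_jk or b_kj is nonzero, and under the AND-rule iff both
#' are. A retained edge's weight is the mean of the two directed
#' coefficients (including a zero member under OR); non-retained weights
#' are exactly 0. Unestimable nodes are isolated (incident edges 0) and
#' listed in the result, with a warning.
#'
#' @param fits List of p `nodewise_fit` objects, in item order.
#' @param rule `"OR"` (default) or `"AND"`.
#' @param n Sample size the fits were computed from (stored as metadata).
#' @return An object of class `ising_network`.
#' @export
assemble_network <- function(fits, rule = c("OR", "AND"), n = NA_integer_) {
  rule <- match.arg(rule)
  labels <- purrr::map_chr(fits, "node")
  p <- length(labels)
  if (p < 2) stop("Need at least two nodewise fits.", call. = FALSE)
  B <- matrix(0, p, p, dimnames = list(labels, labels))  # B[j,k] = b_jk
  thresholds <- setNames(rep(NA_real_, p), labels)
  unestimable <- character(0)
  for (f in fits) {
    j <- match(f$node, labels)
    if (!isTRUE(f$estimable)) {
      unestimable <- c(unestimable, f$node)
      next
    }
    thresholds[j] <- f$intercept
    B[j, names(f$slopes)] <- f$slopes
  }
  if (length(unestimable) > 0) {
    warning("Unestimable (constant) nodes isolated in the network: ",
            paste(unestimable, collapse = ", "), call. = FALSE)
    B[unestimable, ] <- 0
    B[, unestimable] <- 0
  }
  keep <- if (rule == "OR") (B != 0) | (t(B) != 0) else (B != 0) & (t(B) != 0)
  W <- ifelse(keep, (B + t(B)) / 2, 0)
  diag(W) <- 0
  gammas <- unique(purrr::map_dbl(fits, ~ .x$gamma %||% NA_real_))
  structure(
    list(weights = W, thresholds = thresholds, rule = rule,
         gamma = gammas[1], labels = labels, unestimable = unestimable,
         n = n, fits = fits),
    class = "ising_network"
  )
}

#' Estimate a symptom network by eLasso
#'
#' Runs [fit_node()] for every item and combines the p regularized
#' logistic regressions with [assemble_network()]. Deterministic given
#' its inputs.
#'
#' @param data Binary symptom data: a data frame or matrix whose columns
#'   are 0/1 item indicators (one row per participant).
#' @param gamma EBIC hyperparameter (default 0.25, recommended for binary
#'   networks).
#' @param rule Edge-retention rule, `"OR"` (default) or `"AND"`.
#' @param n_lambdas,min_ratio Path construction, see [lambda_grid()].
#' @param tol,max_iter Solver controls, see [fit_l1_logistic()].
#' @param store_fits Keep the per-node path objects on the result
#'   (default TRUE; disable inside bootstrap loops to save memory).
#' @return An object of class `ising_network` with elements `weights`
#'   (symmetric p x p matrix, zero diagonal), `thresholds` (nodewise
#'   intercepts), `rule`, `gamma`, `labels`, `unestimable` and `n`.
#' @seealso [network_summary()], [centrality_table()], [tidy.ising_network()]
#' @export
estimate_network <- function(data, gamma = 0.25, rule = c("OR", "AND"),
                             n_lambdas = 100, min_ratio = 0.01,
                             tol = 1e-7, max_iter = 100, store_fits = TRUE) {
  rule <- match.arg(rule)
  m <- as_symptom_matrix(data)
  fits <- purrr::map(seq_len(ncol(m)), function(j) {
    fit_node(m, j, gamma = gamma, n_lambdas = n_lambdas,
             min_ratio = min_ratio, tol = tol, max_iter = max_iter)
  })
  net <- assemble_network(fits, rule = rule, n = nrow(m))
  if (!store_fits) net$fits <- NULL
  net
}

#' @export
print.ising_network <- function(x, ...) {
  s <- network_summary(x)
  cat("eLasso Ising network: ", length(x$labels), " items, n = ", x$n,
      " (rule = ", x$rule, ", gamma = ", x$gamma, ")\n", sep = "")
  cat("  retained edges: ", s$retained_edges, " of ", s$possible_edges,
      if (!is.na(s$mean_retained_weight))
        paste0(", mean weight ", round(s$mean_retained_weight, 3)),
      "\n", sep = "")
  if (length(x$unestimable) > 0)
    cat("  unestimable nodes:", paste(x$unestimable, collapse = ", "), "\n")
  invisible(x)
}

#' Summary counts and weights of an estimated network
#'
#' @param net An `ising_network`.
#' @return One-row tibble: `possible_edges` (p(p-1)/2), `retained_edges`,
#'   `proportion_retained`, `mean_retained_weight` (over retained edges
#'   only; `NA` when no edge is retained), `proportion_positive` (among
#'   retained edges; `NA` when none).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  w <- lower_tri_vec(net$weights)
  retained <- w[w != 0]
  tibble::tibble(
    possible_edges = length(w),
    retained_edges = length(retained),
    proportion_retained = length(retained) / length(w),
    mean_retained_weight = if (length(retained) > 0) mean(retained) else NA_real_,
    proportion_positive = if (length(retained) > 0) mean(retained > 0) else NA_real_
  )
}

#' Tidy an estimated network into an edge tibble
#'
#' @param x An `ising_network`.
#' @param retained_only Keep only retained (nonzero) edges (default
#'   FALSE: all p(p-1)/2 pairs with a `retained` flag).
#' @param ... Unused.
#' @return Tibble with `item_a`, `item_b`, `weight`, `retained`, sorted
#'   by absolute weight (descending).
#' @export
tidy.ising_network <- function(x, retained_only = FALSE, ...) {
  pairs <- node_pairs(x$labels)
  out <- tibble::tibble(
    item_a = pairs$item_a, item_b = pairs$item_b,
    weight = x$weights[cbind(pairs$i, pairs$j)]
  )
  out$retained <- out$weight != 0
  if (retained_only) out <- out[out$retained, , drop = FALSE]
  out[order(-abs(out$weight)), , drop = FALSE]
}

#' One-row summary of an estimated network
#'
#' @param x An `ising_network`.
#' @param ... Unused.
#' @return [network_summary()] plus `n_items`, `n`, `rule`, `gamma`.
#' @export
glance.ising_network <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_items = length(x$labels), n = x$n,
                   rule = x$rule, gamma = x$gamma),
    network_summary(x)
  )
}
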