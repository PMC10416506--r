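# Network accuracy machinery: nonparametric bootstrap edge CIs,
# case-dropping subset bootstrap with the CS coefficient, and
# bootstrapped difference tests.

# estimate quietly, recording unestimable nodes instead of warning
estimate_quietly <- function(m, settings) {
  withCallingHandlers(
    estimate_network(m, gamma = settings$gamma, rule = settings$rule,
                     n_lambdas = settings$n_lambdas,
                     min_ratio = settings$min_ratio, tol = settings$tol,
                     max_iter = settings$max_iter, store_fits = FALSE),
    warning = function(w) {
      if (grepl("Unestimable", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
}

bootstrap_settings <- function(gamma, rule, n_lambdas, min_ratio, tol,
                               max_iter) {
  list(gamma = gamma, rule = rule, n_lambdas = n_lambdas,
       min_ratio = min_ratio, tol = tol, max_iter = max_iter)
}

replicate_records <- function(net, b) {
  ed <- node_pairs(net$labels)
  list(
    edges = tibble::tibble(replicate = b, item_a = ed$item_a,
                           item_b = ed$item_b,
                           weight = net$weights[cbind(ed$i, ed$j)]),
    centrality = tibble::tibble(
      replicate = b, node = net$labels,
      strength = as.numeric(rowSums(abs(net$weights))),
      expected_influence = as.numeric(rowSums(net$weights))
    ),
    flagged = if (length(net$unestimable) > 0)
      tibble::tibble(replicate = b, node = net$unestimable)
    else NULL
  )
}

#' Nonparametric bootstrap of an estimated network
#'
#' Resamples the n participants with replacement B times and re-runs the
#' full eLasso estimator with identical settings on each replicate.
#' Replicate b always uses the b-th substream seed derived from `seed`,
#' so results do not depend on evaluation order or worker count.
#' Replicates in which an item becomes constant are retained with the
#' affected nodes flagged, not discarded.
#'
#' @param data Binary symptom data (rows = participants).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the replicate substreams.
#' @param gamma,rule,n_lambdas,min_ratio,tol,max_iter Estimator settings,
#'   applied both to the original fit and to every replicate.
#' @return An object of class `network_bootstrap` (type
#'   `"nonparametric"`) holding the original network, per-replicate edge
#'   weights and centralities, and flagged nodes.
#' @export
nonparametric_bootstrap <- function(data, B = 1000, seed = NULL,
                                    gamma = 0.25, rule = "OR",
                                    n_lambdas = 100, min_ratio = 0.01,
                                    tol = 1e-7, max_iter = 100) {
  if (B < 1) stop("`B` must be at least 1.", call. = FALSE)
  m <- as_symptom_matrix(data)
  settings <- bootstrap_settings(gamma, rule, n_lambdas, min_ratio, tol,
                                 max_iter)
  original <- estimate_quietly(m, settings)
  seeds <- replicate_seeds(seed, B)
  recs <- purrr::map(seq_len(B), function(b) {
    idx <- with_seed(seeds[b], sample.int(nrow(m), nrow(m), replace = TRUE))
    replicate_records(estimate_quietly(m[idx, , drop = FALSE], settings), b)
  })
  structure(
    list(type = "nonparametric", B = B, seed = seed, settings = settings,
         original = original,
         edges = dplyr::bind_rows(purrr::map(recs, "edges")),
         centrality = dplyr::bind_rows(purrr::map(recs, "centrality")),
         flagged = dplyr::bind_rows(purrr::map(recs, "flagged"))),
    class = "network_bootstrap"
  )
}

#' Case-dropping subset bootstrap
#'
#' For each drop proportion q, draws B subsamples of
#' \eqn{\lceil (1-q) n \rceil} participants without replacement,
#' re-estimates the network, and records the correlation of each
#' centrality index (and the edge-weight vector) with the full-sample
#' values. Proportions whose subsample would fall below 3p rows are
#' refused with a warning.
#'
#' @param data Binary symptom data.
#' @param proportions Drop-proportion grid, default 0.10 to 0.75 in steps
#'   of 0.05.
#' @param B Replicates per proportion (default 250).
#' @param seed Integer seed (replicate-indexed substreams).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param gamma,rule,n_lambdas,min_ratio,tol,max_iter Estimator settings.
#' @return A `network_bootstrap` of type `"case_dropping"` with a
#'   `correlations` tibble (proportion, replicate, index, correlation)
#'   and the refused proportions in `refused`.
#' @export
case_dropping_bootstrap <- function(data,
                                    proportions = seq(0.10, 0.75, by = 0.05),
                                    B = 250, seed = NULL,
                                    cor_method = c("pearson", "spearman"),
                                    gamma = 0.25, rule = "OR",
                                    n_lambdas = 100, min_ratio = 0.01,
                                    tol = 1e-7, max_iter = 100) {
  cor_method <- match.arg(cor_method)
  if (length(proportions) < 1)
    stop("`proportions` must be a non-empty grid.", call. = FALSE)
  if (any(proportions <= 0 | proportions >= 1))
    stop("`proportions` must lie strictly between 0 and 1.", call. = FALSE)
  if (B < 1) stop("`B` must be at least 1.", call. = FALSE)
  m <- as_symptom_matrix(data)
  n <- nrow(m)
  p <- ncol(m)
  settings <- bootstrap_settings(gamma, rule, n_lambdas, min_ratio, tol,
                                 max_iter)
  original <- estimate_quietly(m, settings)
  full <- replicate_records(original, 0L)
  keep_size <- ceiling((1 - proportions) * n)
  refused <- proportions[keep_size < 3 * p]
  if (length(refused) > 0) {
    warning("Refusing drop proportions leaving fewer than 3p = ", 3 * p,
            " rows: ", paste(refused, collapse = ", "), call. = FALSE)
  }
  grid <- proportions[keep_size >= 3 * p]
  if (length(grid) == 0)
    stop("Every requested drop proportion was refused; the grid is empty.",
         call. = FALSE)
  seeds <- matrix(replicate_seeds(seed, B * length(grid)),
                  nrow = B, ncol = length(grid))
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = cor_method)
  }
  rows <- purrr::map(seq_along(grid), function(g) {
    q <- grid[g]
    keep <- ceiling((1 - q) * n)
    purrr::map(seq_len(B), function(b) {
      idx <- with_seed(seeds[b, g], sample.int(n, keep, replace = FALSE))
      net <- estimate_quietly(m[idx, , drop = FALSE], settings)
      rec <- replicate_records(net, b)
      tibble::tibble(
        proportion = q, replicate = b,
        index = c("strength", "expected_influence", "edge"),
        correlation = c(
          safe_cor(full$centrality$strength, rec$centrality$strength),
          safe_cor(full$centrality$expected_influence,
                   rec$centrality$expected_influence),
          safe_cor(full$edges$weight, rec$edges$weight)
        )
      )
    })
  })
  structure(
    list(type = "case_dropping", B = B, seed = seed, settings = settings,
         cor_method = cor_method, original = original,
         proportions = grid, refused = refused,
         correlations = dplyr::bind_rows(purrr::flatten(rows))),
    class = "network_bootstrap"
  )
}

#' @export
print.network_bootstrap <- function(x, ...) {
  cat("Network bootstrap (", x$type, "): B = ", x$B, ", ",
      length(x$original$labels), " items, n = ", x$original$n, "\n",
      sep = "")
  if (x$type == "case_dropping")
    cat("  drop proportions:", paste(x$proportions, collapse = ", "), "\n")
  invisible(x)
}

#' Percentile bootstrap confidence intervals for edge weights
#'
#' @param run A nonparametric `network_bootstrap` with B >= 2.
#' @param level Confidence level (default 0.95); percentile bounds at
#'   (1-level)/2 and 1-(1-level)/2 (R's default type-7 quantiles).
#' @return Tibble per edge: `item_a`, `item_b`, `weight` (original),
#'   `boot_mean`, `lower`, `upper`.
#' @export
edge_ci_table <- function(run, level = 0.95) {
  stopifnot(inherits(run, "network_bootstrap"))
  if (run$type != "nonparametric")
    stop("Edge CIs require a nonparametric bootstrap run.", call. = FALSE)
  if (run$B < 2)
    stop("Confidence intervals require at least 2 bootstrap replicates.",
         call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("`level` must be in (0, 1).", call. = FALSE)
  alpha <- (1 - level) / 2
  orig <- tidy(run$original)
  out <- run$edges |>
    dplyr::group_by(.data$item_a, .data$item_b) |>
    dplyr::summarise(
      boot_mean = mean(.data$weight),
      lower = quantile(.data$weight, alpha, names = FALSE),
      upper = quantile(.data$weight, 1 - alpha, names = FALSE),
      .groups = "drop"
    )
  dplyr::left_join(orig[, c("item_a", "item_b", "weight")], out,
                   by = c("item_a", "item_b"))
}

#' Correlation-stability (CS) coefficient
#'
#' CS(cor = r) is the maximum drop proportion q in the grid at which at
#' least `prob` of the replicates keep a correlation of at least
#' `r_threshold` with the full-sample values, and 0 when no proportion
#' qualifies. Values above .50 indicate a stable index; values below .25
#' an untrustworthy one. Replicates whose correlation is undefined
#' (degenerate subsample) are excluded pairwise and counted in
#' `failure_rate`.
#'
#' @param run A case-dropping `network_bootstrap`.
#' @param r_threshold Correlation threshold (default 0.7).
#' @param prob Required fraction of qualifying replicates (default 0.95).
#' @return Tibble per index: `index`, `cs`, `band`, `failure_rate`; the
#'   per-proportion qualifying fractions are attached as attribute
#'   `"detail"`.
#' @export
cs_coefficient <- function(run, r_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(run, "network_bootstrap"))
  if (run$type != "case_dropping")
    stop("The CS coefficient requires a case-dropping bootstrap run.",
         call. = FALSE)
  if (length(run$proportions) == 0)
    stop("Empty drop-proportion grid.", call. = FALSE)
  detail <- run$correlations |>
    dplyr::group_by(.data$index, .data$proportion) |>
    dplyr::summarise(
      fraction_ok = mean(.data$correlation >= r_threshold, na.rm = TRUE),
      n_failed = sum(is.na(.data$correlation)),
      .groups = "drop"
    )
  out <- detail |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(
      cs = {
        ok <- .data$proportion[.data$fraction_ok >= prob]
        if (length(ok) > 0) max(ok) else 0
      },
      failure_rate = sum(.data$n_failed) / (run$B * dplyr::n()),
      .groups = "drop"
    )
  out$band <- dplyr::case_when(
    out$cs > 0.50 ~ "stable (> .50)",
    out$cs >= 0.25 ~ "borderline (.25-.50)",
    TRUE ~ "untrustworthy (< .25)"
  )
  out <- out[, c("index", "cs", "band", "failure_rate")]
  attr(out, "detail") <- detail
  out
}

#' Bootstrapped difference tests
#'
#' For each pair of targets (retained edges, node strengths, or expected
#' influences) computes the percentile CI of the replicate-wise
#' difference; the difference is significant iff zero lies outside the
#' CI. All ordered pairs are returned (the matrix is symmetric up to CI
#' sign; the diagonal is non-significant by definition).
#'
#' @param run A nonparametric `network_bootstrap`.
#' @param targets `"edges"` (retained edges of the original network),
#'   `"strength"`, or `"expected_influence"`.
#' @param level CI level (default 0.95).
#' @return Tibble: `target_a`, `target_b`, `lower`, `upper`,
#'   `significant`.
#' @export
difference_tests <- function(run,
                             targets = c("edges", "strength",
                                         "expected_influence"),
                             level = 0.95) {
  stopifnot(inherits(run, "network_bootstrap"))
  targets <- match.arg(targets)
  if (run$type != "nonparametric")
    stop("Difference tests require a nonparametric bootstrap run.",
         call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("`level` must be in (0, 1).", call. = FALSE)
  if (targets == "edges") {
    orig <- tidy(run$original, retained_only = TRUE)
    if (nrow(orig) < 2)
      stop("Fewer than 2 retained edges; nothing to compare.", call. = FALSE)
    key <- paste(orig$item_a, orig$item_b, sep = "--")
    wide <- run$edges |>
      dplyr::semi_join(orig, by = c("item_a", "item_b")) |>
      dplyr::mutate(target = paste(.data$item_a, .data$item_b, sep = "--"))
    V <- matrix(NA_real_, run$B, length(key), dimnames = list(NULL, key))
    V[cbind(wide$replicate, match(wide$target, key))] <- wide$weight
  } else {
    key <- run$original$labels
    V <- matrix(NA_real_, run$B, length(key), dimnames = list(NULL, key))
    V[cbind(run$centrality$replicate,
            match(run$centrality$node, key))] <-
      run$centrality[[targets]]
    if (length(key) < 2)
      stop("Fewer than 2 nodes; nothing to compare.", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  grid <- expand.grid(a = seq_along(key), b = seq_along(key))
  lo <- up <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    d <- V[, grid$a[r]] - V[, grid$b[r]]
    d <- d[!is.na(d)]
    lo[r] <- quantile(d, alpha, names = FALSE)
    up[r] <- quantile(d, 1 - alpha, names = FALSE)
  }
  tibble::tibble(
    target_a = key[grid$a], target_b = key[grid$b],
    lower = lo, upper = up,
    significant = (lo > 0 | up < 0) & grid$a != grid$b
  )
}
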