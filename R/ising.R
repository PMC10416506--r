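#' NPI-Q item labels in administration order
#'
#' The twelve Neuropsychiatric Inventory Questionnaire items: delusions,
#' hallucinations, agitation/aggression, depression/dysphoria, anxiety,
#' elation/euphoria, apathy/indifference, disinhibition,
#' irritability/lability, motor disturbance, nighttime behaviors and
#' appetite/eating problems.
#'
#' @return Character vector of the 12 item abbreviations.
#' @export
npiq_items <- function() {
  c("DEL", "HALL", "AGIT", "DEPD", "ANX", "ELAT",
    "APA", "DISN", "IRR", "MOT", "NITE", "APP")
}

#' Ising model parameters for binary symptom data
#'
#' Defines the pairwise Markov random field over p items coded
#' \{0, 1\}: \eqn{P(x) \propto \exp(\sum_i \tau_i x_i + \sum_{i<j}
#' \Omega_{ij} x_i x_j)}. The thresholds \eqn{\tau} are item dispositions
#' on the log-odds scale; the couplings \eqn{\Omega} are the symmetric
#' pairwise dependencies with zero diagonal.
#'
#' @param thresholds Numeric vector of length p (log-odds scale).
#' @param couplings Symmetric numeric p x p matrix, zero diagonal.
#' @param labels Optional character vector of p item labels.
#' @return An object of class `ising_parameters`.
#' @export
ising_parameters <- function(thresholds, couplings, labels = NULL) {
  thresholds <- as.numeric(thresholds)
  p <- length(thresholds)
  if (p < 1) stop("Need at least one item.", call. = FALSE)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(p, p)))
    stop("`couplings` must be ", p, " x ", p, ".", call. = FALSE)
  if (max(abs(couplings - t(couplings))) > 1e-12)
    stop("`couplings` must be symmetric (tolerance 1e-12).", call. = FALSE)
  if (any(diag(couplings) != 0))
    stop("`couplings` must have an exactly zero diagonal.", call. = FALSE)
  if (is.null(labels)) {
    labels <- colnames(couplings) %||% paste0("V", seq_len(p))
  }
  if (length(labels) != p) stop("`labels` must have length ", p, ".", call. = FALSE)
  dimnames(couplings) <- list(labels, labels)
  names(thresholds) <- labels
  structure(
    list(thresholds = thresholds, couplings = couplings, labels = labels),
    class = "ising_parameters"
  )
}

#' @export
print.ising_parameters <- function(x, ...) {
  cat("Ising model parameters:", length(x$labels), "items\n")
  cat("  items:", paste(x$labels, collapse = ", "), "\n")
  nz <- sum(x$couplings[lower.tri(x$couplings)] != 0)
  cat("  nonzero couplings:", nz, "of",
      choose(length(x$labels), 2), "\n")
  invisible(x)
}

# capacity guard shared by enumeration-based operations
check_enumerable <- function(p) {
  if (p > 20) {
    stop("Exact enumeration over 2^", p, " states is not feasible (p > 20); ",
         "use sample_ising(..., method = \"gibbs\") instead.",
         call. = FALSE)
  }
}

# All 2^p states (integer matrix) in a fixed, reproducible order.
ising_states <- function(p) {
  g <- do.call(expand.grid, rep(list(0:1), p))
  m <- as.matrix(g)[, seq_len(p), drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- NULL
  m
}

# states + normalized probabilities; log-domain accumulation.
ising_joint <- function(params) {
  p <- length(params$labels)
  check_enumerable(p)
  states <- ising_states(p)
  logw <- as.vector(states %*% params$thresholds) +
    0.5 * rowSums((states %*% params$couplings) * states)
  logz <- log_sum_exp(logw)
  list(states = states, prob = exp(logw - logz))
}

#' Exact state distribution of an Ising model
#'
#' Enumerates all 2^p binary states and returns their normalized
#' probabilities. Feasible for p <= 20; larger models should be sampled
#' with the Gibbs sampler.
#'
#' @param params An [ising_parameters()] object.
#' @return A tibble with one 0/1 column per item plus a `probability`
#'   column summing to 1.
#' @export
exact_distribution <- function(params) {
  stopifnot(inherits(params, "ising_parameters"))
  joint <- ising_joint(params)
  out <- tibble::as_tibble(as.data.frame(joint$states))
  names(out) <- params$labels
  out$probability <- joint$prob
  out
}

#' Exact marginal endorsement probabilities of an Ising model
#'
#' @param params An [ising_parameters()] object (p <= 20).
#' @return Named numeric vector of P(item = 1).
#' @export
ising_marginals <- function(params) {
  joint <- ising_joint(params)
  setNames(as.vector(crossprod(joint$states, joint$prob)), params$labels)
}

#' Sample binary symptom matrices from an Ising model
#'
#' `method = "exact"` draws i.i.d. rows from the fully enumerated joint
#' distribution (p <= 20). `method = "gibbs"` runs a single-site Gibbs
#' sampler using the logistic conditionals
#' \eqn{P(x_j = 1 \mid x_{-j}) = \sigma(\tau_j + \sum_k \Omega_{jk} x_k)},
#' retaining one row per `thin` full sweeps after `burnin` sweeps.
#'
#' @param params An [ising_parameters()] object.
#' @param n Number of rows to draw.
#' @param method `"exact"` or `"gibbs"`.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   output. The caller's RNG state is restored afterwards.
#' @param burnin Gibbs burn-in sweeps (default 200).
#' @param thin Full sweeps between retained rows (default 5).
#' @return A tibble of n rows of 0/1 item indicators.
#' @export
sample_ising <- function(params, n, method = c("exact", "gibbs"),
                         seed = NULL, burnin = 200, thin = 5) {
  stopifnot(inherits(params, "ising_parameters"))
  method <- match.arg(method)
  if (n < 1) stop("`n` must be at least 1.", call. = FALSE)
  p <- length(params$labels)
  m <- if (method == "exact") {
    joint <- ising_joint(params)
    idx <- with_seed(seed, sample.int(nrow(joint$states), n, replace = TRUE,
                                      prob = joint$prob))
    joint$states[idx, , drop = FALSE]
  } else {
    if (burnin < 0) stop("`burnin` must be >= 0.", call. = FALSE)
    if (thin < 1) stop("`thin` must be >= 1.", call. = FALSE)
    with_seed(seed, gibbs_sample_ising(params$thresholds, params$couplings,
                                       as.integer(n), as.integer(burnin),
                                       as.integer(thin)))
  }
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- params$labels
  out
}
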