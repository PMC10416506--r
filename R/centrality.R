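# Node centrality: strength, expected influence, z-standardization and
# rank orders on an estimated network.

#' Node strength
#'
#' Sum of the absolute values of all edge weights incident to each node,
#' \eqn{s_i = \sum_j |W_{ij}|}.
#'
#' @param net An `ising_network`.
#' @return Tibble with `node` and `strength`.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  tibble::tibble(node = net$labels,
                 strength = as.numeric(rowSums(abs(net$weights))))
}

#' Expected influence
#'
#' Signed sum of all edge weights incident to each node,
#' \eqn{EI_i = \sum_j W_{ij}}; coincides with strength when no edge is
#' negative.
#'
#' @param net An `ising_network`.
#' @return Tibble with `node` and `expected_influence`.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "ising_network"))
  tibble::tibble(node = net$labels,
                 expected_influence = as.numeric(rowSums(net$weights)))
}

#' Standardize centrality values and rank them
#'
#' z-scores use the population (divide-by-p) standard deviation by
#' default, matching the usual plotted convention for a fixed node set.
#' Ranks are descending (rank 1 = largest value); ties are broken by the
#' node-label order supplied.
#'
#' @param values Numeric vector of per-node centrality values.
#' @param labels Node labels (defaults to `names(values)`).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Tibble with `node`, `value`, `z`, `rank` and a `degenerate`
#'   attribute flag; constant input yields flagged zeros with a warning.
#' @export
standardize_and_rank <- function(values, labels = names(values),
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  values <- as.numeric(values)
  p <- length(values)
  if (p < 2) stop("Need at least two values to standardize.", call. = FALSE)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  s <- sd(values)
  if (sd_type == "population") s <- s * sqrt((p - 1) / p)
  degenerate <- !is.finite(s) || s == 0
  if (degenerate) {
    warning("Constant centrality values: z-scores are undefined, ",
            "returning zeros.", call. = FALSE)
    z <- rep(0, p)
  } else {
    z <- (values - mean(values)) / s
  }
  out <- tibble::tibble(node = labels, value = values, z = z)
  out$rank <- rank_descending(values, labels)
  attr(out, "degenerate") <- degenerate
  out
}

# descending rank with ties broken by label order
rank_descending <- function(values, labels) {
  ord <- order(-values, seq_along(labels))
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

#' Centrality table for an estimated network
#'
#' Strength and expected influence with standardized z-scores and
#' descending rank orders.
#'
#' @param net An `ising_network`.
#' @param sd_type Passed to [standardize_and_rank()].
#' @return Tibble with one row per node: `node`, `strength`,
#'   `expected_influence`, `z_strength`, `z_expected_influence`,
#'   `rank_strength`, `rank_expected_influence`.
#' @export
centrality_table <- function(net, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  s <- node_strength(net)
  ei <- expected_influence(net)
  zs <- standardize_and_rank(s$strength, s$node, sd_type = sd_type)
  zei <- standardize_and_rank(ei$expected_influence, ei$node,
                              sd_type = sd_type)
  tibble::tibble(
    node = s$node,
    strength = s$strength,
    expected_influence = ei$expected_influence,
    z_strength = zs$z,
    z_expected_influence = zei$z,
    rank_strength = zs$rank,
    rank_expected_influence = zei$rank
  )
}

#' Plot centrality rank orders
#'
#' Standardized strength and expected influence, nodes ordered from
#' highest to lowest strength.
#'
#' @param net An `ising_network`.
#' @param sd_type Passed to [centrality_table()].
#' @return A ggplot object.
#' @export
plot_centrality <- function(net, sd_type = "population") {
  ct <- centrality_table(net, sd_type = sd_type)
  long <- tidyr::pivot_longer(
    ct[, c("node", "z_strength", "z_expected_influence")],
    cols = -"node", names_to = "index", values_to = "z",
    names_prefix = "z_"
  )
  long$node <- factor(long$node,
                      levels = ct$node[order(ct$strength)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$node)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(ggplot2::aes(group = .data$index)) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "z-score", y = NULL) +
    ggplot2::theme_minimal()
}
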