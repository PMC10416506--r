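# Force-directed layout: Fruchterman-Reingold with absolute edge weights
# as attraction multipliers, seeded initial positions and linear cooling.

#' Fruchterman-Reingold layout of an estimated network
#'
#' Standard FR iteration on the unit square: repulsive force
#' \eqn{k^2/d} between every node pair, attractive force
#' \eqn{|w| d^2 / k} along every edge (so strongly tied nodes end up
#' closer together), displacement capped by a quadratically cooling
#' temperature, with \eqn{k = \sqrt{area/p}}. Reproducible for a fixed
#' seed and weight matrix; a single node is placed at the origin.
#'
#' @param net An `ising_network` (or a symmetric weight matrix).
#' @param iterations Number of iterations (default 500).
#' @param seed Seed for the initial positions (default 42).
#' @param area Layout area constant (default 1: the unit square).
#' @return Tibble with `node`, `x`, `y`; the per-iteration layout energy
#'   trace is attached as attribute `"energy"`, plus `"iterations"` and
#'   `"seed"`.
#' @export
fruchterman_reingold <- function(net, iterations = 500, seed = 42,
                                 area = 1) {
  W <- if (inherits(net, "ising_network")) net$weights else as.matrix(net)
  labels <- rownames(W) %||% paste0("V", seq_len(nrow(W)))
  p <- nrow(W)
  if (p == 1) {
    out <- tibble::tibble(node = labels, x = 0, y = 0)
    attr(out, "energy") <- numeric(0)
    attr(out, "iterations") <- 0L
    attr(out, "seed") <- seed
    return(out)
  }
  A <- abs(W)
  k <- sqrt(area / p)
  pos <- with_seed(seed, matrix(runif(2 * p, -0.5, 0.5), ncol = 2))
  t0 <- 0.1 * sqrt(area)
  energy <- numeric(iterations)
  eps <- 1e-9
  for (it in seq_len(iterations)) {
    disp <- matrix(0, p, 2)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < eps] <- eps
    # repulsion between all pairs
    f_rep <- k^2 / d^2
    diag(f_rep) <- 0
    disp[, 1] <- rowSums(f_rep * dx)
    disp[, 2] <- rowSums(f_rep * dy)
    # attraction along weighted edges
    f_att <- A * d / k
    disp[, 1] <- disp[, 1] - rowSums(f_att * dx)
    disp[, 2] <- disp[, 2] - rowSums(f_att * dy)
    # cap displacement by the cooling temperature (quadratic cooling:
    # late steps shrink fast enough that the layout settles instead of
    # oscillating around the energy minimum)
    temp <- t0 * (1 - (it - 1) / iterations)^2
    len <- sqrt(rowSums(disp^2))
    len[len < eps] <- eps
    # damp uncapped (small-force) moves by the cooling fraction as well,
    # so the layout settles instead of oscillating around the optimum
    step <- pmin(len, temp) / len * (temp / t0)
    pos <- pos + disp * step
    # FR potential: attractive |w| d^3 / (3k) minus repulsive k^2 log d
    d2 <- sqrt(outer(pos[, 1], pos[, 1], "-")^2 +
                 outer(pos[, 2], pos[, 2], "-")^2)
    d2[d2 < eps] <- eps
    lt <- lower.tri(d2)
    energy[it] <- sum(A[lt] * d2[lt]^3 / (3 * k)) - sum(k^2 * log(d2[lt]))
  }
  out <- tibble::tibble(node = labels, x = pos[, 1], y = pos[, 2])
  attr(out, "energy") <- energy
  attr(out, "iterations") <- as.integer(iterations)
  attr(out, "seed") <- seed
  out
}

#' Plot an estimated network
#'
#' Nodes at a Fruchterman-Reingold layout, edges drawn with width
#' proportional to |weight| and colour by sign.
#'
#' @param object An `ising_network`.
#' @param layout Optional precomputed layout from
#'   [fruchterman_reingold()].
#' @param seed Layout seed when `layout` is not supplied.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ising_network <- function(object, layout = NULL, seed = 42, ...) {
  if (is.null(layout)) layout <- fruchterman_reingold(object, seed = seed)
  edges <- tidy(object, retained_only = TRUE)
  edges <- dplyr::left_join(edges, layout, by = c(item_a = "node")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(layout, by = c(item_b = "node")) |>
    dplyr::rename(xb = "x", yb = "y")
  gg <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    gg <- gg + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      alpha = 0.6, show.legend = c(linewidth = FALSE, colour = FALSE)
    ) +
      ggplot2::scale_linewidth(range = c(0.2, 2.5)) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                              `FALSE` = "#B2182B"))
  }
  gg +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        size = 9, shape = 21, fill = "grey90") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node), size = 2.6) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
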