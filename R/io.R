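# Plain-text serialization: symptom matrices (CSV), networks (JSON,
# edge-list CSV, GraphML), presets (JSON) and filter logs (JSON/text).

#' Read and write binary symptom matrices as CSV
#'
#' @param data Binary symptom data (optionally with an `id` column).
#' @param path CSV path.
#' @return `write_symptom_matrix()` returns `data` invisibly;
#'   `read_symptom_matrix()` returns a validated tibble.
#' @export
write_symptom_matrix <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(data)
}

#' @rdname write_symptom_matrix
#' @export
read_symptom_matrix <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check <- if ("id" %in% names(d)) d[, setdiff(names(d), "id")] else d
  as_symptom_matrix(check)  # validates; discard result
  d
}

#' Serialize an estimated network to JSON
#'
#' Stores labels, the full weight matrix, thresholds and estimation
#' settings; `read_network_json()` reconstructs an `ising_network`
#' (without the per-node path objects).
#'
#' @param net An `ising_network`.
#' @param path JSON path.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "ising_network"))
  payload <- list(labels = net$labels,
                  weights = unname(net$weights),
                  thresholds = unname(net$thresholds),
                  rule = net$rule, gamma = net$gamma, n = net$n,
                  unestimable = net$unestimable)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(x$weights)
  dimnames(W) <- list(x$labels, x$labels)
  structure(
    list(weights = W,
         thresholds = setNames(as.numeric(x$thresholds), x$labels),
         rule = x$rule, gamma = x$gamma, labels = x$labels,
         unestimable = as.character(x$unestimable %||% character(0)),
         n = x$n, fits = NULL),
    class = "ising_network"
  )
}

#' Write the retained edges as a CSV edge list
#'
#' @param net An `ising_network`.
#' @param path CSV path (columns `item_a`, `item_b`, `weight`).
#' @export
write_edge_list <- function(net, path) {
  readr::write_csv(
    tidy(net, retained_only = TRUE)[, c("item_a", "item_b", "weight")],
    path, progress = FALSE)
  invisible(net)
}

#' Export a network (optionally with layout coordinates) as GraphML
#'
#' @param net An `ising_network`.
#' @param path GraphML path.
#' @param layout Optional tibble from [fruchterman_reingold()]; its
#'   coordinates are carried as vertex attributes `x`, `y`.
#' @export
write_network_graphml <- function(net, path, layout = NULL) {
  stopifnot(inherits(net, "ising_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$threshold <- unname(net$thresholds)
  if (!is.null(layout)) {
    ord <- match(igraph::V(g)$name, layout$node)
    igraph::V(g)$x <- layout$x[ord]
    igraph::V(g)$y <- layout$y[ord]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(net)
}

#' Serialize a scenario preset to JSON
#'
#' @param preset A `scenario_preset` from [make_preset()], or a bare
#'   [ising_parameters()] object.
#' @param path JSON path.
#' @export
write_preset_json <- function(preset, path) {
  if (inherits(preset, "ising_parameters")) {
    preset <- list(name = "custom", params = preset, n = NA_integer_)
  }
  payload <- list(name = preset$name,
                  labels = preset$params$labels,
                  thresholds = unname(preset$params$thresholds),
                  couplings = unname(preset$params$couplings),
                  n = preset$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(preset)
}

#' @rdname write_preset_json
#' @export
read_preset_json <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- ising_parameters(as.numeric(x$thresholds),
                             as.matrix(x$couplings), x$labels)
  structure(list(name = x$name, params = params,
                 n = x$n %||% NA_integer_,
                 target_marginals = NULL, strong_edges = NULL),
            class = "scenario_preset")
}

#' Write a filter log as JSON and/or human-readable text
#'
#' @param log Funnel tibble from [apply_inclusion_filters()].
#' @param json_path Optional JSON path.
#' @param text_path Optional text path.
#' @export
write_filter_log <- function(log, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(log), json_path, auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(text_path))
    writeLines(sprintf("%-24s n = %d", log$criterion, log$n_remaining),
               text_path)
  invisible(log)
}
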