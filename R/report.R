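# Consolidated analysis report: network summary, strongest edges,
# centrality rank order, stability diagnostics and the cohort funnel,
# rendered as JSON and Markdown.

#' Build a consolidated analysis report
#'
#' Collects the main result tables into a single serializable object.
#' Only the network is required; missing optional sections are noted in
#' the report rather than raising errors.
#'
#' @param net An `ising_network`.
#' @param centrality Optional [centrality_table()] tibble.
#' @param stability Optional list with elements `cs` (a
#'   [cs_coefficient()] tibble) and/or `edge_ci` (an [edge_ci_table()]
#'   tibble).
#' @param summaries Optional list with elements `filter_log` (funnel
#'   tibble) and/or `endorsement` ([endorsement_frequencies()] tibble).
#' @param top_k Number of strongest edges to list (default 10).
#' @return A list of class `symptom_report`.
#' @export
build_report <- function(net, centrality = NULL, stability = NULL,
                         summaries = NULL, top_k = 10) {
  stopifnot(inherits(net, "ising_network"))
  edges <- tidy(net, retained_only = TRUE)
  report <- list(
    settings = list(rule = net$rule, gamma = net$gamma, n = net$n,
                    n_items = length(net$labels)),
    summary = as.list(network_summary(net)),
    top_edges = if (nrow(edges) > 0) {
      as.data.frame(head(edges[, c("item_a", "item_b", "weight")], top_k))
    } else {
      "no edges retained"
    },
    omitted = character(0)
  )
  if (!is.null(centrality)) {
    report$centrality <- as.data.frame(centrality)
    report$leaders <- list(
      strength = centrality$node[centrality$rank_strength == 1],
      expected_influence = centrality$node[
        centrality$rank_expected_influence == 1]
    )
  } else {
    report$omitted <- c(report$omitted, "centrality")
  }
  if (!is.null(stability)) {
    report$stability <- list()
    if (!is.null(stability$cs)) {
      report$stability$cs <- as.data.frame(
        stability$cs[, c("index", "cs", "band")])
    }
    if (!is.null(stability$edge_ci)) {
      report$stability$edge_ci <- as.data.frame(stability$edge_ci)
    }
  } else {
    report$omitted <- c(report$omitted, "stability")
  }
  if (!is.null(summaries)) {
    if (!is.null(summaries$filter_log))
      report$filter_log <- as.data.frame(summaries$filter_log)
    if (!is.null(summaries$endorsement))
      report$endorsement <- as.data.frame(summaries$endorsement)
  } else {
    report$omitted <- c(report$omitted, "cohort summaries")
  }
  if (length(report$omitted) == 0) report$omitted <- NULL
  structure(report, class = "symptom_report")
}

#' Serialize a report to JSON
#'
#' @param report A `symptom_report`.
#' @return A JSON string; `report_from_json()` round-trips it.
#' @export
report_to_json <- function(report) {
  # canonical form: data frames become named lists of columns first, so
  # that serializing a parsed report reproduces the same bytes
  canonical <- function(x) {
    if (is.data.frame(x)) lapply(x, identity)
    else if (is.list(x)) lapply(x, canonical)
    else x
  }
  as.character(jsonlite::toJSON(canonical(unclass(report)),
                                auto_unbox = TRUE, digits = NA,
                                na = "null"))
}

#' @rdname report_to_json
#' @param json A JSON string or file path produced by
#'   [report_to_json()] / [write_report()].
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  structure(x, class = "symptom_report")
}

#' Render a report as Markdown
#'
#' @param report A `symptom_report`.
#' @return A character vector of Markdown lines.
#' @export
report_to_markdown <- function(report) {
  stopifnot(inherits(report, "symptom_report"))
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r)
        paste0("| ", paste(r, collapse = " | "), " |")))
  }
  s <- report$summary
  lines <- c(
    "# Symptom network analysis report", "",
    paste0("- items: ", report$settings$n_items,
           ", n = ", report$settings$n),
    paste0("- rule: ", report$settings$rule,
           ", EBIC gamma = ", report$settings$gamma),
    paste0("- edges retained: ", s$retained_edges, " of ",
           s$possible_edges, " (",
           round(100 * s$proportion_retained), "%)"),
    if (!is.null(s$mean_retained_weight) &&
        !is.na(s$mean_retained_weight))
      paste0("- mean retained weight: ",
             signif(s$mean_retained_weight, 3)),
    "", "## Strongest edges", ""
  )
  if (is.character(report$top_edges)) {
    lines <- c(lines, report$top_edges)
  } else {
    lines <- c(lines, md_table(report$top_edges))
  }
  if (!is.null(report$centrality)) {
    lines <- c(lines, "", "## Centrality", "",
               md_table(report$centrality),
               "",
               paste0("Highest strength: ", report$leaders$strength,
                      "; highest expected influence: ",
                      report$leaders$expected_influence, "."))
  }
  if (!is.null(report$stability$cs)) {
    lines <- c(lines, "", "## Centrality stability (CS coefficients)", "",
               md_table(report$stability$cs),
               "",
               paste0("CS above .50 indicates a stable index; ",
                      "below .25, an untrustworthy one."))
  }
  if (!is.null(report$filter_log)) {
    lines <- c(lines, "", "## Inclusion funnel", "",
               md_table(report$filter_log))
  }
  if (!is.null(report$omitted)) {
    lines <- c(lines, "",
               paste0("_Sections omitted (not supplied): ",
                      paste(report$omitted, collapse = ", "), "._"))
  }
  lines
}

#' @export
print.symptom_report <- function(x, ...) {
  cat(report_to_markdown(x), sep = "\n")
  invisible(x)
}

#' Write a report to disk
#'
#' @param report A `symptom_report`.
#' @param json_path Optional path for the JSON rendering.
#' @param md_path Optional path for the Markdown rendering.
#' @return The report, invisibly.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) writeLines(report_to_json(report), json_path)
  if (!is.null(md_path)) writeLines(report_to_markdown(report), md_path)
  invisible(report)
}
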