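# Cohort construction: read raw participant tables, apply the inclusion
# funnel, and produce the clean binary symptom matrix with descriptive
# summaries.

#' Default schema mapping for a raw participant table
#'
#' Maps the logical columns the pipeline needs (the 12 symptom items,
#' `id`, `age`, `cognitive_status`, `ad_etiology`, `visit_label`) onto
#' the column names of the file. The default is the identity mapping on
#' the logical names.
#'
#' @param ... Named overrides, e.g. `age = "NACCAGE"`.
#' @return Named character vector (logical name -> file column).
#' @export
participant_schema <- function(...) {
  logical_cols <- c("id", "age", "cognitive_status", "ad_etiology",
                    "visit_label", npiq_items())
  schema <- setNames(logical_cols, logical_cols)
  overrides <- c(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), logical_cols)
    if (length(bad) > 0)
      stop("Unknown logical columns in schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Filtering configuration for the inclusion funnel
#'
#' @param min_age Minimum age in years (default 50).
#' @param allowed_statuses Cognitive statuses retained (default MCI and
#'   dementia).
#' @param allowed_etiologies Alzheimer's-etiology categories retained
#'   (default primary and contributing).
#' @param min_symptoms Minimum number of endorsed items (default 1).
#' @param missing_codes Item codes treated as unknown / not available
#'   (default `c(9, -4)`; the coding differs by form version, so this is
#'   configurable rather than hard-wired).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_age = 50,
                          allowed_statuses = c("MCI", "dementia"),
                          allowed_etiologies = c("primary", "contributing"),
                          min_symptoms = 1,
                          missing_codes = c(9, -4)) {
  if (min_age < 0) stop("`min_age` must be >= 0.", call. = FALSE)
  if (min_symptoms < 0) stop("`min_symptoms` must be >= 0.", call. = FALSE)
  structure(list(min_age = min_age, allowed_statuses = allowed_statuses,
                 allowed_etiologies = allowed_etiologies,
                 min_symptoms = min_symptoms,
                 missing_codes = missing_codes),
            class = "filter_config")
}

#' Load and validate a raw participant table
#'
#' Reads a CSV with a header row, renames file columns to the pipeline's
#' logical names via `schema`, and validates the symptom item codes
#' against the legal set (0, 1 and the configured missing codes).
#' Unknown/not-available codes are preserved, not coerced.
#'
#' @param path CSV file path.
#' @param schema Column mapping from [participant_schema()], or a path
#'   to a JSON/YAML file holding one.
#' @param missing_codes Item codes that are legal besides 0/1 (default
#'   `c(9, -4)`); keep in sync with [filter_config()].
#' @return A validated tibble with logical column names.
#' @export
load_participant_table <- function(path, schema = participant_schema(),
                                   missing_codes = c(9, -4)) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema_list <- if (grepl("\\.ya?ml$", schema)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("Reading a YAML schema requires the yaml package.",
             call. = FALSE)
      yaml::read_yaml(schema)
    } else {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    }
    schema <- do.call(participant_schema, as.list(unlist(schema_list)))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0)
    stop("Schema error: required column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- raw[, unname(schema)]
  names(tab) <- names(schema)
  if (anyDuplicated(tab$id))
    stop("Participant identifiers are not unique (e.g. id = ",
         tab$id[duplicated(tab$id)][1], ").", call. = FALSE)
  legal <- c(0, 1, missing_codes)
  for (item in npiq_items()) {
    bad <- which(!(tab[[item]] %in% legal))
    if (length(bad) > 0)
      stop("Validation error: illegal code ", tab[[item]][bad[1]],
           " in item '", item, "', row ", bad[1],
           " (legal codes: ", paste(legal, collapse = ", "), ").",
           call. = FALSE)
  }
  tab
}

#' Apply the inclusion funnel to a raw participant table
#'
#' Filters in the fixed funnel order: (1) cognitive status, (2)
#' Alzheimer's etiology, (3) minimum age, then (4) complete-case removal
#' of rows with any unknown/not-available item code followed by the
#' minimum-symptom criterion. The log records the remaining n after each
#' step, making the order auditable.
#'
#' @param table Validated table from [load_participant_table()].
#' @param config A [filter_config()].
#' @return A list with `symptoms` (tibble: `id` plus the 12 binary item
#'   columns) and `log` (tibble: `criterion`, `n_remaining`).
#' @export
apply_inclusion_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  items <- npiq_items()
  steps <- list(
    `cognitive status` = function(d)
      d[d$cognitive_status %in% config$allowed_statuses, , drop = FALSE],
    `AD etiology` = function(d)
      d[d$ad_etiology %in% config$allowed_etiologies, , drop = FALSE],
    age = function(d) d[d$age >= config$min_age, , drop = FALSE],
    `complete NPI-Q items` = function(d) {
      any_missing <- Reduce(`|`, lapply(items, function(it)
        d[[it]] %in% config$missing_codes))
      d[!any_missing, , drop = FALSE]
    },
    `minimum symptoms` = function(d) {
      counts <- rowSums(as.matrix(d[, items]))
      d[counts >= config$min_symptoms, , drop = FALSE]
    }
  )
  log <- tibble::tibble(criterion = "initial", n_remaining = nrow(table))
  d <- table
  for (nm in names(steps)) {
    d <- steps[[nm]](d)
    log <- dplyr::bind_rows(
      log, tibble::tibble(criterion = nm, n_remaining = nrow(d)))
  }
  if (nrow(d) == 0)
    stop("Empty cohort: no participant survives the inclusion filters.",
         call. = FALSE)
  symptoms <- d[, c("id", items)]
  symptoms[items] <- lapply(symptoms[items], as.integer)
  list(symptoms = tibble::as_tibble(symptoms), log = log)
}

#' Per-item endorsement frequencies
#'
#' @param data Binary symptom data (an `id` column, if present, is
#'   ignored).
#' @return Tibble with `item`, `n_present` (integer column sum) and
#'   `frequency` (proportion in \[0, 1\]).
#' @export
endorsement_frequencies <- function(data) {
  if (inherits(data, "data.frame") && "id" %in% names(data))
    data <- data[, setdiff(names(data), "id")]
  m <- as_symptom_matrix(data, min_items = 1L)
  tibble::tibble(item = colnames(m),
                 n_present = unname(as.integer(colSums(m))),
                 frequency = unname(colMeans(m)))
}

#' Summary of endorsed-symptom counts
#'
#' Descriptive statistics of the per-row total of endorsed symptoms,
#' optionally by group. Groups with a single row are flagged as
#' degenerate (SD reported as 0); declared groups with zero rows are
#' flagged, not dropped.
#'
#' @param data Binary symptom data.
#' @param groups Optional vector of row labels (one per row) or a factor
#'   whose levels declare the expected groups.
#' @return Tibble per group: `group`, `n`, `mean`, `sd`, `min`, `max`,
#'   `degenerate`.
#' @export
symptom_count_summary <- function(data, groups = NULL) {
  if (inherits(data, "data.frame") && "id" %in% names(data))
    data <- data[, setdiff(names(data), "id")]
  m <- as_symptom_matrix(data, min_items = 1L)
  counts <- rowSums(m)
  if (is.null(groups)) groups <- factor(rep("all", nrow(m)))
  if (length(groups) != nrow(m))
    stop("`groups` must label every row (length ", nrow(m), ").",
         call. = FALSE)
  groups <- as.factor(groups)
  out <- purrr::map(levels(groups), function(g) {
    x <- counts[groups == g]
    if (length(x) == 0) {
      tibble::tibble(group = g, n = 0L, mean = NA_real_, sd = NA_real_,
                     min = NA_real_, max = NA_real_, degenerate = TRUE)
    } else {
      tibble::tibble(group = g, n = length(x), mean = mean(x),
                     sd = if (length(x) > 1) sd(x) else 0,
                     min = min(x), max = max(x),
                     degenerate = length(x) < 2)
    }
  })
  dplyr::bind_rows(out)
}
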