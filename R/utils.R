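# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-replicate substream seeds: replicate b always receives
# seeds[b] regardless of evaluation order or worker count.
replicate_seeds <- function(seed, B) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Lower-triangle (i < j) pair index tibble for a labelled node set.
node_pairs <- function(labels) {
  p <- length(labels)
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  tibble::tibble(
    item_a = labels[idx[, "col"]],
    item_b = labels[idx[, "row"]],
    i = as.integer(idx[, "col"]),
    j = as.integer(idx[, "row"])
  )
}

lower_tri_vec <- function(W) W[lower.tri(W)]

# Validate an n x p {0,1} symptom matrix (tibble, data.frame or matrix);
# returns an integer matrix with column names.
as_symptom_matrix <- function(data, min_items = 2L, allow_constant = TRUE) {
  if (inherits(data, "data.frame")) {
    m <- as.matrix(data)
  } else if (is.matrix(data)) {
    m <- data
  } else {
    stop("`data` must be a data frame or matrix of 0/1 symptom indicators.",
         call. = FALSE)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  if (!is.numeric(m)) stop("Symptom columns must be numeric 0/1.", call. = FALSE)
  if (nrow(m) < 1) stop("Symptom matrix needs at least one row.", call. = FALSE)
  if (ncol(m) < min_items)
    stop("Symptom matrix needs at least ", min_items, " item columns.",
         call. = FALSE)
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop("Symptom matrix entries must be 0 or 1; found ", m[bad[1]],
         " at row ", rc[1], ", column '", colnames(m)[rc[2]], "'.",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}
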