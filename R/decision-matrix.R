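#' @title Decision matrices for multi-criteria model selection
#' @description
#' An MCDM decision matrix X arranges n alternatives (candidate models) as
#' rows against p criteria (evaluation metrics) as columns, with x_ij the raw
#' value of criterion j for alternative i. Raw criteria carry mixed units
#' (percentages, parameter counts, frames per second), so every pipeline
#' stage operates on the dimensionless min-max normalized matrix:
#' \deqn{x'_{ij} = (x_{ij} - x_{min,j}) / (x_{max,j} - x_{min,j})}
#' for benefit criteria (larger is better), and
#' \deqn{x'_{ij} = (x_{max,j} - x_{ij}) / (x_{max,j} - x_{min,j})}
#' for cost criteria (smaller is better), putting every column on [0, 1]
#' with 1 always the most desirable value.
#' @name decision_matrix_tools
NULL

#' Build a criteria schema
#'
#' @param name character vector of criterion names (unique).
#' @param direction `"benefit"` or `"cost"`, recycled if scalar.
#' @param weight optional subjective weights in [0, 1].
#' @param level optional first-level grouping tags (informational).
#' @return A data frame of class `criteria_set`.
#' @export
criteria_set <- function(name, direction, weight = NULL, level = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("duplicate criterion names", call. = FALSE)
  direction <- rep_len(as.character(direction), length(name))
  if (!all(direction %in% c("benefit", "cost")))
    stop("criterion direction must be 'benefit' or 'cost'", call. = FALSE)
  weight <- if (is.null(weight)) rep(NA_real_, length(name)) else as.numeric(weight)
  if (any(!is.na(weight) & (weight < 0 | weight > 1)))
    stop("subjective weights must lie in [0, 1]", call. = FALSE)
  level <- if (is.null(level)) rep(NA_character_, length(name)) else as.character(level)
  structure(data.frame(name = name, direction = direction, weight = weight,
                       level = level, stringsAsFactors = FALSE),
            class = c("criteria_set", "data.frame"))
}

#' Construct a decision matrix
#'
#' @param values numeric n x p matrix of raw criterion values (no missing
#'   entries; n >= 2 alternatives, p >= 2 criteria).
#' @param alternatives character vector of n unique alternative identifiers;
#'   defaults to rownames of `values`.
#' @param criteria a `criteria_set` (or data frame coercible to one) whose
#'   names match `colnames(values)`.
#' @return An object of class `decision_matrix` with fields `values`,
#'   `alternatives`, `criteria`.
#' @export
decision_matrix <- function(values, alternatives = rownames(values), criteria) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a decision matrix needs at least 2 alternatives and 2 criteria",
         call. = FALSE)
  if (anyNA(values)) stop("decision matrix contains missing values", call. = FALSE)
  if (is.null(alternatives)) stop("alternative identifiers are required", call. = FALSE)
  alternatives <- as.character(alternatives)
  if (length(alternatives) != nrow(values))
    stop("one identifier per alternative is required", call. = FALSE)
  if (anyDuplicated(alternatives))
    stop("duplicate alternative identifiers: ",
         paste(unique(alternatives[duplicated(alternatives)]), collapse = ", "),
         call. = FALSE)
  if (!inherits(criteria, "criteria_set"))
    criteria <- criteria_set(criteria$name, criteria$direction,
                             criteria$weight, criteria$level)
  if (nrow(criteria) != ncol(values))
    stop("criteria schema and matrix column counts differ", call. = FALSE)
  if (!is.null(colnames(values)) && !identical(colnames(values), criteria$name)) {
    if (!setequal(colnames(values), criteria$name))
      stop("matrix columns do not match criteria schema: ",
           paste(setdiff(colnames(values), criteria$name), collapse = ", "),
           call. = FALSE)
    values <- values[, criteria$name, drop = FALSE]
  }
  dimnames(values) <- list(alternatives, criteria$name)
  structure(list(values = values, alternatives = alternatives, criteria = criteria),
            class = "decision_matrix")
}

#' @export
print.decision_matrix <- function(x, ...) {
  kind <- if (inherits(x, "normalized_matrix")) "normalized decision matrix" else "decision matrix"
  cat(sprintf("%s: %d alternatives x %d criteria\n",
              kind, nrow(x$values), ncol(x$values)))
  cat("criteria:", paste(sprintf("%s(%s)", x$criteria$name,
                                 substr(x$criteria$direction, 1, 1)),
                         collapse = " "), "\n")
  print(utils::head(round(x$values, 4), 6))
  if (nrow(x$values) > 6) cat("...", nrow(x$values) - 6, "more rows\n")
  invisible(x)
}

#' Min-max normalize a decision matrix
#'
#' Benefit columns map their column maximum to 1 and minimum to 0; cost
#' columns are inverted so that the cheapest alternative scores 1. A constant
#' column has no contrast and leaves the ratio undefined: the default is a
#' hard error, or it may be mapped to all zeros with a warning.
#'
#' @param dm a `decision_matrix`.
#' @param constant `"error"` (default) or `"zero"`.
#' @return A `normalized_matrix` (subclass of `decision_matrix`) whose
#'   `values` lie in [0, 1]; the raw matrix is retained in field `raw`.
#' @export
normalize_matrix <- function(dm, constant = c("error", "zero")) {
  constant <- match.arg(constant)
  stopifnot(inherits(dm, "decision_matrix"))
  if (inherits(dm, "normalized_matrix")) dm <- decision_matrix(dm$raw, dm$alternatives, dm$criteria)
  raw <- dm$values
  out <- raw
  for (j in seq_len(ncol(raw))) {
    lo <- min(raw[, j]); hi <- max(raw[, j])
    if (hi == lo) {
      if (constant == "error")
        stop("constant criterion column '", dm$criteria$name[j],
             "' cannot be min-max normalized", call. = FALSE)
      warning("constant criterion column '", dm$criteria$name[j],
              "' mapped to zeros", call. = FALSE)
      out[, j] <- 0
    } else if (dm$criteria$direction[j] == "benefit") {
      out[, j] <- (raw[, j] - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - raw[, j]) / (hi - lo)
    }
  }
  structure(list(values = out, raw = raw, alternatives = dm$alternatives,
                 criteria = dm$criteria),
            class = c("normalized_matrix", "decision_matrix"))
}

#' Load a decision matrix from CSV
#'
#' The CSV must have a header row naming the criteria, a first column of
#' alternative identifiers, and one row per alternative. Criterion order in
#' the result follows the criteria config, not the CSV.
#'
#' @param path CSV file path.
#' @param criteria a `criteria_set` or a path to a criteria config (see
#'   [read_criteria()]).
#' @return A `decision_matrix`.
#' @export
read_decision_matrix <- function(path, criteria) {
  if (is.character(criteria)) criteria <- read_criteria(criteria)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L) stop("matrix CSV needs an id column and >= 2 criteria", call. = FALSE)
  ids <- as.character(df[[1]])
  cols <- names(df)[-1]
  missing_crit <- setdiff(criteria$name, cols)
  if (length(missing_crit))
    stop("matrix CSV is missing criteria: ", paste(missing_crit, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(cols, criteria$name)
  if (length(unknown))
    stop("matrix CSV has criteria absent from the config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[criteria$name])
  if (!is.numeric(vals) || anyNA(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[criteria$name], 2, as.numeric))),
                 arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric or blank cell at row '%s', column '%s'",
                   ids[bad[1, 1]], criteria$name[bad[1, 2]]), call. = FALSE)
    stop("matrix CSV contains non-numeric cells", call. = FALSE)
  }
  decision_matrix(vals, ids, criteria)
}
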