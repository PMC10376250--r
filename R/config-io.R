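# Minimal reader for the flat YAML subset used by the criteria and weight
# configs: either a top-level list of mappings
#     - name: IoU
#       direction: benefit
# or a single flat mapping
#     IoU: 0.3
# Comments (#) and blank lines are ignored; no nesting, anchors or multiline
# scalars. Kept in-package because no YAML parser is available as a hard
# dependency; CSV configs are accepted as an alternative.

yaml_scalar <- function(x) {
  x <- trimws(x)
  x <- sub('^"(.*)"$', "\\1", x)
  x <- sub("^'(.*)'$", "\\1", x)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", x)) num else x
}

read_yaml_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("(^|[[:space:]])#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty config file: ", path, call. = FALSE)
  is_list <- grepl("^\\s*-", lines[1])
  if (is_list) {
    items <- list()
    current <- NULL
    for (line in lines) {
      start <- grepl("^\\s*-\\s*", line)
      body <- sub("^\\s*-?\\s*", "", line)
      if (!grepl(":", body)) stop("malformed config line: ", line, call. = FALSE)
      key <- trimws(sub(":.*$", "", body))
      val <- yaml_scalar(sub("^[^:]*:", "", body))
      if (start) {
        if (!is.null(current)) items[[length(items) + 1L]] <- current
        current <- list()
      }
      if (is.null(current)) stop("config list item without leading '-': ", line, call. = FALSE)
      current[[key]] <- val
    }
    items[[length(items) + 1L]] <- current
    items
  } else {
    out <- list()
    for (line in lines) {
      if (!grepl(":", line)) stop("malformed config line: ", line, call. = FALSE)
      key <- trimws(sub(":.*$", "", line))
      out[[key]] <- yaml_scalar(sub("^[^:]*:", "", line))
    }
    out
  }
}

#' Read a criteria configuration
#'
#' The config declares, per criterion, its name, optimization direction
#' (`benefit` = larger is better, `cost` = smaller is better), subjective
#' weight, and an optional first-level grouping tag. Accepted formats: a flat
#' YAML list of `{name, direction, weight, level}` mappings, or a CSV with
#' those column headers.
#'
#' @param path path to a `.yaml`/`.yml` or `.csv` file.
#' @return A criteria data frame as from [criteria_set()].
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) stop("criteria config not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    items <- read_yaml_flat(path)
    if (!is.list(items[[1]]))
      stop("criteria config must be a list of mappings: ", path, call. = FALSE)
    df <- do.call(rbind, lapply(items, function(it) {
      data.frame(name = it$name, direction = it$direction,
                 weight = if (is.null(it$weight)) NA_real_ else it$weight,
                 level = if (is.null(it$level)) NA_character_ else it$level,
                 stringsAsFactors = FALSE)
    }))
  }
  criteria_set(df$name, df$direction, df$weight,
               if ("level" %in% names(df)) df$level else NULL)
}

#' Read a subjective weight configuration
#'
#' A flat YAML mapping (`IoU: 0.3`) or two-column CSV (`name,weight`).
#'
#' @param path config file path.
#' @param renormalize if TRUE, weights not summing to one are rescaled with a
#'   warning instead of raising an error.
#' @return A `subjective_weights` vector.
#' @export
read_weights <- function(path, renormalize = FALSE) {
  if (!file.exists(path)) stop("weight config not found: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    w <- stats::setNames(as.numeric(df$weight), df$name)
  } else {
    items <- read_yaml_flat(path)
    if (is.list(items[[1]]))
      stop("weight config must be a flat name: weight mapping: ", path, call. = FALSE)
    w <- unlist(items)
  }
  subjective_weights(w, renormalize = renormalize,
                     provenance = paste("loaded from", basename(path)))
}
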