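# Mask raster I/O. Two on-disk dialects:
#   * plain-text grid: lines of '0'/'1' characters, equal length;
#   * netpbm PBM/PGM: ASCII P1/P2 and binary P4/P5, any nonzero pixel = positive.
# PNG is not supported (no decoder available without external dependencies).

#' Read a binary mask from disk
#'
#' @param path file path; `.pbm`/`.pgm` are parsed as netpbm, anything else as
#'   the plain-text 0/1 grid dialect unless `format` overrides.
#' @param format `"auto"`, `"grid"` or `"pnm"`.
#' @return A logical matrix (TRUE = foreground).
#' @export
read_mask <- function(path, format = c("auto", "grid", "pnm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(pbm|pgm|pnm)$", path, ignore.case = TRUE)) "pnm" else "grid"
  }
  if (format == "grid") read_grid_mask(path) else read_pnm_mask(path)
}

read_grid_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty mask grid: ", path, call. = FALSE)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L)
    stop("ragged mask grid (unequal line lengths): ", path, call. = FALSE)
  if (any(grepl("[^01]", lines)))
    stop("mask grid may contain only '0' and '1': ", path, call. = FALSE)
  bits <- lapply(strsplit(lines, ""), function(ch) ch == "1")
  do.call(rbind, bits)
}

# netpbm header tokens, skipping '#' comments
pnm_tokens <- function(raw, n_tokens) {
  tokens <- character(0)
  i <- 1L
  current <- character(0)
  while (length(tokens) < n_tokens && i <= length(raw)) {
    ch <- rawToChar(raw[i])
    if (ch == "#") {
      while (i <= length(raw) && !rawToChar(raw[i]) %in% c("\n", "\r")) i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      if (length(current)) {
        tokens <- c(tokens, paste(current, collapse = ""))
        current <- character(0)
      }
    } else {
      current <- c(current, ch)
    }
    i <- i + 1L
  }
  if (length(current) && length(tokens) < n_tokens)
    tokens <- c(tokens, paste(current, collapse = ""))
  list(tokens = tokens, offset = i)
}

read_pnm_mask <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P1", "P2", "P4", "P5"))
    stop("unsupported netpbm magic '", magic, "' in ", path, call. = FALSE)
  bitmap <- magic %in% c("P1", "P4")
  n_head <- if (bitmap) 3L else 4L
  head <- pnm_tokens(raw, n_head)
  dims <- as.integer(head$tokens[2:3])
  width <- dims[1]; height <- dims[2]
  if (anyNA(dims) || width < 1L || height < 1L)
    stop("invalid netpbm dimensions in ", path, call. = FALSE)
  n <- width * height
  if (magic %in% c("P1", "P2")) {
    body <- rawToChar(raw[head$offset:length(raw)])
    vals <- as.integer(strsplit(trimws(body), "[[:space:]]+")[[1]])
    if (length(vals) < n) stop("truncated netpbm body in ", path, call. = FALSE)
    vals <- vals[seq_len(n)]
  } else if (magic == "P5") {
    vals <- as.integer(raw[head$offset + seq_len(n) - 1L])
  } else { # P4: rows padded to whole bytes
    bytes_per_row <- ceiling(width / 8)
    bits <- matrix(0L, nrow = height, ncol = width)
    for (r in seq_len(height)) {
      row_bytes <- raw[head$offset + (r - 1L) * bytes_per_row + seq_len(bytes_per_row) - 1L]
      row_bits <- as.integer(rawToBits(row_bytes))
      # rawToBits is little-endian per byte; PBM packs MSB first
      row_bits <- as.vector(t(matrix(row_bits, nrow = 8)[8:1, , drop = FALSE]))
      bits[r, ] <- row_bits[seq_len(width)]
    }
    return(bits > 0L)
  }
  matrix(vals > 0L, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a binary mask to disk
#'
#' @param mask logical matrix.
#' @param path destination path.
#' @param format `"grid"` (0/1 text lines) or `"pgm"` (ASCII P2, 0/255).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("grid", "pgm")) {
  format <- match.arg(format)
  mask <- as_binary_mask(mask)
  if (format == "grid") {
    lines <- apply(mask, 1, function(row) paste(as.integer(row), collapse = ""))
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mask), nrow(mask)), "255"), con)
    apply(mask, 1, function(row) writeLines(paste(ifelse(row, 255L, 0L), collapse = " "), con))
  }
  invisible(path)
}
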