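#' Node-by-time series container
#'
#' A `node_ts` holds one subject's node-by-time real-valued matrix together
#' with its sampling interval (TR, in seconds) and ordered node labels. Rows
#' are nodes, columns are time points.
#'
#' @param values numeric matrix, nodes in rows, time in columns (T >= 3).
#' @param dt sampling interval in seconds (> 0).
#' @param node_ids optional character vector of node labels; defaults to
#'   rownames or `node1..nodeN`.
#' @return an object of class `node_ts`: a list with elements `values`,
#'   `dt`, `node_ids`.
#' @export
node_ts <- function(values, dt = 1, node_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 3L)
    stop("a node_ts needs at least 3 time points, got ", ncol(values))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("node_ts values must be finite")
  if (is.null(node_ids)) {
    node_ids <- rownames(values)
    if (is.null(node_ids)) node_ids <- paste0("node", seq_len(nrow(values)))
  }
  if (length(node_ids) != nrow(values))
    stop("node_ids length (", length(node_ids),
         ") does not match number of rows (", nrow(values), ")")
  rownames(values) <- node_ids
  structure(list(values = values, dt = as.numeric(dt),
                 node_ids = as.character(node_ids)),
            class = "node_ts")
}

#' @export
dim.node_ts <- function(x) dim(x$values)

#' @export
as.matrix.node_ts <- function(x, ...) x$values

#' @export
print.node_ts <- function(x, ...) {
  cat(sprintf("node_ts: %d nodes x %d time points (dt = %g s, %.4g s total)\n",
              nrow(x$values), ncol(x$values), x$dt, x$dt * ncol(x$values)))
  invisible(x)
}

n_nodes <- function(ts) nrow(ts$values)
n_time  <- function(ts) ncol(ts$values)

#' Read a node-by-time matrix from delimited text
#'
#' Accepts tab- or comma-delimited text (auto-detected), optionally with a
#' header row of time indices and a first column of node labels (both
#' auto-detected from non-numeric content). Decimal points only, no decimal
#' commas.
#'
#' @param path file path.
#' @param dt sampling interval in seconds attached to the result.
#' @param transpose if `TRUE` the file stores time in rows and nodes in
#'   columns and is transposed after reading.
#' @return a [node_ts].
#' @export
read_node_matrix <- function(path, dt = 1, transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  cells <- lapply(cells, trimws)

  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v)))
  # header row: any non-numeric cell beyond the first
  has_header <- !is_num(cells[[1L]][-1L])
  if (has_header) cells <- cells[-1L]
  if (length(cells) == 0L) stop("no data rows in ", path)
  # label column: first cell of any data row non-numeric
  has_labels <- !is_num(vapply(cells, `[[`, "", 1L))
  labels <- if (has_labels) vapply(cells, `[[`, "", 1L) else NULL
  if (has_labels) cells <- lapply(cells, `[`, -1L)

  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1L]])[[1L]]
    stop("ragged row ", bad + has_header, " in ", path, ": expected ",
         widths[[1L]], " cells, found ", widths[[bad]])
  }
  rows <- lapply(seq_along(cells), function(i) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop("non-numeric cell in data row ", i + has_header, " of ", path)
    v
  })
  m <- do.call(rbind, rows)
  if (transpose) {
    m <- t(m)
    labels <- NULL  # labels were time indices in transposed layout
  } else if (!is.null(labels)) {
    rownames(m) <- labels
  }
  node_ts(m, dt = dt, node_ids = rownames(m))
}

#' Write a node-by-time matrix as tab-delimited text
#'
#' Values are printed with \%.17g so that a read/write round trip reproduces
#' every double exactly.
#'
#' @param ts a [node_ts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_matrix <- function(ts, path) {
  stopifnot(inherits(ts, "node_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("node", paste0("t", seq_len(n_time(ts)))),
                   collapse = "\t"), con)
  for (i in seq_len(n_nodes(ts))) {
    writeLines(paste(c(ts$node_ids[[i]],
                       sprintf("%.17g", ts$values[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards: generators stay pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
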