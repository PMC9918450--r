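#' A set of trials of one scalar trajectory component
#'
#' Wraps a trials x nodes numeric matrix together with its component
#' metadata. Rows are individual trials (patient conditions) or per-subject
#' trial averages (normative reference). Cells that could not be parsed as
#' numbers are `NaN`; the per-node `missing_mask` is `TRUE` wherever any
#' trial is not finite at that node.
#'
#' @param values numeric matrix, trials in rows, nodes in columns.
#' @param meta optional [component_key()] describing the component.
#' @return Object of class `"trajectory_set"` with elements `values`,
#'   `meta`, `n_trials`, `node_count` and `missing_mask`.
#' @examples
#' ts <- trajectory_set(matrix(rnorm(303), 3, 101))
#' ts$n_trials
#' ts$node_count
#' @export
trajectory_set <- function(values, meta = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (trials x nodes)")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must have at least one trial and one node")
  if (!is.null(meta) && !inherits(meta, "component_key"))
    stop("'meta' must be a component_key or NULL")
  structure(list(
    values       = unname(values),
    meta         = meta,
    n_trials     = nrow(values),
    node_count   = ncol(values),
    missing_mask = apply(values, 2L, function(col) any(!is.finite(col)))
  ), class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trials x %d nodes", x$n_trials,
              x$node_count))
  if (!is.null(x$meta)) cat("  [", format(x$meta), "]", sep = "")
  nmiss <- sum(x$missing_mask)
  if (nmiss > 0L) cat(sprintf("  (%d nodes with missing data)", nmiss))
  cat("\n")
  invisible(x)
}

#' Read one trajectory CSV file
#'
#' The expected dialect is one header line (content ignored) followed by one
#' comma-separated numeric row per trial, all rows of equal length
#' (canonically 101 samples spanning 0--100\% of the gait cycle; shorter or
#' longer rows are accepted here and canonicalised by [apply_preprocess()]).
#' Empty or non-numeric cells become `NaN` and set the missing mask at that
#' node, so files with e.g. a missing trailing portion of the cycle load
#' without error.
#'
#' @param path path to a CSV file.
#' @param meta optional [component_key()] to attach.
#' @return A [trajectory_set()].
#' @export
read_trajectory_csv <- function(path, meta = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e)
                      stop(sprintf("cannot read '%s': %s", path,
                                   conditionMessage(e))))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop(sprintf("'%s': expected a header line plus at least one data row",
                 path))
  body <- lines[-1L]
  cells <- strsplit(body, ",", fixed = TRUE)
  # a trailing comma-less empty final field survives as "" via trimws rows;
  # strsplit drops a trailing empty field, so pad rows ending in ','
  ends_comma <- endsWith(body, ",")
  cells[ends_comma] <- lapply(cells[ends_comma], function(x) c(x, ""))
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf(
      "'%s': ragged rows — data line %d has %d cells but line 1 has %d",
      path, bad, lens[bad], lens[1L]))
  }
  parse_row <- function(x) {
    v <- suppressWarnings(as.numeric(trimws(x)))
    v[!is.finite(v)] <- NaN
    v
  }
  values <- do.call(rbind, lapply(cells, parse_row))
  trajectory_set(values, meta = meta)
}

#' Write a trajectory set as CSV
#'
#' Inverse of [read_trajectory_csv()]: one header line then one row per
#' trial. Non-finite cells are written as `NaN`. Numbers are written with
#' 17 significant digits so a write/read/write cycle is byte-identical.
#'
#' @param ts a [trajectory_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trajectory_set"))
  header <- paste(sprintf("node_%d", seq_len(ts$node_count) - 1L),
                  collapse = ",")
  rows <- apply(ts$values, 1L, function(r)
    paste(format_cell(r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e)
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

# %.17g round-trips IEEE doubles exactly and deterministically
format_cell <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- "NaN"
  out
}
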