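#' Clinician-facing severity legend scale
#'
#' Severity is expressed as folds of the family-wise critical threshold:
#' 1 fold means "just significant", larger values grade the deviation from
#' subtle/mild (blue end) to extreme/very severe (dark red end). Individual
#' 1D components clip at 4 folds; the combined 3D (Hotelling) bar clips at
#' 8 folds. The legend is discretised into `n_levels` colour levels drawn
#' from one of three MATLAB-like colormaps.
#'
#' @param max_fold_uni clip for univariate (t) severity, default 4.
#' @param max_fold_multi clip for multivariate (T-squared) severity,
#'   default 8; must be `>= max_fold_uni >= 1`.
#' @param n_levels number of legend levels (>= 2), default 8.
#' @param colormap `"cool_to_warm"`, `"jet"` or `"viridis"`.
#' @return Object of class `"severity_scale"`.
#' @export
severity_scale <- function(max_fold_uni = 4, max_fold_multi = 8,
                           n_levels = 8L,
                           colormap = c("cool_to_warm", "jet", "viridis")) {
  if (!(max_fold_multi >= max_fold_uni && max_fold_uni >= 1))
    stop("need max_fold_multi >= max_fold_uni >= 1")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  structure(list(max_fold_uni = max_fold_uni,
                 max_fold_multi = max_fold_multi,
                 n_levels = n_levels,
                 colormap = match.arg(colormap)),
            class = "severity_scale")
}

#' Fold-of-threshold severity map from an SPM result
#'
#' Per node: severity 0 where the statistic does not strictly exceed the
#' critical threshold (`|z| <= z*` for t fields, `z <= z*` for T-squared),
#' otherwise `min(|z|/z*, max_fold)` with the clip taken from the scale
#' according to the field kind (4 folds univariate, 8 folds multivariate by
#' default). Invalid nodes propagate as masked. A degenerate result without
#' a threshold yields an all-masked map.
#'
#' @param res an `"spm_result"`.
#' @param scale a [severity_scale()].
#' @return Object of class `"severity_map"`: list with `values` (length-Q
#'   numeric, `NaN` at masked nodes), `masked`, `kind`
#'   (`"univariate"`/`"multivariate"`), `max_fold` and `scale`.
#' @export
severity_from_spm <- function(res, scale = severity_scale()) {
  stopifnot(inherits(res, "spm_result"), inherits(scale, "severity_scale"))
  kind <- if (startsWith(res$stat_kind, "T2")) "multivariate" else "univariate"
  max_fold <- if (kind == "multivariate") scale$max_fold_multi
              else scale$max_fold_uni
  Q <- length(res$z)
  if (!is.finite(res$z_star) || res$z_star <= 0) {
    return(severity_map(rep(NaN, Q), rep(TRUE, Q), kind, scale))
  }
  mag <- abs(res$z)
  s <- ifelse(mag > res$z_star, pmin(mag / res$z_star, max_fold), 0)
  masked <- !res$valid_mask | !is.finite(res$z)
  s[masked] <- NaN
  severity_map(s, masked, kind, scale)
}

severity_map <- function(values, masked, kind, scale, max_fold = NULL) {
  if (is.null(max_fold))
    max_fold <- if (kind == "multivariate") scale$max_fold_multi
                else scale$max_fold_uni
  structure(list(values = values, masked = masked, kind = kind,
                 max_fold = max_fold, scale = scale),
            class = "severity_map")
}

#' @export
print.severity_map <- function(x, ...) {
  sig <- sum(x$values > 0, na.rm = TRUE)
  cat(sprintf("<severity_map> %s (clip %g folds): %d/%d nodes significant",
              x$kind, x$max_fold, sig, length(x$values)))
  if (sig > 0)
    cat(sprintf(", peak %.2f folds", max(x$values, na.rm = TRUE)))
  if (any(x$masked)) cat(sprintf(", %d masked", sum(x$masked)))
  cat("\n")
  invisible(x)
}

#' Discretise a severity map into legend levels
#'
#' Significant severities are binned uniformly over `(1, max_fold]` into
#' `n_levels` levels (level 1 = just above threshold, level `n_levels` =
#' at/above the clip). Non-significant nodes get level 0; masked nodes get
#' the sentinel -1.
#'
#' @param map a severity map from [severity_from_spm()].
#' @param n_levels override for the scale's level count.
#' @return Integer vector of levels in `{-1, 0, 1, ..., n_levels}`.
#' @export
discretize_severity <- function(map, n_levels = map$scale$n_levels) {
  stopifnot(inherits(map, "severity_map"))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  s <- map$values
  lev <- integer(length(s))
  sig <- !map$masked & is.finite(s) & s > 0
  lev[sig] <- pmin(pmax(ceiling((s[sig] - 1) / (map$max_fold - 1) * n_levels),
                        1L), n_levels)
  lev[map$masked | !is.finite(s)] <- -1L
  lev
}

#' Legend colours for a severity scale
#'
#' Thin presentation helper mapping legend levels to hex colours for the
#' three supported MATLAB-like colormaps. Not part of the numeric contract.
#'
#' @param scale a [severity_scale()].
#' @param n_levels number of colours.
#' @return Character vector of `n_levels` hex colours (blue/cool end first).
#' @export
severity_colors <- function(scale = severity_scale(),
                            n_levels = scale$n_levels) {
  switch(scale$colormap,
    cool_to_warm = grDevices::colorRampPalette(
      c("#3B4CC0", "#B4C4E7", "#DDDDDD", "#F4987A", "#B40426"))(n_levels),
    jet = grDevices::colorRampPalette(
      c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F", "yellow",
        "#FF7F00", "red", "#7F0000"))(n_levels),
    viridis = grDevices::hcl.colors(n_levels, palette = "viridis"))
}

#' Write / read a severity map as CSV
#'
#' One header line then a single row of Q comma-separated fold values,
#' `NaN` at masked nodes. Values are written with 17 significant digits so
#' write/read/write round-trips are byte-identical.
#'
#' @param map a severity map ([severity_from_spm()]), or for reading, a
#'   path written by `write_severity_csv`.
#' @param path output path.
#' @return `write_severity_csv`: `path` invisibly. `read_severity_csv`: a
#'   `"severity_map"` (with a default scale attached; `kind` is restored
#'   from the header).
#' @export
write_severity_csv <- function(map, path) {
  stopifnot(inherits(map, "severity_map"))
  header <- sprintf("# severity folds-of-threshold, kind=%s, max_fold=%s",
                    map$kind, format_cell(map$max_fold))
  row <- paste(format_cell(map$values), collapse = ",")
  tryCatch(writeLines(c(header, row), path),
           error = function(e)
             stop(sprintf("cannot write '%s': %s", path,
                          conditionMessage(e))))
  invisible(path)
}

#' @rdname write_severity_csv
#' @export
read_severity_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop(sprintf("'%s': expected a header line plus one data row", path))
  kind <- if (grepl("kind=multivariate", lines[1L])) "multivariate"
          else "univariate"
  mf <- regmatches(lines[1L], regexpr("max_fold=[^,]+", lines[1L]))
  mf <- if (length(mf)) suppressWarnings(as.numeric(sub("max_fold=", "", mf)))
        else NA_real_
  values <- suppressWarnings(
    as.numeric(trimws(strsplit(lines[2L], ",", fixed = TRUE)[[1L]])))
  values[!is.finite(values)] <- NaN
  severity_map(values, masked = !is.finite(values), kind = kind,
               scale = severity_scale(),
               max_fold = if (is.finite(mf)) mf else NULL)
}
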