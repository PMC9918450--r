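#' Preprocessing specification
#'
#' Describes how raw trajectory rows are canonicalised before analysis:
#' time normalisation to a fixed node count, amplitude scaling (typically
#' body-weight normalisation of joint moments, Nm -> Nm/kg by dividing by
#' body mass in kg), and sign flipping of components recorded under a
#' laboratory convention that disagrees with the ISB positive directions.
#'
#' @param target_nodes number of nodes after time normalisation; 101 maps
#'   node i to exactly i\% of the gait cycle.
#' @param scale_factor positive scalar divisor (e.g. body mass in kg), or a
#'   vector recycled over trials for per-trial masses.
#' @param flip list of [component_key()] patterns; matching components are
#'   negated.
#' @param method interpolation method, `"linear"` (default; exact on
#'   piecewise-linear waveforms, no ringing) or `"cubic"` (natural spline).
#' @return Object of class `"preprocess_spec"`.
#' @export
preprocess_spec <- function(target_nodes = 101L, scale_factor = 1,
                            flip = list(), method = c("linear", "cubic")) {
  target_nodes <- as.integer(target_nodes)
  if (is.na(target_nodes) || target_nodes < 2L)
    stop("'target_nodes' must be an integer >= 2")
  if (any(!is.finite(scale_factor)) || any(scale_factor <= 0))
    stop("'scale_factor' must be positive")
  if (inherits(flip, "component_key")) flip <- list(flip)
  structure(list(target_nodes = target_nodes, scale_factor = scale_factor,
                 flip = flip, method = match.arg(method)),
            class = "preprocess_spec")
}

#' Time-normalise one trajectory row
#'
#' Resamples a row to `target_nodes` equally spaced points over the row's
#' finite support by piecewise-linear interpolation (never extrapolating
#' beyond the observed values). A trailing run of non-finite cells — e.g. a
#' recording that stops partway through the cycle — maps to a
#' proportionally placed trailing run of `NaN` nodes, so partial recordings
#' stay partial rather than being stretched to a full cycle.
#'
#' @param row numeric vector, length >= 2, finite except possibly a
#'   trailing non-finite run (interior non-finite cells are bridged by
#'   interpolation between their finite neighbours).
#' @param target_nodes output length (>= 2).
#' @param method `"linear"` or `"cubic"`.
#' @return Numeric vector of length `target_nodes`.
#' @examples
#' resample_to_nodes(seq(0, 1, length.out = 50), 101)  # exact ramp 0..1
#' @export
resample_to_nodes <- function(row, target_nodes = 101L,
                              method = c("linear", "cubic")) {
  method <- match.arg(method)
  m <- length(row)
  if (m < 2L) stop("cannot resample a row with fewer than 2 samples")
  target_nodes <- as.integer(target_nodes)
  if (target_nodes < 2L) stop("'target_nodes' must be >= 2")
  if (m == target_nodes && all(is.finite(row))) return(as.numeric(row))
  fin <- which(is.finite(row))
  if (length(fin) < 2L)
    stop("row has fewer than 2 finite samples; cannot interpolate")
  x <- seq(0, 1, length.out = m)
  xout <- seq(0, 1, length.out = target_nodes)
  out <- rep(NaN, target_nodes)
  # finite support ends at the last finite sample; beyond it stays missing
  support_end <- x[max(fin)]
  inside <- xout <= support_end + 1e-12
  if (method == "linear") {
    out[inside] <- approx(x[fin], row[fin], xout = xout[inside],
                          method = "linear", rule = 1)$y
  } else {
    sf <- stats::splinefun(x[fin], row[fin], method = "natural")
    out[inside] <- sf(xout[inside])
  }
  out
}

#' Canonicalise a trajectory set
#'
#' Applies, in order: time normalisation of every row to
#' `spec$target_nodes` nodes, division by `spec$scale_factor`, and negation
#' when the set's component key matches any pattern in `spec$flip`. The
#' missing mask is recomputed from the transformed values.
#'
#' @param ts a [trajectory_set()].
#' @param spec a [preprocess_spec()].
#' @return A new [trajectory_set()] with `node_count == spec$target_nodes`.
#' @export
apply_preprocess <- function(ts, spec = preprocess_spec()) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(spec, "preprocess_spec"))
  vals <- t(apply(ts$values, 1L, resample_to_nodes,
                  target_nodes = spec$target_nodes, method = spec$method))
  scale <- rep_len(spec$scale_factor, ts$n_trials)
  vals <- vals / scale
  if (!is.null(ts$meta) && key_matches(ts$meta, spec$flip)) vals <- -vals
  trajectory_set(vals, meta = ts$meta)
}

#' @rdname apply_preprocess
#' @param data a `"gait_dataset"`; every component is preprocessed.
#' @export
preprocess_dataset <- function(data, spec = preprocess_spec()) {
  stopifnot(inherits(data, "gait_dataset"))
  gait_dataset(lapply(data$components, apply_preprocess, spec = spec))
}
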