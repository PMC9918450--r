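# Synthetic gait-like trajectory datasets: smooth Gaussian noise around
# low-order sinusoid templates, with optional phase-localised deviations,
# written in the same CSV tree the loader reads. Used for calibration,
# power and fixture tests; not a biomechanically faithful gait simulation.

# Gaussian-kernel convolution matrix with reflecting boundaries, rows
# scaled so the output field has exactly unit pointwise SD for white
# unit-variance input (avoids edge variance loss distorting smoothness).
smoothing_matrix <- function(Q, fwhm) {
  sd_k <- fwhm / sqrt(8 * log(2))
  if (sd_k < 1e-8) return(diag(Q))
  pad <- ceiling(4 * sd_k)
  ext <- Q + 2L * pad
  # index into the reflected extension: positions -pad+1 .. Q+pad
  src <- c(rev(seq_len(pad) + 1L), seq_len(Q), Q - seq_len(pad))
  src <- pmin(pmax(src, 1L), Q)
  C <- matrix(0, Q, ext)
  offs <- -pad:pad
  w <- exp(-offs^2 / (2 * sd_k^2))
  for (qi in seq_len(Q)) C[qi, qi + pad + offs] <- w
  # fold the extension back onto the Q real nodes (reflection)
  M <- matrix(0, Q, Q)
  for (j in seq_len(ext)) M[, src[j]] <- M[, src[j]] + C[, j]
  M / sqrt(rowSums(M^2))
}

# smoothing matrices are deterministic in (Q, fwhm); cache across calls
.smooth_cache <- new.env(parent = emptyenv())
smoothing_matrix_cached <- function(Q, fwhm) {
  key <- sprintf("%d_%.10g", Q, fwhm)
  M <- .smooth_cache[[key]]
  if (is.null(M)) {
    M <- smoothing_matrix(Q, fwhm)
    .smooth_cache[[key]] <- M
  }
  M
}

#' Smooth 1D Gaussian random fields
#'
#' Draws `n` fields of length `Q`: white Gaussian noise convolved with a
#' Gaussian kernel of the given FWHM (reflecting boundaries), renormalised
#' to exactly unit pointwise SD and scaled by `sd`. This is the standard
#' validation substrate for 1D Random Field Theory: [estimate_fwhm()]
#' applied to such fields recovers `fwhm`.
#'
#' @param n number of fields (rows).
#' @param Q nodes per field (default 101).
#' @param fwhm smoothness in nodes (`fwhm <= 1` gives white noise).
#' @param sd pointwise standard deviation.
#' @return Numeric matrix `n x Q`.
#' @examples
#' f <- smooth_gaussian_field(5, fwhm = 20)
#' @export
smooth_gaussian_field <- function(n, Q = 101L, fwhm = 20, sd = 1) {
  stopifnot(n >= 1L, Q >= 2L, fwhm > 0, sd > 0)
  M <- smoothing_matrix_cached(Q, fwhm)
  noise <- matrix(rnorm(n * Q), n, Q)
  sd * noise %*% t(M)
}

#' Gait-like mean-curve templates
#'
#' Illustrative smooth templates (sums of low-order sinusoids over the
#' cycle) per measure/joint/dimension — e.g. a biphasic knee-moment-like
#' curve. Their exact shape is irrelevant to the statistics (group
#' comparisons subtract them out); they only make generated files look like
#' gait data. Moments are on a Nm/kg-like scale, kinematics on a
#' degrees-like scale.
#'
#' @param measure,joint,dimension component coordinates
#'   (see [component_key()]).
#' @param Q nodes.
#' @return Numeric vector of length `Q`.
#' @export
gait_template <- function(measure, joint, dimension, Q = 101L) {
  t <- seq(0, 1, length.out = Q)
  ji <- match(joint, JOINTS)
  di <- match(dimension, DIMENSIONS)
  base <- sin(2 * pi * (ji * t + 0.13 * di)) +
    0.5 * sin(2 * pi * (2 * t + 0.21 * ji * di)) +
    0.25 * cos(2 * pi * 3 * t)
  if (measure == "moments") 0.4 * base else 15 * base
}

#' Synthetic dataset specification
#'
#' Defines the generating conditions for [simulate_gait_dataset()]. The
#' defaults mirror a typical clinical comparison: a normative reference of
#' 20 subjects (each row the average of `subject_trials = 5` simulated
#' trials, with trial-level noise `sd * sqrt(subject_trials)` so delivered
#' reference rows have the same pointwise SD and smoothness as patient
#' trial rows), 10 patient trials per condition, 101 nodes, residual
#' smoothness FWHM 20 nodes, and noise SD 0.5 on the template scale.
#'
#' @param n_reference reference subjects (rows).
#' @param n_pre,n_post patient trials per condition (0 omits the
#'   condition).
#' @param Q nodes per cycle.
#' @param fwhm residual smoothness, nodes.
#' @param noise_sd pointwise noise SD (template units).
#' @param subject_trials pseudo-trials averaged per reference subject.
#' @param measures,limbs,joints,dimensions which components to generate.
#' @param effects list of effect specifications, each a list with fields
#'   `target` (a [component_key()] pattern; its `condition` selects which
#'   condition(s) receive the deviation), `center` (node, 0-based),
#'   `width` (Gaussian bump SD in nodes) and `amplitude` (template units).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_reference = 20L, n_pre = 10L, n_post = 10L,
                       Q = 101L, fwhm = 20, noise_sd = 0.5,
                       subject_trials = 5L,
                       measures = MEASURES, limbs = LIMBS, joints = JOINTS,
                       dimensions = DIMENSIONS,
                       effects = list(), seed = 0L) {
  stopifnot(Q >= 2L, fwhm >= 1, fwhm <= Q - 1, noise_sd > 0,
            subject_trials >= 1L)
  structure(list(n_reference = n_reference, n_pre = n_pre, n_post = n_post,
                 Q = as.integer(Q), fwhm = fwhm, noise_sd = noise_sd,
                 subject_trials = as.integer(subject_trials),
                 measures = match.arg(measures, MEASURES, several.ok = TRUE),
                 limbs = match.arg(limbs, LIMBS, several.ok = TRUE),
                 joints = match.arg(joints, JOINTS, several.ok = TRUE),
                 dimensions = match.arg(dimensions, DIMENSIONS,
                                        several.ok = TRUE),
                 effects = effects, seed = as.integer(seed)),
            class = "synth_spec")
}

gaussian_bump <- function(Q, center, width, amplitude) {
  x <- seq_len(Q) - 1L
  amplitude * exp(-(x - center)^2 / (2 * width^2))
}

#' Generate a synthetic gait dataset
#'
#' Per component and condition, rows are `template + injected effect bumps
#' + smooth Gaussian noise` ([smooth_gaussian_field()]). Reference rows
#' emulate per-subject trial averages (mean of `subject_trials` simulated
#' trials per pseudo-subject; see [synth_spec()] for the variance
#' convention that keeps all conditions equal in distribution under the
#' null). With `out_dir` the dataset is also written as a CSV tree in the
#' [default_naming()] scheme — byte-identical for identical seeds.
#'
#' @param spec a [synth_spec()].
#' @param out_dir optional directory to write the CSV tree into.
#' @return A `"gait_dataset"`.
#' @examples
#' ds <- simulate_gait_dataset(synth_spec(measures = "moments",
#'                                        limbs = "right", joints = "knee"))
#' @export
simulate_gait_dataset <- function(spec = synth_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    components <- list()
    conds <- c(reference = spec$n_reference, pre = spec$n_pre,
               post = spec$n_post)
    for (measure in spec$measures) for (limb in spec$limbs)
      for (joint in spec$joints) for (dimension in spec$dimensions) {
        tmpl <- gait_template(measure, joint, dimension, spec$Q)
        for (cond in names(conds)) {
          n <- conds[[cond]]
          if (n < 1L) next
          key <- component_key(measure, limb, joint, dimension, cond)
          if (cond == "reference") {
            k <- spec$subject_trials
            trials <- smooth_gaussian_field(n * k, spec$Q, spec$fwhm,
                                            spec$noise_sd * sqrt(k))
            rows <- rowsum(trials, rep(seq_len(n), each = k)) / k
          } else {
            rows <- smooth_gaussian_field(n, spec$Q, spec$fwhm,
                                          spec$noise_sd)
          }
          rows <- sweep(rows, 2L, tmpl, "+")
          for (eff in spec$effects) {
            if (key_matches(key, eff$target)) {
              bump <- gaussian_bump(spec$Q, eff$center, eff$width,
                                    eff$amplitude)
              rows <- sweep(rows, 2L, bump, "+")
            }
          }
          components[[key_id(key)]] <- trajectory_set(rows, meta = key)
        }
      }
    ds <- gait_dataset(components)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      naming <- default_naming()
      for (ts in ds$components)
        write_trajectory_csv(ts, file.path(out_dir, naming$filename(ts$meta)))
    }
    ds
  })
}
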