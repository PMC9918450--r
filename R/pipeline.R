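#' Analysis configuration
#'
#' Bundles everything [run_analysis()] needs: which of the five analysis
#' modes to run, the family-wise alpha (conventionally 5\%; presets
#' 0.01/0.05/0.10 or any value in (0,1)), the inference engine, the
#' severity legend scale and the preprocessing to apply.
#'
#' Modes and the tests they dispatch (multivariate bar / per-component):
#' \describe{
#'   \item{`pre_vs_ref`, `post_vs_ref`}{two-sample Hotelling's T-squared /
#'     two-sample t, patient condition vs normative reference.}
#'   \item{`both_vs_ref`}{the two comparisons above stacked in one report.}
#'   \item{`pre_vs_post_paired`}{paired Hotelling / paired t (trials paired
#'     by row index; equal counts required).}
#'   \item{`pre_vs_post_twosample`}{two-sample Hotelling / two-sample t.}
#' }
#'
#' @param mode one of the five modes above.
#' @param alpha family-wise type I error rate in (0, 1), default 0.05.
#' @param inference `"rft"` or `"permutation"`.
#' @param n_perm,seed permutation controls (seed also fixes any other
#'   randomness; RFT runs are exactly reproducible regardless).
#' @param scale a [severity_scale()].
#' @param preprocess a [preprocess_spec()] applied to every component
#'   before testing.
#' @param measures which measures to analyse.
#' @return Object of class `"analysis_config"`.
#' @export
analysis_config <- function(mode = c("pre_vs_ref", "post_vs_ref",
                                     "both_vs_ref", "pre_vs_post_paired",
                                     "pre_vs_post_twosample"),
                            alpha = 0.05,
                            inference = c("rft", "permutation"),
                            n_perm = 1000L, seed = 0L,
                            scale = severity_scale(),
                            preprocess = preprocess_spec(),
                            measures = c("moments", "kinematics")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a number strictly between 0 and 1")
  structure(list(mode = match.arg(mode), alpha = alpha,
                 inference = match.arg(inference),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 scale = scale, preprocess = preprocess,
                 measures = match.arg(measures, several.ok = TRUE)),
            class = "analysis_config")
}

mode_comparisons <- function(mode) {
  switch(mode,
    pre_vs_ref  = list(list(label = "pre_vs_ref", x = "pre",
                            y = "reference", paired = FALSE)),
    post_vs_ref = list(list(label = "post_vs_ref", x = "post",
                            y = "reference", paired = FALSE)),
    both_vs_ref = list(list(label = "pre_vs_ref", x = "pre",
                            y = "reference", paired = FALSE),
                       list(label = "post_vs_ref", x = "post",
                            y = "reference", paired = FALSE)),
    pre_vs_post_paired = list(list(label = "pre_vs_post", x = "pre",
                                   y = "post", paired = TRUE)),
    pre_vs_post_twosample = list(list(label = "pre_vs_post", x = "pre",
                                      y = "post", paired = FALSE)))
}

#' Run one analysis mode over a gait dataset
#'
#' For every measure x limb x joint with at least one movement component
#' present in both compared conditions, runs the mode's Hotelling variant
#' on the joint rotation vector (p = number of shared dimensions; with
#' p = 1 this is exactly the squared t field) and the mode's t variant on
#' each component, attaches fold-of-threshold severity maps, and collects
#' structured warnings for everything skipped or degenerate. Joints with
#' no shared components are skipped with a note, never an error; the run
#' is total over arbitrarily missing components.
#'
#' @param data a `"gait_dataset"` (see [load_gait_dataset()],
#'   [simulate_gait_dataset()]).
#' @param cfg an [analysis_config()].
#' @return Object of class `"gait_report"`: list of per-joint reports, each
#'   with `key` (measure/limb/joint), `comparisons` (one per mode
#'   comparison; `both_vs_ref` has two) carrying `multivariate` and
#'   `per_component` (each an `spm` + `severity` pair), `p`, and `notes`.
#' @export
run_analysis <- function(data, cfg = analysis_config()) {
  stopifnot(inherits(data, "gait_dataset"), inherits(cfg, "analysis_config"))
  comparisons <- mode_comparisons(cfg$mode)
  needed <- unique(unlist(lapply(comparisons, function(cp) c(cp$x, cp$y))))
  missing_conds <- setdiff(needed, data$conditions_present)
  if (length(missing_conds))
    stop(sprintf("mode '%s' needs condition(s) %s not present in the dataset",
                 cfg$mode, paste(missing_conds, collapse = ", ")))
  data <- preprocess_dataset(data, cfg$preprocess)

  reports <- list()
  for (measure in intersect(cfg$measures, MEASURES)) {
    for (limb in LIMBS) for (joint in JOINTS) {
      rep1 <- analyze_joint(data, measure, limb, joint, comparisons, cfg)
      if (!is.null(rep1))
        reports[[paste(measure, limb, joint, sep = "_")]] <- rep1
    }
  }
  structure(reports, class = "gait_report",
            mode = cfg$mode, alpha = cfg$alpha, inference = cfg$inference)
}

analyze_joint <- function(data, measure, limb, joint, comparisons, cfg) {
  # a joint with no data at all in any condition is silently not a finding;
  # a joint partially present gets a structured note
  present_any <- any(vapply(CONDITIONS, function(cond)
    length(joint_dimensions(data, cond, measure, limb, joint)) > 0L,
    logical(1)))
  if (!present_any) return(NULL)
  notes <- character(0)
  out_comparisons <- list()
  any_dims <- FALSE
  for (cp in comparisons) {
    dims <- intersect(joint_dimensions(data, cp$x, measure, limb, joint),
                      joint_dimensions(data, cp$y, measure, limb, joint))
    if (length(dims) == 0L) {
      notes <- c(notes, sprintf("%s %s %s: no shared components for %s; skipped",
                                measure, limb, joint, cp$label))
      next
    }
    any_dims <- TRUE
    res <- tryCatch(
      run_joint_comparison(data, measure, limb, joint, dims, cp, cfg),
      error = function(e) {
        if (cp$paired && grepl("equal trial counts", conditionMessage(e)))
          stop(e)  # pairing errors are contract violations, not tolerance
        notes <<- c(notes, sprintf("%s %s %s (%s): %s", measure, limb, joint,
                                   cp$label, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) {
      notes <- c(notes, res$notes)
      res$notes <- NULL
      out_comparisons[[cp$label]] <- res
    }
  }
  if (!any_dims && length(out_comparisons) == 0L) {
    if (length(notes)) warning(paste(notes, collapse = "; "), call. = FALSE)
    return(NULL)
  }
  p <- if (length(out_comparisons))
    max(vapply(out_comparisons, function(cp) cp$p, integer(1))) else 0L
  list(key = list(measure = measure, limb = limb, joint = joint),
       comparisons = out_comparisons, p = p, notes = notes)
}

run_joint_comparison <- function(data, measure, limb, joint, dims, cp, cfg) {
  notes <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  X <- joint_vector_set(data, cp$x, measure, limb, joint, dims)
  Y <- joint_vector_set(data, cp$y, measure, limb, joint, dims)
  multiv <- collect(
    if (cp$paired) spm_hotelling_paired(X, Y, alpha = cfg$alpha,
                                        inference = cfg$inference,
                                        n_perm = cfg$n_perm, seed = cfg$seed)
    else spm_hotelling_two_sample(X, Y, alpha = cfg$alpha,
                                  inference = cfg$inference,
                                  n_perm = cfg$n_perm, seed = cfg$seed))
  per_component <- list()
  for (d in dims) {
    a <- get_component(data, component_key(measure, limb, joint, d, cp$x))
    b <- get_component(data, component_key(measure, limb, joint, d, cp$y))
    res <- collect(
      if (cp$paired) spm_t_paired(a, b, alpha = cfg$alpha,
                                  inference = cfg$inference,
                                  n_perm = cfg$n_perm, seed = cfg$seed)
      else spm_t_two_sample(a, b, alpha = cfg$alpha,
                            inference = cfg$inference,
                            n_perm = cfg$n_perm, seed = cfg$seed))
    per_component[[d]] <- list(spm = res,
                               severity = severity_from_spm(res, cfg$scale))
  }
  list(label = cp$label, p = length(dims), dimensions = dims,
       multivariate = list(spm = multiv,
                           severity = severity_from_spm(multiv, cfg$scale)),
       per_component = per_component,
       notes = notes)
}

#' @export
print.gait_report <- function(x, ...) {
  cat(sprintf("<gait_report> mode %s, alpha %g, %s inference; %d joint(s)\n",
              attr(x, "mode"), attr(x, "alpha"), attr(x, "inference"),
              length(x)))
  for (r in x) {
    cat(sprintf("  %s %s %s (p = %d)\n", r$key$measure, r$key$limb,
                r$key$joint, r$p))
    for (cp in r$comparisons) {
      sev <- cp$multivariate$severity
      peak <- if (any(sev$values > 0, na.rm = TRUE))
        sprintf("peak severity %.2f folds", max(sev$values, na.rm = TRUE))
      else "no significant deviation"
      cat(sprintf("    %s [3D, p=%d]: %s\n", cp$label, cp$p, peak))
    }
    for (w in r$notes) cat("    note:", w, "\n")
  }
  invisible(x)
}
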