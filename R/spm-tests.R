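# Exported SPM tests: statistic field + smoothness + family-wise threshold
# + supra-threshold clusters, bundled into an "spm_result".

spm_result <- function(z, stat_kind, df, p, alpha, fwhm, resels, z_star,
                       valid_mask, two_sided, inference, n, notes) {
  clusters <- extract_clusters(z, z_star, valid_mask,
                               two_sided = two_sided && p == 1L)
  structure(list(z = z, stat_kind = stat_kind, df = df, p = p, alpha = alpha,
                 fwhm = fwhm, resels = resels, z_star = z_star,
                 clusters = clusters, valid_mask = valid_mask,
                 two_sided = two_sided, inference = inference, n = n,
                 notes = notes),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> %s field  (n = %s, df = %g%s)\n", x$stat_kind,
              paste(x$n, collapse = " vs "), x$df,
              if (x$p > 1L) sprintf(", p = %d", x$p) else ""))
  cat(sprintf("  alpha = %g (%s%s)   FWHM = %s nodes   resels = %s   z* = %s\n",
              x$alpha, x$inference,
              if (startsWith(x$stat_kind, "t"))
                if (x$two_sided) ", two-sided" else ", one-sided" else "",
              fmt_or_na(x$fwhm), fmt_or_na(x$resels), fmt_or_na(x$z_star)))
  nc <- nrow(x$clusters)
  if (nc == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    iv <- sprintf("%d-%d%%", x$clusters$start, x$clusters$end)
    cat(sprintf("  %d supra-threshold cluster%s: %s  (percent of cycle)\n",
                nc, if (nc > 1L) "s" else "", paste(iv, collapse = ", ")))
  }
  for (w in x$notes) cat("  note:", w, "\n")
  invisible(x)
}

fmt_or_na <- function(x) if (is.finite(x)) sprintf("%.3f", x) else "NA"

values_of <- function(x, what) {
  if (inherits(x, "trajectory_set")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("'%s' must be a trajectory_set or a numeric matrix", what))
}

finite_node_mask <- function(...) {
  masks <- lapply(list(...), function(M) {
    if (length(dim(M)) == 3L) apply(M, 2L, function(s) all(is.finite(s)))
    else apply(M, 2L, function(col) all(is.finite(col)))
  })
  Reduce(`&`, masks)
}

# shared tail of every spm_* wrapper: smoothness, resels, threshold, result
finish_spm <- function(z, stat_kind, df, p, residuals, valid, alpha,
                       inference, n_perm, seed, two_sided, n, notes,
                       perm_args = NULL) {
  degenerate <- !any(valid)
  if (degenerate) {
    notes <- c(notes, "no valid nodes: statistic field is entirely degenerate")
    warning(notes[length(notes)], call. = FALSE)
    return(spm_result(z, stat_kind, df, p, alpha, NA_real_, NA_real_,
                      NA_real_, valid, two_sided, inference, n, notes))
  }
  fwhm <- estimate_fwhm(residuals, valid)
  resels <- resel_count(valid, fwhm)
  z_star <- if (inference == "rft") {
    rft_threshold(if (p == 1L && startsWith(stat_kind, "t")) "t" else "T2",
                  nu = df, p = p, resels = resels, alpha = alpha,
                  two_sided = two_sided)
  } else {
    as.numeric(do.call(permutation_threshold,
                       c(perm_args, list(alpha = alpha, n_perm = n_perm,
                                         seed = seed, two_sided = two_sided,
                                         valid_mask = valid))))
  }
  spm_result(z, stat_kind, df, p, alpha, fwhm, resels, z_star, valid,
             two_sided, inference, n, notes)
}

#' Two-sample t SPM over a trajectory continuum
#'
#' At every valid node q the pooled-variance two-sample t statistic
#' \deqn{z(q) = \frac{\bar a(q) - \bar b(q)}
#'   {\sqrt{s_p^2(q) (1/n_a + 1/n_b)}}}
#' is computed (degrees of freedom `n_a + n_b - 2`), and the family-wise
#' critical threshold for the whole field is obtained from 1D Random Field
#' Theory ([rft_threshold()]) or by permutation
#' ([permutation_threshold()]). Nodes where any trial is non-finite, or
#' where the pooled variance is zero, are flagged invalid with a warning —
#' never an error — and excluded from the field and the resel count.
#'
#' @param a,b [trajectory_set()]s or numeric matrices (trials x Q), at
#'   least 2 trials each, equal node counts.
#' @param alpha family-wise type I error rate (default 0.05).
#' @param inference `"rft"` (default) or `"permutation"`.
#' @param n_perm,seed permutation inference controls.
#' @param two_sided threshold the `|t|` field (default `TRUE`).
#' @return An `"spm_result"`; see [rft_threshold()] and
#'   [extract_clusters()] for the threshold and cluster conventions.
#' @examples
#' a <- matrix(rnorm(10 * 101), 10)
#' b <- matrix(rnorm(10 * 101), 10)
#' spm_t_two_sample(a, b)
#' @export
spm_t_two_sample <- function(a, b, alpha = 0.05,
                             inference = c("rft", "permutation"),
                             n_perm = 1000L, seed = 0L, two_sided = TRUE) {
  inference <- match.arg(inference)
  A <- values_of(a, "a"); B <- values_of(b, "b")
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("both groups need at least 2 trials")
  if (ncol(A) != ncol(B)) stop("'a' and 'b' must share the node count")
  valid <- finite_node_mask(A, B)
  f <- t_field_two_sample(A, B)
  notes <- character(0)
  zerovar <- f$zero_var & valid
  if (any(zerovar)) {
    valid <- valid & !zerovar
    f$z[zerovar] <- NA_real_
    notes <- c(notes, sprintf("%d node(s) with zero pooled variance flagged invalid",
                              sum(zerovar)))
    warning(notes[length(notes)], call. = FALSE)
  }
  f$z[!valid] <- NA_real_
  residuals <- rbind(sweep(A, 2L, colMeans(A)), sweep(B, 2L, colMeans(B)))
  finish_spm(f$z, "t_twosample", f$df, 1L, residuals, valid, alpha,
             inference, n_perm, seed, two_sided, c(nrow(A), nrow(B)), notes,
             perm_args = list(a = A, b = B, stat_kind = "t_twosample"))
}

#' Paired t SPM over a trajectory continuum
#'
#' Node-wise paired t statistic `z(q) = mean(d(q)) / (sd(d(q))/sqrt(n))` on
#' the row-wise differences `d = a - b`, with `n - 1` degrees of freedom;
#' family-wise inference as in [spm_t_two_sample()].
#'
#' @inheritParams spm_t_two_sample
#' @return An `"spm_result"`.
#' @export
spm_t_paired <- function(a, b, alpha = 0.05,
                         inference = c("rft", "permutation"),
                         n_perm = 1000L, seed = 0L, two_sided = TRUE) {
  inference <- match.arg(inference)
  A <- values_of(a, "a"); B <- values_of(b, "b")
  if (nrow(A) != nrow(B))
    stop(sprintf("paired test needs equal trial counts (%d vs %d)",
                 nrow(A), nrow(B)))
  if (nrow(A) < 2L) stop("need at least 2 trial pairs")
  if (ncol(A) != ncol(B)) stop("'a' and 'b' must share the node count")
  valid <- finite_node_mask(A, B)
  f <- t_field_paired(A, B)
  notes <- character(0)
  zerovar <- f$zero_var & valid
  if (any(zerovar)) {
    valid <- valid & !zerovar
    f$z[zerovar] <- NA_real_
    notes <- c(notes, sprintf("%d node(s) with zero difference variance flagged invalid",
                              sum(zerovar)))
    warning(notes[length(notes)], call. = FALSE)
  }
  f$z[!valid] <- NA_real_
  D <- A - B
  residuals <- sweep(D, 2L, colMeans(D))
  finish_spm(f$z, "t_paired", f$df, 1L, residuals, valid, alpha, inference,
             n_perm, seed, two_sided, nrow(A), notes,
             perm_args = list(a = A, b = B, stat_kind = "t_paired"))
}

prep_vector_args <- function(a, b, what = c("a", "b")) {
  A <- as_array3(a); B <- as_array3(b)
  if (!identical(dim(A)[2:3], dim(B)[2:3]))
    stop(sprintf("'%s' and '%s' must share node count and components",
                 what[1L], what[2L]))
  list(A = A, B = B, p = dim(A)[3L])
}

# residuals stacked over components (trials*p x Q), mean removed per group
stacked_residuals <- function(A, B = NULL) {
  p <- dim(A)[3L]
  out <- vector("list", p)
  for (i in seq_len(p)) {
    Ai <- A[, , i, drop = FALSE][, , 1L]
    ri <- sweep(Ai, 2L, colMeans(Ai))
    if (!is.null(B)) {
      Bi <- B[, , i, drop = FALSE][, , 1L]
      ri <- rbind(ri, sweep(Bi, 2L, colMeans(Bi)))
    }
    out[[i]] <- ri
  }
  do.call(rbind, out)
}

#' Two-sample Hotelling's T-squared SPM for joint rotation vectors
#'
#' Multivariate analogue of [spm_t_two_sample()] for the up-to-3-component
#' joint vector: at every valid node
#' \deqn{z(q) = \frac{n_a n_b}{n_a + n_b}
#'   (\bar a(q) - \bar b(q))^\top W(q)^{-1} (\bar a(q) - \bar b(q))}
#' with pooled covariance `W(q)` and `nu = n_a + n_b - 2` degrees of
#' freedom. Family-wise inference goes through the exact pointwise
#' transform to an F field (see [rft_threshold()]). Nodes with a singular
#' pooled covariance are flagged invalid, not errors. With a single
#' component (`p = 1`, e.g. an ankle missing its Y/Z recordings) the field
#' reduces exactly to the squared two-sample t field.
#'
#' @param a,b [joint_vector_set()]s or trials x Q x p arrays (matrices are
#'   taken as p = 1); `n_a + n_b - 2 > p` required.
#' @inheritParams spm_t_two_sample
#' @return An `"spm_result"` with `stat_kind = "T2_twosample"`.
#' @export
spm_hotelling_two_sample <- function(a, b, alpha = 0.05,
                                     inference = c("rft", "permutation"),
                                     n_perm = 1000L, seed = 0L) {
  inference <- match.arg(inference)
  v <- prep_vector_args(a, b)
  na <- dim(v$A)[1L]; nb <- dim(v$B)[1L]
  if (na < 2L || nb < 2L) stop("both groups need at least 2 trials")
  if (na + nb - 2L <= v$p)
    stop(sprintf("need n_a + n_b - 2 > p (have %d trials, p = %d)",
                 na + nb, v$p))
  valid <- finite_node_mask(v$A, v$B)
  f <- T2_field_two_sample(v$A, v$B)
  notes <- character(0)
  singular <- valid & !is.finite(f$z)
  if (any(singular)) {
    valid <- valid & !singular
    notes <- c(notes, sprintf("%d node(s) with singular pooled covariance flagged invalid",
                              sum(singular)))
    warning(notes[length(notes)], call. = FALSE)
  }
  f$z[!valid] <- NA_real_
  finish_spm(f$z, "T2_twosample", f$df, v$p, stacked_residuals(v$A, v$B),
             valid, alpha, inference, n_perm, seed, FALSE, c(na, nb), notes,
             perm_args = list(a = v$A, b = v$B, stat_kind = "T2_twosample"))
}

#' Paired Hotelling's T-squared SPM for joint rotation vectors
#'
#' As [spm_hotelling_two_sample()] but on paired differences:
#' `z(q) = n * dbar(q)' S(q)^{-1} dbar(q)` with `nu = n - 1 > p`.
#'
#' @inheritParams spm_hotelling_two_sample
#' @return An `"spm_result"` with `stat_kind = "T2_paired"`.
#' @export
spm_hotelling_paired <- function(a, b, alpha = 0.05,
                                 inference = c("rft", "permutation"),
                                 n_perm = 1000L, seed = 0L) {
  inference <- match.arg(inference)
  v <- prep_vector_args(a, b)
  n <- dim(v$A)[1L]
  if (dim(v$B)[1L] != n)
    stop(sprintf("paired test needs equal trial counts (%d vs %d)",
                 n, dim(v$B)[1L]))
  if (n - 1L <= v$p)
    stop(sprintf("need n - 1 > p (have n = %d, p = %d)", n, v$p))
  valid <- finite_node_mask(v$A, v$B)
  f <- T2_field_paired(v$A, v$B)
  notes <- character(0)
  singular <- valid & !is.finite(f$z)
  if (any(singular)) {
    valid <- valid & !singular
    notes <- c(notes, sprintf("%d node(s) with singular difference covariance flagged invalid",
                              sum(singular)))
    warning(notes[length(notes)], call. = FALSE)
  }
  f$z[!valid] <- NA_real_
  D <- v$A - v$B
  finish_spm(f$z, "T2_paired", f$df, v$p, stacked_residuals(D), valid,
             alpha, inference, n_perm, seed, FALSE, n, notes,
             perm_args = list(a = v$A, b = v$B, stat_kind = "T2_paired"))
}
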