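# Nonparametric family-wise inference: permutation distribution of the
# field maximum (max |t| for two-sided t fields, max T2 for Hotelling
# fields). Serves both as an assumption-light alternative to RFT and as an
# internal validation oracle for the RFT thresholds.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

as_array3 <- function(x) {
  if (inherits(x, "joint_vector_set")) return(x$values)
  if (inherits(x, "trajectory_set")) x <- x$values
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

# max of the statistic field over valid nodes for one relabelling
field_max <- function(stat_fun, two_sided) {
  function(A, B, valid) {
    z <- stat_fun(A, B)$z[valid]
    z <- z[is.finite(z)]
    if (length(z) == 0L) return(NA_real_)
    if (two_sided) max(abs(z)) else max(z)
  }
}

#' Permutation family-wise threshold for a 1D statistic field
#'
#' Computes the `1 - alpha` quantile (linear-interpolation empirical
#' quantile) of the permutation distribution of the field maximum:
#' group labels are permuted for two-sample statistics, difference signs
#' for paired statistics. When the number of distinct relabellings does not
#' exceed `n_perm`, all of them are enumerated (exact test); otherwise
#' `n_perm` random relabellings are drawn, deterministically for a given
#' `seed`. If fewer distinct relabellings exist than `1/alpha`, the
#' requested alpha cannot be resolved and a warning is issued (exact
#' enumeration is still used).
#'
#' @param a,b trajectory sets, numeric matrices (trials x Q), or
#'   trials x Q x p arrays / [joint_vector_set()]s for T-squared kinds.
#' @param stat_kind one of `"t_twosample"`, `"t_paired"`, `"T2_twosample"`,
#'   `"T2_paired"`.
#' @param alpha family-wise type I error rate.
#' @param n_perm maximum number of permutations (>= 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param two_sided t kinds only: threshold the `|t|` maximum (default).
#' @param valid_mask optional logical length-Q vector restricting the
#'   field maximum to valid nodes.
#' @return Critical threshold (numeric scalar) with attributes `exact`
#'   (logical) and `n_perm` (relabellings actually used).
#' @export
permutation_threshold <- function(a, b,
                                  stat_kind = c("t_twosample", "t_paired",
                                                "T2_twosample", "T2_paired"),
                                  alpha = 0.05, n_perm = 1000L, seed = 0L,
                                  two_sided = TRUE, valid_mask = NULL) {
  stat_kind <- match.arg(stat_kind)
  if (n_perm < 100L) stop("'n_perm' must be at least 100")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  A <- as_array3(a); B <- as_array3(b)
  Q <- dim(A)[2L]; p <- dim(A)[3L]
  stopifnot(dim(B)[2L] == Q, dim(B)[3L] == p)
  paired <- grepl("paired", stat_kind)
  multiv <- startsWith(stat_kind, "T2")
  if (multiv) two_sided <- FALSE
  stat_fun <- if (multiv) {
    if (paired) T2_field_paired else T2_field_two_sample
  } else {
    drop1 <- function(f) function(X, Y) f(X[, , 1L], Y[, , 1L])
    if (paired) drop1(t_field_paired) else drop1(t_field_two_sample)
  }
  fmax <- field_max(stat_fun, two_sided)
  if (is.null(valid_mask)) {
    finite_nodes <- function(X) apply(X, 2L, function(s) all(is.finite(s)))
    valid_mask <- finite_nodes(A) & finite_nodes(B)
  }

  na <- dim(A)[1L]; nb <- dim(B)[1L]
  if (paired) {
    if (na != nb) stop("paired permutation needs equal trial counts")
    n_distinct <- 2^na
  } else {
    n_distinct <- choose(na + nb, na)
  }
  exact <- n_distinct <= n_perm
  if (n_distinct < 1 / alpha)
    warning(sprintf(
      "only %.0f distinct relabellings < 1/alpha = %.0f; alpha cannot be resolved (exact enumeration used)",
      n_distinct, 1 / alpha), call. = FALSE)

  maxima <- if (paired) {
    # sign-flip the paired differences; realised as swapping a and b rows
    flips <- if (exact) {
      m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), na)))
      lapply(seq_len(nrow(m)), function(i) m[i, ])
    } else {
      with_seed(seed, replicate(n_perm,
        sample(c(FALSE, TRUE), na, replace = TRUE), simplify = FALSE))
    }
    vapply(flips, function(fl) {
      Ap <- A; Bp <- B
      Ap[fl, , ] <- B[fl, , ]; Bp[fl, , ] <- A[fl, , ]
      fmax(Ap, Bp, valid_mask)
    }, numeric(1))
  } else {
    Z <- array(NA_real_, dim = c(na + nb, Q, p))
    Z[seq_len(na), , ] <- A
    Z[na + seq_len(nb), , ] <- B
    splits <- if (exact) {
      cb <- combn(na + nb, na)
      lapply(seq_len(ncol(cb)), function(i) cb[, i])
    } else {
      with_seed(seed, replicate(n_perm, sample.int(na + nb, na),
                                simplify = FALSE))
    }
    vapply(splits, function(idx) {
      fmax(Z[idx, , , drop = FALSE], Z[-idx, , , drop = FALSE], valid_mask)
    }, numeric(1))
  }
  maxima <- maxima[is.finite(maxima)]
  if (length(maxima) == 0L)
    stop("permutation distribution is empty (no valid nodes?)")
  z_star <- unname(quantile(maxima, probs = 1 - alpha, type = 7))
  attr(z_star, "exact") <- exact
  attr(z_star, "n_perm") <- length(maxima)
  z_star
}
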