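# Node-wise statistic fields, vectorised across the 101 cycle nodes.
# All functions operate on plain matrices (trials x Q) or arrays
# (trials x Q x p); the exported spm_* wrappers accept the package's
# container classes and add family-wise inference.

# -- univariate fields -------------------------------------------------------

# centred form: exact zero on constant columns (no cancellation residue),
# so zero-variance detection is reliable
col_var <- function(X) {
  n <- nrow(X)
  C <- X - rep(colMeans(X), each = n)
  colSums(C * C) / (n - 1)
}

# a node is zero-variance when its SD vanishes relative to the data scale
# (catches exact constants and constant shifts whose differences carry only
# floating-point rounding residue)
near_zero_sd <- function(sd, scale) {
  is.finite(sd) & sd <= 1e-12 * pmax(scale, .Machine$double.xmin)
}

t_field_two_sample <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  sp2 <- ((na - 1) * col_var(A) + (nb - 1) * col_var(B)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  z <- (colMeans(A) - colMeans(B)) / se
  scale <- (colSums(abs(A)) + colSums(abs(B))) / (na + nb)
  list(z = z, df = na + nb - 2, zero_var = near_zero_sd(sqrt(sp2), scale))
}

t_field_paired <- function(A, B) {
  D <- A - B
  n <- nrow(D)
  sd_d <- sqrt(col_var(D))
  z <- colMeans(D) / (sd_d / sqrt(n))
  scale <- (colSums(abs(A)) + colSums(abs(B))) / (2 * n)
  list(z = z, df = n - 1, zero_var = near_zero_sd(sd_d, scale))
}

# -- multivariate fields -----------------------------------------------------

# per-node mean (p x Q) and covariance entries (upper triangle, list of Q-vectors)
array_moments <- function(X) {
  n <- dim(X)[1L]; Q <- dim(X)[2L]; p <- dim(X)[3L]
  M <- matrix(NA_real_, p, Q)
  S <- vector("list", p * p); dim(S) <- c(p, p)
  Cc <- vector("list", p)
  for (i in seq_len(p)) {
    Xi <- X[, , i, drop = FALSE][, , 1L]
    M[i, ] <- colMeans(Xi)
    Cc[[i]] <- Xi - rep(M[i, ], each = n)   # centred: exact zeros survive
  }
  for (i in seq_len(p)) for (j in i:p)
    S[[i, j]] <- colSums(Cc[[i]] * Cc[[j]]) / (n - 1)
  list(mean = M, cov = S, n = n)
}

# quadratic form d' W^{-1} d per node, closed-form inverses for p <= 3
quad_form_field <- function(d, W, p) {
  if (p == 1L) {
    det <- W[[1L, 1L]]
    q <- d[1L, ]^2 / det
  } else if (p == 2L) {
    w11 <- W[[1L, 1L]]; w12 <- W[[1L, 2L]]; w22 <- W[[2L, 2L]]
    det <- w11 * w22 - w12^2
    q <- (d[1L, ]^2 * w22 - 2 * d[1L, ] * d[2L, ] * w12 +
            d[2L, ]^2 * w11) / det
  } else if (p == 3L) {
    w11 <- W[[1L, 1L]]; w12 <- W[[1L, 2L]]; w13 <- W[[1L, 3L]]
    w22 <- W[[2L, 2L]]; w23 <- W[[2L, 3L]]; w33 <- W[[3L, 3L]]
    det <- w11 * (w22 * w33 - w23^2) - w12 * (w12 * w33 - w23 * w13) +
      w13 * (w12 * w23 - w22 * w13)
    i11 <- (w22 * w33 - w23^2) / det
    i12 <- (w13 * w23 - w12 * w33) / det
    i13 <- (w12 * w23 - w13 * w22) / det
    i22 <- (w11 * w33 - w13^2) / det
    i23 <- (w12 * w13 - w11 * w23) / det
    i33 <- (w11 * w22 - w12^2) / det
    q <- d[1L, ]^2 * i11 + d[2L, ]^2 * i22 + d[3L, ]^2 * i33 +
      2 * (d[1L, ] * d[2L, ] * i12 + d[1L, ] * d[3L, ] * i13 +
             d[2L, ] * d[3L, ] * i23)
  } else {
    stop("quad_form_field supports p <= 3")
  }
  q[!is.finite(det) | det <= 0] <- NA_real_
  q
}

T2_field_two_sample <- function(A, B) {
  p <- dim(A)[3L]
  ma <- array_moments(A); mb <- array_moments(B)
  na <- ma$n; nb <- mb$n; nu <- na + nb - 2
  W <- ma$cov
  for (i in seq_len(p)) for (j in i:p)
    W[[i, j]] <- ((na - 1) * ma$cov[[i, j]] + (nb - 1) * mb$cov[[i, j]]) / nu
  d <- ma$mean - mb$mean
  z <- (na * nb / (na + nb)) * quad_form_field(d, W, p)
  list(z = z, df = nu, p = p)
}

T2_field_paired <- function(A, B) {
  D <- A - B
  p <- dim(D)[3L]
  md <- array_moments(D)
  n <- md$n
  z <- n * quad_form_field(md$mean, md$cov, p)
  list(z = z, df = n - 1, p = p)
}

# -- smoothness --------------------------------------------------------------

#' Estimate residual-field smoothness (FWHM)
#'
#' Estimates the full width at half maximum of the effective Gaussian
#' autocorrelation kernel of a set of residual trajectories, in node units.
#' Residuals are normalised to unit variance per node; the mean squared
#' gradient \eqn{\bar v} of the normalised residuals between adjacent valid
#' nodes then satisfies \eqn{FWHM = \sqrt{4\log 2 / \bar v}} for a
#' Gaussian-autocorrelated field. For white (node-independent) noise
#' \eqn{\bar v \to 2}, giving the rough-field floor
#' \eqn{\sqrt{2\log 2} \approx 1.18}. The estimate is clipped to
#' `[1, Q - 1]`.
#'
#' @param residuals numeric matrix (trials x Q) of mean-removed residuals.
#' @param valid_mask optional logical length-Q vector; gradients are taken
#'   only between adjacent valid nodes.
#' @return FWHM in nodes (positive scalar).
#' @export
estimate_fwhm <- function(residuals, valid_mask = NULL) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 2L)
  Q <- ncol(residuals)
  if (Q < 2L) stop("need at least 2 nodes to estimate smoothness")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, Q)
  rms <- sqrt(colMeans(residuals^2))
  usable <- valid_mask & is.finite(rms) & rms > 0
  pair <- which(usable[-Q] & usable[-1L])   # adjacent valid pairs
  if (length(pair) == 0L) {
    warning("degenerate residuals: no adjacent valid nodes; returning upper clip",
            call. = FALSE)
    return(Q - 1)
  }
  U <- sweep(residuals, 2L, rms, "/")
  grad2 <- (U[, pair + 1L, drop = FALSE] - U[, pair, drop = FALSE])^2
  vbar <- mean(grad2)
  if (!is.finite(vbar) || vbar <= 0) {
    warning("degenerate residuals: zero gradient variance; returning upper clip",
            call. = FALSE)
    return(Q - 1)
  }
  min(max(sqrt(4 * log(2) / vbar), 1), Q - 1)
}

# resel count over the valid extent: sum over contiguous valid runs of
# (run length - 1) / FWHM; equals (n_valid - 1)/FWHM when contiguous
resel_count <- function(valid_mask, fwhm) {
  r <- rle(valid_mask)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) return(0)
  sum(pmax(runs - 1L, 0L)) / fwhm
}

# -- clusters ----------------------------------------------------------------

#' Supra-threshold clusters of a statistic field
#'
#' Maximal runs of valid nodes whose statistic exceeds the critical
#' threshold (strictly: boundary equality is non-significant). Invalid
#' nodes split runs. Intervals are reported in percent-of-cycle node units
#' (node i at position i, 0-based, so node 50 is 50\% of the cycle for a
#' 101-node field).
#'
#' @param z numeric statistic field.
#' @param z_star critical threshold.
#' @param valid_mask logical; `FALSE` nodes can never belong to a cluster.
#'   Defaults to the finite nodes of `z`.
#' @param two_sided if `TRUE`, exceedance is on `abs(z)`.
#' @return `data.frame` with integer columns `start` and `end` (inclusive,
#'   0-based nodes).
#' @export
extract_clusters <- function(z, z_star, valid_mask = NULL, two_sided = FALSE) {
  if (is.null(valid_mask)) valid_mask <- is.finite(z)
  if (!is.finite(z_star))
    return(data.frame(start = integer(0), end = integer(0)))
  val <- if (two_sided) abs(z) else z
  exceed <- valid_mask & is.finite(val) & val > z_star
  r <- rle(as.vector(exceed))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}
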