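# shared fixtures, all generated in code

# trials x Q x p array of independent smooth unit fields
make_vector_array <- function(n, p, Q = 101L, fwhm = 20, sd = 1) {
  A <- array(0, c(n, Q, p))
  for (i in seq_len(p)) A[, , i] <- smooth_gaussian_field(n, Q, fwhm, sd)
  A
}

# write a trajectory CSV by hand (independent of write_trajectory_csv)
write_raw_csv <- function(path, rows, header = "h") {
  body <- vapply(rows, function(r) paste(r, collapse = ","), character(1))
  writeLines(c(header, body), path)
}

# textbook node-wise oracles (loops + stats::t.test / solve), kept
# deliberately independent of the vectorised implementation
# direct-formula pooled t field (fast enough for Monte Carlo loops)
t_field_two_sample_for_test <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  (colMeans(A) - colMeans(B)) / sqrt(sp2 * (1 / na + 1 / nb))
}

oracle_t_two_sample <- function(A, B) {
  vapply(seq_len(ncol(A)), function(q)
    unname(stats::t.test(A[, q], B[, q], var.equal = TRUE)$statistic),
    numeric(1))
}

oracle_t_paired <- function(A, B) {
  vapply(seq_len(ncol(A)), function(q)
    unname(stats::t.test(A[, q], B[, q], paired = TRUE)$statistic),
    numeric(1))
}

oracle_T2_two_sample <- function(A, B) {
  na <- dim(A)[1L]; nb <- dim(B)[1L]; Q <- dim(A)[2L]
  vapply(seq_len(Q), function(q) {
    Xa <- A[, q, ]; Xb <- B[, q, ]
    if (is.null(dim(Xa))) { Xa <- cbind(Xa); Xb <- cbind(Xb) }
    d <- colMeans(Xa) - colMeans(Xb)
    W <- ((na - 1) * stats::cov(Xa) + (nb - 1) * stats::cov(Xb)) /
      (na + nb - 2)
    (na * nb / (na + nb)) * drop(t(d) %*% solve(W) %*% d)
  }, numeric(1))
}

oracle_T2_paired <- function(A, B) {
  D <- A - B
  n <- dim(D)[1L]; Q <- dim(D)[2L]
  vapply(seq_len(Q), function(q) {
    Xd <- D[, q, ]
    if (is.null(dim(Xd))) Xd <- cbind(Xd)
    d <- colMeans(Xd)
    n * drop(t(d) %*% solve(stats::cov(Xd)) %*% d)
  }, numeric(1))
}

# minimal spm_result stand-in for severity tests
fake_spm <- function(z, z_star, stat_kind = "t_twosample",
                     valid = is.finite(z)) {
  structure(list(z = z, stat_kind = stat_kind, df = 10, p = 1L,
                 alpha = 0.05, fwhm = 10, resels = 10, z_star = z_star,
                 clusters = extract_clusters(z, z_star, valid,
                                             two_sided = TRUE),
                 valid_mask = valid, two_sided = TRUE, inference = "rft",
                 n = c(6, 6), notes = character(0)),
            class = "spm_result")
}
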