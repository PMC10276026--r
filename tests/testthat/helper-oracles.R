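# Independent oracles and small dataset builders shared across tests.

# Dense-formula restricted log-likelihood: direct evaluation of
# -1/2 [log|V| + log|X'V^-1 X| + y'Py + (N-p) log 2pi] with explicit
# matrices. Deliberately naive (O(N^3) with full V) so it shares no code
# path with the package's Woodbury implementation.
dense_reml_ll <- function(design, comps) {
  Z <- as.matrix(design$Z)
  X <- design$X
  y <- design$y
  V <- comps[["residual"]] * diag(length(y))
  for (k in names(design$kernels))
    V <- V + comps[[k]] * Z %*% design$kernels[[k]] %*% t(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y +
                       (length(y) - ncol(X)) * log(2 * pi)))
}

# Brute-force double-loop kernel construction
brute_kernel <- function(M, denom) {
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(M[i, ] * M[j, ]) / denom
  K
}

# Complete small simulated dataset with kernels, for REML/CV tests
small_gblup_data <- function(n = 60, m = 150, sigma2_a = 0.5,
                             sigma2_d = 0.3, sigma2_e = 0.5, seed = 101,
                             years = c("2018" = 0, "2019" = 0.4),
                             records_per_year = 1) {
  cfg <- sim_config(n_individuals = n, n_markers = m, missing_rate = 0,
                    sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                    sigma2_e = sigma2_e, year_effects = years,
                    records_per_year = records_per_year, seed = seed)
  dat <- simulate_dataset(cfg)
  p <- allele_frequency(dat$genotypes)
  W <- build_W(dat$genotypes, p)
  S <- build_S(dat$genotypes, p)
  dat$freqs_hat <- p
  dat$G <- vanraden_G(W, p)
  dat$D <- vitezica_D(S, p)
  dat$I <- identity_kernel(rownames(dat$genotypes))
  dat
}
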