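test_that("design matrices encode years and repeated records correctly", {
  ph <- expand.grid(genotype_id = c("a", "b", "c"),
                    year = c("2018", "2019"), stringsAsFactors = FALSE)
  ph$trait <- "t"
  ph$value <- rnorm(6)
  K <- identity_kernel(c("a", "b", "c"))
  d <- build_design(ph, "t", list(genetic = K))
  expect_equal(dim(d$X), c(6L, 2L))
  expect_equal(qr(d$X)$rank, 2L)
  expect_equal(dim(d$Z), c(6L, 3L))
  expect_equal(unname(Matrix::colSums(d$Z)), rep(2, 3))

  # unbalanced: dropping one record drops its row everywhere
  d2 <- build_design(ph[-2, ], "t", list(genetic = K))
  expect_equal(d2$n_records, 5L)
  expect_equal(unname(Matrix::colSums(d2$Z)), c(2, 1, 2))

  ph_bad <- ph
  ph_bad$genotype_id[1] <- "zz"
  expect_error(build_design(ph_bad, "t", list(genetic = K)), "absent")
})

test_that("restricted likelihood matches a dense-formula oracle and scales correctly", {
  dat <- small_gblup_data(n = 20, m = 40, seed = 41)
  d <- build_design(dat$phenotypes, "trait",
                    list(additive = dat$G, dominance = dat$D))
  for (comps in list(c(additive = 0.5, dominance = 0.3, residual = 0.5),
                     c(additive = 1.2, dominance = 0.01, residual = 0.2))) {
    expect_equal(restricted_loglik(d, comps), dense_reml_ll(d, comps),
                 tolerance = 1e-8)
  }
  # unit change y -> c*y shifts the restricted LL by -(N - p) log c
  cc <- 3.7
  ph2 <- dat$phenotypes
  ph2$value <- cc * ph2$value
  d2 <- build_design(ph2, "trait", list(additive = dat$G,
                                        dominance = dat$D))
  comps <- c(additive = 0.5, dominance = 0.3, residual = 0.5)
  comps2 <- comps * cc^2
  expect_equal(restricted_loglik(d2, comps2),
               restricted_loglik(d, comps) -
                 (d$n_records - d$rank_X) * log(cc),
               tolerance = 1e-8)
  expect_error(restricted_loglik(d, c(additive = 0.5, residual = 1)),
               "named")
})

test_that("identity-kernel fit equals the classical random-intercept REML (lme4 oracle)", {
  skip_if_not_installed("lme4")
  dat <- small_gblup_data(n = 40, m = 50, sigma2_d = 0, seed = 42,
                          years = c("2018" = 1, "2019" = 1.5,
                                    "2021" = 0.8))
  d <- build_design(dat$phenotypes, "trait", list(genetic = dat$I))
  fit <- reml_fit(d)
  lf <- lme4::lmer(value ~ 0 + factor(year) + (1 | genotype_id),
                   data = dat$phenotypes, REML = TRUE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lf)),
               tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(unname(fit$variance_components), vc, tolerance = 1e-4)
  expect_equal(sort(unname(fit$fixed_effects)),
               sort(unname(lme4::fixef(lf))), tolerance = 1e-6)
})

test_that("GBLUP-A GEBVs equal ridge-regression marker predictions", {
  dat <- small_gblup_data(n = 30, m = 50, sigma2_a = 1, sigma2_d = 0,
                          sigma2_e = 1, seed = 43)
  d <- build_design(dat$phenotypes, "trait", list(additive = dat$G))
  fit <- reml_fit(d)
  sa <- fit$variance_components[["additive"]]
  se <- fit$variance_components[["residual"]]
  p <- dat$freqs_hat
  W <- build_W(dat$genotypes, p)
  lambda <- se / (sa / sum(2 * p * (1 - p)))
  Z <- as.matrix(d$Z)
  X <- d$X
  ZW <- Z %*% W
  C <- rbind(cbind(t(X) %*% X, t(X) %*% ZW),
             cbind(t(ZW) %*% X, t(ZW) %*% ZW + lambda * diag(ncol(W))))
  sol <- solve(C, c(t(X) %*% d$y, t(ZW) %*% d$y))
  gebv_rr <- unname(drop(W %*% sol[-(1:ncol(X))]))
  expect_equal(unname(fit$random_solutions$additive), gebv_rr,
               tolerance = 1e-6)
})

test_that("solutions satisfy Henderson's mixed-model equations", {
  dat <- small_gblup_data(n = 50, m = 200, seed = 44)
  # invertible kernels so the MME can be formed explicitly
  K1 <- dat$G + 0.05 * diag(nrow(dat$G))
  dimnames(K1) <- dimnames(dat$G)
  K2 <- dat$D + 0.05 * diag(nrow(dat$D))
  dimnames(K2) <- dimnames(dat$D)
  d <- build_design(dat$phenotypes, "trait",
                    list(additive = K1, dominance = K2))
  fit <- reml_fit(d)
  se <- fit$variance_components[["residual"]]
  Z <- as.matrix(d$Z)
  X <- d$X
  resid <- d$y - X %*% fit$fixed_effects -
    Z %*% (fit$random_solutions$additive +
             fit$random_solutions$dominance)
  lhs_x <- t(X) %*% resid / se
  expect_lt(max(abs(lhs_x)) / max(abs(t(X) %*% d$y / se)), 1e-8)
  for (k in c("additive", "dominance")) {
    K <- if (k == "additive") K1 else K2
    sk <- fit$variance_components[[k]]
    u <- fit$random_solutions[[k]]
    gap <- t(Z) %*% resid / se - solve(K, u) / sk
    expect_lt(max(abs(gap)) / max(abs(t(Z) %*% d$y / se)), 1e-6)
  }
})

test_that("the reported optimum is a local maximum with honest PEV", {
  dat <- small_gblup_data(n = 60, m = 150, seed = 45)
  d <- build_design(dat$phenotypes, "trait",
                    list(additive = dat$G, dominance = dat$D))
  fit <- reml_fit(d)
  expect_true(fit$converged)
  comps <- fit$variance_components
  for (k in names(comps)) {
    for (eps in c(-0.01, 0.01)) {
      pert <- comps
      pert[k] <- max(pert[k] * (1 + eps), 1e-10)
      if (pert[k] != comps[k])
        expect_lte(restricted_loglik(d, pert), fit$loglik + 1e-6)
    }
  }
  # PEV bounded by the prior variance per term
  kernels <- list(additive = dat$G, dominance = dat$D)
  for (k in c("additive", "dominance")) {
    expect_true(all(fit$pev[[k]] >= 0))
    expect_true(all(fit$pev[[k]] <=
                      comps[k] * diag(kernels[[k]]) + 1e-8))
  }
  expect_true(all(fit$pev_genetic >= 0))
  expect_lte(pev_scalar(fit), comps[["additive"]] + comps[["dominance"]])
})

test_that("a zero dominance variance is recovered at the boundary", {
  hits <- 0L
  for (s in 1:10) {
    dat <- small_gblup_data(n = 200, m = 500, sigma2_a = 0.6,
                            sigma2_d = 0, sigma2_e = 0.6, seed = 500 + s)
    d <- build_design(dat$phenotypes, "trait",
                      list(additive = dat$G, dominance = dat$D))
    fit <- reml_fit(d)
    tot <- sum(fit$variance_components)
    if (fit$variance_components[["dominance"]] < 0.05 * tot)
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("information criteria follow the fixed-effect-count convention", {
  # arithmetic on published goodness-of-fit rows: LL -345.05 with 4 year
  # levels gives AIC 698.1; LL -257.97 with 3 gives 521.93
  expect_equal(unname(information_criteria(-345.05, k = 4)["AIC"]), 698.1)
  # printed LL is rounded to 2 d.p., so AIC agrees to one printed unit
  expect_lt(abs(information_criteria(-257.97, k = 3)[["AIC"]] - 521.93),
            0.011)
  expect_equal(unname(information_criteria(-100, k = 0)["AIC"]), 200)
  ic <- information_criteria(-100, k = 3, v = 200)
  expect_equal(unname(ic["BIC"]), 200 + 3 * log(200))

  dat <- small_gblup_data(n = 30, m = 60, seed = 46)
  d <- build_design(dat$phenotypes, "trait", list(additive = dat$G))
  fit <- reml_fit(d)
  ic <- information_criteria(fit)
  expect_equal(unname(ic["AIC"]), 2 * fit$rank_X - 2 * fit$loglik)
  expect_equal(unname(ic["BIC"]),
               -2 * fit$loglik + fit$rank_X *
                 log(fit$n_records - fit$rank_X))
})

test_that("the dominance LRT uses the boundary chi-square mixture", {
  dat <- small_gblup_data(n = 40, m = 100, seed = 47)
  dA <- build_design(dat$phenotypes, "trait", list(additive = dat$G))
  dAD <- build_design(dat$phenotypes, "trait",
                      list(additive = dat$G, dominance = dat$D))
  fA <- reml_fit(dA)
  fAD <- reml_fit(dAD)
  lt <- lrt_dominance(fA, fAD)
  expect_gte(lt$statistic, 0)
  expect_equal(lt$p_value,
               0.5 * pchisq(lt$statistic, 1, lower.tail = FALSE))
  # convention at the boundary: equal likelihoods give p = 0.5
  fake <- fAD
  fake$loglik <- fA$loglik
  expect_equal(lrt_dominance(fA, fake)$statistic, 0)
  expect_equal(lrt_dominance(fA, fake)$p_value, 0.5)
  # 3.84 corresponds to half the usual chi2_1 tail
  expect_equal(0.5 * pchisq(3.84, 1, lower.tail = FALSE), 0.025,
               tolerance = 1e-3)
  expect_error(lrt_dominance(fAD, fA), "nested")
})
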