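test_that("fold partitions are balanced, exhaustive and reproducible", {
  ids <- sprintf("G%03d", 1:275)
  plan <- make_folds(ids, k = 5, seed = 1)
  sizes <- table(plan$fold_assignment)
  expect_equal(unname(c(sizes)), rep(55L, 5))
  expect_setequal(names(plan$fold_assignment), ids)

  plan7 <- make_folds(letters[1:7], k = 5, seed = 2)
  sz <- sort(table(plan7$fold_assignment))
  expect_lte(max(sz) - min(sz), 1)
  expect_equal(sum(sz), 7L)

  expect_identical(make_folds(ids, 5, seed = 9),
                   make_folds(ids, 5, seed = 9))
  expect_error(make_folds(letters[1:3], k = 5), "more folds")
})

test_that("masking removes exactly the validation phenotypes (no leakage)", {
  dat <- small_gblup_data(n = 30, m = 60, seed = 51)
  plan <- make_folds(rownames(dat$G), k = 5, seed = 3)
  val_ids <- names(plan$fold_assignment)[plan$fold_assignment == 2]
  pred <- predict_masked(dat$phenotypes, "trait", list(additive = dat$G),
                         plan, 2)
  fit <- attr(pred, "fit")
  manual <- dat$phenotypes[!(dat$phenotypes$genotype_id %in% val_ids), ]
  expect_identical(fit$design$records$value, manual$value)
  expect_identical(fit$design$records$genotype_id, manual$genotype_id)
  # every individual, including masked ones, receives a prediction
  expect_setequal(names(pred), rownames(dat$G))
})

test_that("identity-kernel BLUP cannot predict untested individuals", {
  dat <- small_gblup_data(n = 40, m = 60, seed = 52)
  cv <- cross_validate(dat$phenotypes, "trait",
                       list(genetic = dat$I), k = 5, seed = 4)
  # no information flows between unrelated individuals: predictions for
  # the validation fold are constant (zero) and score r = 0 by convention
  expect_equal(cv$mean_r, 0)
  expect_true(all(cv$per_fold$constant))
})

test_that("predictive ability is 1 for perfect predictions and interpolates duplicates", {
  dat <- small_gblup_data(n = 30, m = 60, seed = 53)
  rec <- dat$phenotypes
  means <- tapply(rec$value, rec$genotype_id, mean)
  plan <- make_folds(names(means), k = 3, seed = 5)
  perfect <- lapply(1:3, function(f) means)
  res <- predictive_ability(perfect, dat$phenotypes, "trait", plan)
  expect_equal(res$mean_r, 1)
  expect_equal(res$se_r, 0)

  # a validation individual genomically identical to a training one gets
  # (approximately) that individual's BLUP through the kernel
  g <- dat$genotypes
  g["G002", ] <- g["G001", ]  # duplicate genotype row
  p <- allele_frequency(g)
  G2 <- vanraden_G(build_W(g, p), p)
  ph <- dat$phenotypes[dat$phenotypes$genotype_id != "G002", ]
  plan2 <- make_folds(rownames(G2), k = 5, seed = 6)
  f2 <- plan2$fold_assignment[["G002"]]
  # ensure G001 trains while G002 is masked
  if (plan2$fold_assignment[["G001"]] == f2)
    plan2$fold_assignment[["G001"]] <- (f2 %% 5) + 1
  pred <- predict_masked(ph, "trait", list(additive = G2), plan2, f2)
  expect_equal(unname(pred["G002"]), unname(pred["G001"]),
               tolerance = 0.02)
})

test_that("an empty mask reproduces the full-data fit", {
  dat <- small_gblup_data(n = 25, m = 50, seed = 54)
  plan <- make_folds(rownames(dat$G), k = 5, seed = 7)
  plan$fold_assignment[] <- 1L  # fold 2 is empty
  pred <- predict_masked(dat$phenotypes, "trait", list(additive = dat$G),
                         plan, 2)
  d <- build_design(dat$phenotypes, "trait", list(additive = dat$G))
  full <- genetic_values(reml_fit(d))
  expect_equal(as.numeric(pred), as.numeric(full), tolerance = 1e-8)
})

test_that("genomic predictive ability rises with heritability", {
  mean_r_at <- function(h2_target, seed) {
    se <- 1 - h2_target
    rs <- numeric(3)
    for (i in 1:3) {
      dat <- small_gblup_data(n = 120, m = 300, sigma2_a = h2_target,
                              sigma2_d = 0, sigma2_e = se,
                              seed = seed + i)
      cv <- cross_validate(dat$phenotypes, "trait",
                           list(additive = dat$G), k = 5, seed = seed)
      rs[i] <- cv$mean_r
    }
    mean(rs)
  }
  r_low <- mean_r_at(0.1, 60)
  r_mid <- mean_r_at(0.4, 70)
  r_high <- mean_r_at(0.7, 80)
  expect_true(cor(c(0.1, 0.4, 0.7), c(r_low, r_mid, r_high),
                  method = "spearman") > 0)
  expect_gt(r_high, r_low)
})
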