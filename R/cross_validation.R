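#' Partition individuals into cross-validation folds
#'
#' Uniform random partition over genotypes (all years of a genotype are
#' masked together so no phenotype of a validation individual leaks into
#' training). Fold sizes differ by at most one; 275 individuals in 5 folds
#' give the classical 220/55 training/validation split.
#'
#' @param individual_ids Labels to partition.
#' @param k Number of folds (>= 2).
#' @param seed Optional integer seed.
#' @return A list of class `cv_plan` with the named integer
#'   `fold_assignment`, `k` and `seed`.
#' @export
make_folds <- function(individual_ids, k = 5, seed = NULL) {
  n <- length(individual_ids)
  stopifnot(k >= 2)
  if (k > n) stop("more folds than individuals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  assignment <- stats::setNames(
    rep_len(seq_len(k), n)[sample.int(n)], individual_ids)
  structure(list(fold_assignment = assignment, k = as.integer(k),
                 seed = seed),
            class = "cv_plan")
}

#' Refit on training records and predict masked individuals
#'
#' Removes every phenotype record of the fold's individuals, refits the
#' model by REML on the training records only (variance components are
#' re-estimated per fold), and predicts all individuals through the
#' kernel: validation individuals carry no records, so their solutions are
#' the conditional expectations given the training BLUPs. For the
#' additive-dominance model the prediction is `g + d`; for the identity
#' kernel no information flows and validation predictions are all zero.
#'
#' @param phenotypes Long-format phenotype table.
#' @param trait Trait to model.
#' @param kernels Named list of relationship matrices (over all
#'   individuals, training and validation).
#' @param plan A [make_folds()] plan.
#' @param fold Fold index to mask.
#' @param ... Passed to [reml_fit()].
#' @return Named vector of total genetic predictions for all individuals,
#'   with the fitted `reml_fit` attached as attribute `"fit"`.
#' @export
predict_masked <- function(phenotypes, trait, kernels, plan, fold, ...) {
  stopifnot(inherits(plan, "cv_plan"), fold %in% seq_len(plan$k))
  val_ids <- names(plan$fold_assignment)[plan$fold_assignment == fold]
  training <- phenotypes[!(phenotypes$genotype_id %in% val_ids), ,
                         drop = FALSE]
  design <- build_design(training, trait, kernels)
  fit <- reml_fit(design, ...)
  pred <- genetic_values(fit)
  attr(pred, "fit") <- fit
  pred
}

#' Predictive ability from per-fold predictions
#'
#' Per fold, the Pearson correlation between the predictions of the
#' validation individuals and their across-year phenotypic means. Folds
#' whose predictions are constant (no information flow, as for
#' identity-kernel BLUP) score `r = 0` by convention and are flagged;
#' folds with fewer than 3 usable pairs are skipped with a message. The
#' summary is the mean correlation across folds and its standard error
#' `sd / sqrt(k)`.
#'
#' @param predictions List of per-fold prediction vectors (as from
#'   [predict_masked()], one element per fold).
#' @param phenotypes Long-format phenotype table.
#' @param trait Trait evaluated.
#' @param plan The [make_folds()] plan.
#' @return A list of class `cv_result`: `per_fold` data.frame (`fold`,
#'   `r`, `n`, `constant`), `mean_r`, `se_r`.
#' @export
predictive_ability <- function(predictions, phenotypes, trait, plan) {
  stopifnot(inherits(plan, "cv_plan"),
            length(predictions) == plan$k)
  rec <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ]
  pheno_mean <- tapply(rec$value, rec$genotype_id, mean)
  rows <- lapply(seq_len(plan$k), function(f) {
    val_ids <- names(plan$fold_assignment)[plan$fold_assignment == f]
    val_ids <- intersect(val_ids, names(pheno_mean))
    pred <- predictions[[f]][val_ids]
    obs <- pheno_mean[val_ids]
    ok <- is.finite(pred) & is.finite(obs)
    if (sum(ok) < 3) {
      message("fold ", f, " skipped: fewer than 3 usable pairs")
      return(NULL)
    }
    constant <- stats::sd(pred[ok]) < 1e-10
    r <- if (constant) 0 else stats::cor(pred[ok], obs[ok])
    data.frame(fold = f, r = r, n = sum(ok), constant = constant)
  })
  per_fold <- do.call(rbind, rows)
  if (is.null(per_fold) || nrow(per_fold) == 0L)
    stop("no usable folds", call. = FALSE)
  structure(list(per_fold = per_fold,
                 mean_r = mean(per_fold$r),
                 se_r = stats::sd(per_fold$r) / sqrt(nrow(per_fold))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Predictive ability: mean r = %.3f (SE %.3f) over %d folds\n",
              x$mean_r, x$se_r, nrow(x$per_fold)))
  invisible(x)
}

#' K-fold cross-validated predictive ability
#'
#' Full procedure: partition the genotypes, refit per fold on training
#' records, predict the masked individuals through the kernel, and
#' correlate with their across-year phenotype means.
#'
#' @inheritParams predict_masked
#' @param k Number of folds.
#' @param seed Seed for the fold partition.
#' @param ... Passed to [reml_fit()].
#' @return A `cv_result` (see [predictive_ability()]) with the plan
#'   attached as attribute `"plan"`.
#' @export
cross_validate <- function(phenotypes, trait, kernels, k = 5, seed = NULL,
                           ...) {
  ids <- rownames(kernels[[1]])
  plan <- make_folds(ids, k = k, seed = seed)
  predictions <- lapply(seq_len(k), function(f)
    predict_masked(phenotypes, trait, kernels, plan, f, ...))
  res <- predictive_ability(predictions, phenotypes, trait, plan)
  attr(res, "plan") <- plan
  res
}
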