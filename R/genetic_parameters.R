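#' Narrow- and broad-sense heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_d + sigma2_e)` and
#' `H2 = (sigma2_a + sigma2_d) / (sigma2_a + sigma2_d + sigma2_e)`. For
#' additive-only models `sigma2_d = 0`, so `h2 = H2`.
#'
#' @param components A [reml_fit()] or a named numeric vector with
#'   `additive`, `residual` and optionally `dominance`.
#' @return Named vector `c(h2 = , H2 = )`.
#' @export
#' @examples
#' heritabilities(c(additive = 0.39, dominance = 0.62, residual = 1.27))
heritabilities <- function(components) {
  vc <- .as_components(components)
  tot <- vc["additive"] + vc["dominance"] + vc["residual"]
  if (!is.finite(tot) || tot <= 0)
    stop("total variance must be positive", call. = FALSE)
  c(h2 = unname(vc["additive"] / tot),
    H2 = unname((vc["additive"] + vc["dominance"]) / tot))
}

#' Dominance ratio and additive-variance ratio between models
#'
#' `d2 = sigma2_d / (sigma2_a + sigma2_d + sigma2_e)` from the
#' additive-dominance fit, and `RL_aa = sigma2_a(AD) / sigma2_a(A)`, the
#' ratio of the additive variance estimated with dominance in the model to
#' the additive-only estimate. Values of `RL_aa` well below 1 indicate
#' that the additive-only model absorbed dominance variance.
#'
#' @param fit_AD Additive-dominance fit (or named component vector with
#'   `additive`, `dominance`, `residual`).
#' @param fit_A Additive-only fit (or named component vector).
#' @return Named vector `c(d2 = , rl_aa = )`; `rl_aa` is `NA` with a
#'   warning when the additive-only variance is zero.
#' @export
dominance_ratios <- function(fit_AD, fit_A) {
  ad <- .as_components(fit_AD)
  a <- .as_components(fit_A)
  tot <- ad["additive"] + ad["dominance"] + ad["residual"]
  if (!is.finite(tot) || tot <= 0)
    stop("total variance must be positive", call. = FALSE)
  d2 <- unname(ad["dominance"] / tot)
  rl_aa <- if (a["additive"] <= 0) {
    warning("additive-only sigma2_a is zero; RL_aa undefined")
    NA_real_
  } else unname(ad["additive"] / a["additive"])
  c(d2 = d2, rl_aa = rl_aa)
}

#' Theoretical accuracy of genetic value prediction
#'
#' `r = sqrt(1 - PEV / sigma2_g)`, where `sigma2_g` is the model's total
#' genetic variance: `sigma2_a` for additive-only models and
#' `sigma2_a + sigma2_d` for the additive-dominance model. If the PEV
#' exceeds the genetic variance the accuracy is clipped to 0 with a
#' warning.
#'
#' @param pev_scalar Non-negative prediction error variance (e.g. from
#'   [pev_scalar()]).
#' @param sigma2_g Positive genetic variance.
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' accuracy(0.21, 0.65)
accuracy <- function(pev_scalar, sigma2_g) {
  stopifnot(pev_scalar >= 0)
  if (sigma2_g <= 0)
    stop("genetic variance must be positive", call. = FALSE)
  ratio <- 1 - pev_scalar / sigma2_g
  if (ratio < 0) {
    warning("PEV exceeds the genetic variance; accuracy clipped to 0")
    ratio <- 0
  }
  sqrt(ratio)
}

#' Genetic parameters of a fitted model
#'
#' Convenience wrapper assembling heritabilities, scalar PEV and accuracy
#' for one fit (with `sigma2_g` the model's total genetic variance).
#'
#' @param fit A [reml_fit()].
#' @return Named vector with `sigma2_a`, `sigma2_d`, `sigma2_e`, `h2`,
#'   `H2`, `PEV`, `r`.
#' @export
genetic_params <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  vc <- .as_components(fit)
  h <- heritabilities(vc)
  pev <- pev_scalar(fit)
  sg <- vc["additive"] + vc["dominance"]
  r <- if (sg > 0) accuracy(pev, sg) else NA_real_
  c(sigma2_a = unname(vc["additive"]), sigma2_d = unname(vc["dominance"]),
    sigma2_e = unname(vc["residual"]), h, PEV = pev, r = unname(r))
}

# Normalize a fit or named vector to c(additive, dominance, residual).
# Single-kernel fits map their genetic term (whatever its name, e.g.
# "genetic" for the identity-kernel BLUP) to "additive".
.as_components <- function(x) {
  if (inherits(x, "reml_fit")) x <- x$variance_components
  stopifnot(is.numeric(x), !is.null(names(x)))
  out <- c(additive = 0, dominance = 0, residual = NA_real_)
  out["residual"] <- x[["residual"]]
  known <- intersect(names(x), c("additive", "dominance"))
  out[known] <- x[known]
  other <- setdiff(names(x), c("additive", "dominance", "residual"))
  if (length(other) == 1 && !"additive" %in% names(x))
    out["additive"] <- x[[other]]
  else if (length(other) > 0)
    stop("unrecognized variance components: ",
         paste(other, collapse = ", "), call. = FALSE)
  out
}

#' Published genetic-parameter estimates for Euterpe edulis fruit traits
#'
#' Reference tables of REML estimates reported for a 275-genotype juçara
#' palm (*Euterpe edulis*) population genotyped at 8,112 post-QC SNPs:
#' variance components with heritabilities, dominance-effect ratios, and
#' goodness-of-fit / prediction criteria, per trait and model (BLUP,
#' GBLUP-A, GBLUP-AD). Used to validate the derived-parameter arithmetic of
#' this package against independently produced estimates.
#'
#' @param table One of `"components"`, `"dominance_ratios"`,
#'   `"fit_criteria"`.
#' @return A `data.frame`.
#' @export
published_estimates <- function(table = c("components", "dominance_ratios",
                                          "fit_criteria")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0("published_", table, ".csv"),
                      package = "gblupad", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
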