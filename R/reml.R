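#' Assemble the mixed-model design for one trait
#'
#' Builds the record-level design of
#' `y = X beta + sum_k Z u_k + e`, where `X` is the cell-means incidence of
#' the year factor (one column per observed year, no intercept), `Z` maps
#' each record to its individual so that repeated records of one individual
#' share a single genetic effect, and each random term `k` has covariance
#' `K_k sigma2_k` over individuals. Individuals present in the kernels but
#' without records are retained: their effects are predicted through the
#' kernel, which is what makes genomic cross-validation possible.
#'
#' @param phenotypes Long-format `data.frame` with columns `genotype_id`,
#'   `year`, `trait`, `value`.
#' @param trait Trait to model.
#' @param kernels Named list of relationship matrices sharing identical
#'   individual labels, e.g. `list(additive = G)` or
#'   `list(additive = G, dominance = D)`.
#' @return A list of class `gblup_design`.
#' @export
build_design <- function(phenotypes, trait, kernels) {
  stopifnot(is.data.frame(phenotypes),
            all(c("genotype_id", "year", "trait", "value") %in%
                  names(phenotypes)),
            is.list(kernels), length(kernels) >= 1,
            !is.null(names(kernels)))
  rec <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                    drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no phenotype records for trait ", trait, call. = FALSE)
  ids <- rownames(kernels[[1]])
  if (is.null(ids))
    stop("kernels must carry individual ids as dimnames", call. = FALSE)
  for (K in kernels)
    if (!identical(rownames(K), ids))
      stop("all kernels must share identical individual labels",
           call. = FALSE)
  missing_ids <- setdiff(unique(rec$genotype_id), ids)
  if (length(missing_ids) > 0)
    stop("individuals absent from kernel labels: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  year <- factor(rec$year)
  X <- stats::model.matrix(~ 0 + year)
  colnames(X) <- levels(year)
  idx <- match(rec$genotype_id, ids)
  n <- nrow(rec)
  q <- length(ids)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                            dims = c(n, q))
  structure(list(y = rec$value, X = X, Z = Z,
                 counts = tabulate(idx, q),
                 ids = ids, kernels = kernels, trait = trait,
                 records = rec,
                 n_records = n, rank_X = ncol(X)),
            class = "gblup_design")
}

# Single evaluation of the restricted likelihood and, optionally, of the
# score/average-information quantities. Everything is reduced to q x q
# (individual-level) algebra through the Woodbury identity
#   V^{-1} = (I - Z M^{-1} Gamma Z') / s_e,  M = s_e I + Gamma Z'Z,
# and Sylvester's determinant identity
#   log|V| = (N - q) log s_e + log|M|,
# with Gamma = sum_k s_k K_k. This never inverts a kernel, so singular G or
# D are handled exactly.
.reml_eval <- function(d, comps, want_ai = FALSE) {
  terms <- names(d$kernels)
  se <- comps[["residual"]]
  N <- d$n_records
  p <- d$rank_X
  q <- length(d$ids)
  Gam <- matrix(0, q, q)
  for (k in terms) Gam <- Gam + comps[[k]] * d$kernels[[k]]
  M <- sweep(Gam, 2, d$counts, `*`)
  diag(M) <- diag(M) + se
  Mqr <- tryCatch(qr(M, LAPACK = TRUE), error = function(e) NULL)
  if (is.null(Mqr)) return(NULL)
  rdiag <- abs(diag(qr.R(Mqr)))
  if (any(rdiag <= 0) || !all(is.finite(rdiag))) return(NULL)
  logdetM <- sum(log(rdiag))
  solveM <- function(B) solve(Mqr, B)
  solveV <- function(B) {
    B <- as.matrix(B)
    ZtB <- as.matrix(Matrix::crossprod(d$Z, B))
    (B - as.matrix(d$Z %*% solveM(Gam %*% ZtB))) / se
  }
  ViX <- solveV(d$X)
  Viy <- solveV(d$y)
  XtViX <- crossprod(d$X, ViX)
  XtViy <- crossprod(d$X, Viy)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(NULL)
  beta <- backsolve(cX, forwardsolve(t(cX), XtViy))
  ytViy <- sum(d$y * Viy)
  yPy <- ytViy - sum(XtViy * beta)
  logdetV <- (N - q) * log(se) + logdetM
  ll <- -0.5 * (logdetV + 2 * sum(log(diag(cX))) + yPy +
                  (N - p) * log(2 * pi))
  if (!is.finite(ll)) return(NULL)
  out <- list(ll = ll, beta = drop(beta), yPy = yPy)
  Py <- Viy - ViX %*% beta
  out$Py <- drop(Py)
  out$v <- drop(as.matrix(Matrix::crossprod(d$Z, Py)))  # Z'Py, q-vector
  if (!want_ai) return(out)

  # score and average-information pieces, all at q x q cost
  T1 <- solveM(sweep(Gam, 2, d$counts, `*`))            # M^{-1} Gamma Dn
  ZtViZ <- (diag(q) - T1) * d$counts / se               # row-scale by Dn
  ZtViX <- as.matrix(Matrix::crossprod(d$Z, ViX))       # q x p
  XtViX_inv <- chol2inv(cX)
  npar <- length(terms) + 1L
  score <- numeric(npar)
  wlist <- vector("list", npar)
  for (i in seq_along(terms)) {
    K <- d$kernels[[terms[i]]]
    trViH <- sum(K * t(ZtViZ))
    tmp <- t(ZtViX) %*% K %*% ZtViX                     # p x p
    trPH <- trViH - sum(XtViX_inv * tmp)
    vKv <- drop(crossprod(out$v, K %*% out$v))
    score[i] <- -0.5 * (trPH - vKv)
    wlist[[i]] <- as.matrix(d$Z %*% (K %*% out$v))
  }
  trVi <- (N - sum(diag(T1))) / se
  trP <- trVi - sum(XtViX_inv * crossprod(d$X, solveV(ViX)))
  score[npar] <- -0.5 * (trP - sum(out$Py^2))
  wlist[[npar]] <- matrix(out$Py, ncol = 1)
  Pw <- lapply(wlist, function(w) {
    as.matrix(solveV(w)) - ViX %*% (XtViX_inv %*% crossprod(ViX, w))
  })
  AI <- matrix(0, npar, npar)
  for (i in seq_len(npar))
    for (j in i:npar)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(wlist[[i]] * Pw[[j]])
  out$score <- score
  out$AI <- AI
  out$ZtViZ <- ZtViZ
  out$ZtViX <- ZtViX
  out$XtViX_inv <- XtViX_inv
  out
}

#' Restricted log-likelihood of a variance-component vector
#'
#' Evaluates `-1/2 [log|V| + log|X'V^{-1}X| + y'Py + (N - p) log(2 pi)]`
#' with `V = sum_k Z K_k Z' sigma2_k + I sigma2_e` and `P` the REML
#' projection. The `(N - p) log(2 pi)` constant matches the convention of
#' `lme4` and most REML software, so likelihood differences (LRT, AIC) are
#' convention-free.
#'
#' @param design A [build_design()] bundle.
#' @param components Named non-negative vector: one entry per kernel in the
#'   design plus `"residual"` (which must be positive).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(design, components) {
  stopifnot(inherits(design, "gblup_design"))
  needed <- c(names(design$kernels), "residual")
  if (!all(needed %in% names(components)))
    stop("components must be named: ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (any(components[needed] < 0) || components[["residual"]] <= 0)
    stop("variance components must be >= 0 with residual > 0",
         call. = FALSE)
  ev <- .reml_eval(design, as.list(components[needed]))
  if (is.null(ev)) {
    # jitter retry once on factorization failure, then fail
    comps <- as.list(components[needed])
    comps[["residual"]] <- comps[["residual"]] * (1 + 1e-6) + 1e-10
    ev <- .reml_eval(design, comps)
    if (is.null(ev))
      stop("covariance matrix factorization failed", call. = FALSE)
  }
  ev$ll
}

#' Fit a multi-kernel mixed model by average-information REML
#'
#' Maximizes the restricted likelihood over the non-negative orthant using
#' average-information updates with step halving, an expectation-
#' maximization fallback when the AI system is not usable, and active-set
#' pinning of components that hit the zero boundary (a boundary estimate,
#' e.g. a dominance variance of exactly zero, is legitimate and is
#' flagged). At the optimum, fixed and random solutions and per-individual
#' prediction error variances (PEV) are recovered from kernel-side
#' identities equivalent to the inverse mixed-model-equation blocks:
#' `PEV_k = sigma2_k K_k - sigma2_k^2 K_k Z'PZ K_k`, with cross-covariances
#' between genetic terms included in the PEV of their sum.
#'
#' @param design A [build_design()] bundle.
#' @param init Optional named starting values (as in
#'   [restricted_loglik()]); defaults split the phenotypic variance evenly
#'   between the residual and the genetic terms.
#' @param max_iter Maximum AI iterations.
#' @param tol_ll Relative log-likelihood convergence tolerance.
#' @param tol_par Relative parameter-change convergence tolerance.
#' @param verbose Print the iteration trace.
#' @return An object of class `reml_fit`: `variance_components`, `loglik`,
#'   `fixed_effects`, `random_solutions` (one named vector per term, over
#'   all kernel individuals), `pev` (per term), `pev_genetic`
#'   (per-individual PEV of the summed genetic value), `converged`,
#'   `boundary`, `n_iter`, `n_records`, `rank_X`, and the `design`.
#' @export
reml_fit <- function(design, init = NULL, max_iter = 100,
                     tol_ll = 1e-8, tol_par = 1e-6, verbose = FALSE) {
  stopifnot(inherits(design, "gblup_design"))
  terms <- names(design$kernels)
  npar <- length(terms) + 1L
  vy <- stats::var(design$y)
  if (!is.finite(vy) || vy <= 0)
    stop("phenotype variance is zero; nothing to decompose", call. = FALSE)
  floor_k <- 1e-8 * vy
  floor_e <- 1e-6 * vy
  comps <- if (is.null(init)) {
    stats::setNames(c(rep(0.5 * vy / length(terms), length(terms)),
                      0.5 * vy), c(terms, "residual"))
  } else {
    stopifnot(all(c(terms, "residual") %in% names(init)))
    pmax(init[c(terms, "residual")], c(rep(floor_k, length(terms)),
                                       floor_e))
  }
  lower <- stats::setNames(c(rep(floor_k, length(terms)), floor_e),
                           c(terms, "residual"))
  pinned <- rep(FALSE, npar)
  ev <- .reml_eval(design, as.list(comps), want_ai = TRUE)
  if (is.null(ev)) stop("REML: initial likelihood evaluation failed",
                        call. = FALSE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # release pinned components whose score points inward
    pinned <- pinned & (ev$score <= 0)
    free <- which(!pinned)
    delta <- rep(0, npar)
    ai_ok <- FALSE
    if (length(free) > 0) {
      sol <- tryCatch(solve(ev$AI[free, free, drop = FALSE],
                            ev$score[free]),
                      error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        delta[free] <- sol
        ai_ok <- TRUE
      }
    }
    if (!ai_ok) {
      # EM-style fallback: guaranteed uphill for small enough step
      qk <- length(design$ids)
      for (i in seq_along(terms))
        delta[i] <- comps[i]^2 * 2 * ev$score[i] / qk
      delta[npar] <- comps[npar]^2 * 2 * ev$score[npar] / design$n_records
      delta[pinned] <- 0
    }
    step <- 1
    accepted <- FALSE
    for (h in 1:30) {
      cand <- comps + step * delta
      at_floor <- cand < lower
      cand[at_floor] <- lower[at_floor]
      ev_new <- .reml_eval(design, as.list(cand), want_ai = TRUE)
      if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break  # no uphill step found: treat as converged
    pinned <- pinned | (cand <= lower * (1 + 1e-12) & delta < 0) |
      (cand <= lower * (1 + 1e-12) & pinned)
    pinned[npar] <- FALSE  # residual never pinned
    rel_par <- max(abs(cand - comps) / (abs(comps) + 1e-10 * vy))
    rel_ll <- abs(ev_new$ll - ev$ll) / (1 + abs(ev$ll))
    comps <- cand
    ev <- ev_new
    if (verbose)
      message(sprintf("iter %2d  ll %.6f  [%s]", iter, ev$ll,
                      paste(sprintf("%.4g", comps), collapse = ", ")))
    if (rel_ll < tol_ll && rel_par < tol_par) {
      converged <- TRUE
      break
    }
  }
  boundary <- comps[seq_along(terms)] <= lower[seq_along(terms)] * (1 + 1e-6)
  # snap boundary genetic components to exact zero and refresh solutions
  if (any(boundary)) {
    comps[seq_along(terms)][boundary] <- 0
    ev <- .reml_eval(design, as.list(comps), want_ai = TRUE)
  }
  .finalize_fit(design, comps, ev, converged, iter, boundary)
}

.finalize_fit <- function(design, comps, ev, converged, iter, boundary) {
  terms <- names(design$kernels)
  q <- length(design$ids)
  ZtPZ <- ev$ZtViZ - ev$ZtViX %*% ev$XtViX_inv %*% t(ev$ZtViX)
  u <- pev <- stats::setNames(vector("list", length(terms)), terms)
  for (k in terms) {
    K <- design$kernels[[k]]
    s <- comps[[k]]
    u[[k]] <- stats::setNames(s * drop(K %*% ev$v), design$ids)
    KZtPZ <- K %*% ZtPZ
    pev[[k]] <- stats::setNames(
      pmax(s * diag(K) - s^2 * rowSums(KZtPZ * K), 0), design$ids)
  }
  # PEV of the summed genetic value (cross-covariances included)
  pev_gen <- Reduce(`+`, pev)
  if (length(terms) > 1) {
    for (i in seq_along(terms)[-length(terms)])
      for (j in (i + 1):length(terms)) {
        Ki <- design$kernels[[terms[i]]]
        Kj <- design$kernels[[terms[j]]]
        cross <- -comps[[terms[i]]] * comps[[terms[j]]] *
          rowSums((Ki %*% ZtPZ) * Kj)
        pev_gen <- pev_gen + 2 * cross
      }
    pev_gen <- pmax(pev_gen, 0)
  }
  structure(list(
    variance_components = stats::setNames(as.numeric(comps),
                                          names(comps)),
    loglik = ev$ll,
    fixed_effects = stats::setNames(ev$beta, colnames(design$X)),
    random_solutions = u,
    pev = pev,
    pev_genetic = pev_gen,
    converged = converged,
    boundary = boundary,
    n_iter = iter,
    n_records = design$n_records,
    rank_X = design$rank_X,
    design = design),
    class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit: trait '%s', %d records, %d individuals, %s\n",
              x$design$trait, x$n_records, length(x$design$ids),
              if (x$converged) sprintf("converged in %d iterations",
                                       x$n_iter)
              else "NOT converged"))
  cat("Variance components:\n")
  print(round(x$variance_components, 6))
  if (any(x$boundary))
    cat("Boundary estimate(s):",
        paste(names(which(x$boundary)), collapse = ", "), "\n")
  cat(sprintf("Restricted log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Total genetic prediction per individual
#'
#' Sum of the random solutions of all genetic terms: the breeding value for
#' additive-only models, `g + d` for the additive-dominance model.
#'
#' @param fit A [reml_fit()] object.
#' @return Named numeric vector over all kernel individuals.
#' @export
genetic_values <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  Reduce(`+`, fit$random_solutions)
}

#' Scalar prediction error variance of the genetic value
#'
#' The per-trait PEV reported alongside accuracy: the mean over individuals
#' of the per-individual PEV of the total genetic effect (for the
#' additive-dominance model this is the PEV of `g + d`, cross-covariances
#' included).
#'
#' @param fit A [reml_fit()] object.
#' @return Scalar mean PEV.
#' @export
pev_scalar <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  mean(fit$pev_genetic)
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = 2k - 2 LL` and `BIC = -2 LL + k log(v)` with `k` the number of
#' fixed-effect parameters (year levels under the cell-means
#' parameterization; variance components are not counted) and `v` the
#' residual degrees of freedom `n_records - rank(X)`. Counting only the
#' fixed effects in `k` is deliberate and non-standard; it is the
#' convention this analysis framework uses for comparing BLUP and GBLUP
#' variants on identical fixed structures.
#'
#' @param x A [reml_fit()] object, or a numeric restricted log-likelihood.
#' @param k Number of fixed-effect parameters (required when `x` is
#'   numeric).
#' @param v Residual degrees of freedom (optional when `x` is numeric; BIC
#'   is `NA` without it).
#' @return Named vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(x, k = NULL, v = NULL) {
  if (inherits(x, "reml_fit")) {
    ll <- x$loglik
    k <- x$rank_X
    v <- x$n_records - x$rank_X
  } else {
    stopifnot(is.numeric(x), length(x) == 1, !is.null(k))
    ll <- x
  }
  c(AIC = 2 * k - 2 * ll,
    BIC = if (is.null(v)) NA_real_ else -2 * ll + k * log(v))
}

#' Likelihood-ratio test for the dominance component
#'
#' Compares nested fits (additive-only vs additive + dominance) on the same
#' data: statistic `2 (LL_AD - LL_A)` clipped at zero. Because the null
#' value of the dominance variance lies on the boundary of the parameter
#' space, the p-value uses the `1/2 chi2_0 + 1/2 chi2_1` mixture:
#' `p = 0.5 P(chi2_1 >= t)`, which equals 0.5 at `t = 0`.
#'
#' @param fit_A Additive-only [reml_fit()].
#' @param fit_AD Additive-dominance [reml_fit()].
#' @return List with `statistic` and `p_value`.
#' @export
lrt_dominance <- function(fit_A, fit_AD) {
  stopifnot(inherits(fit_A, "reml_fit"), inherits(fit_AD, "reml_fit"))
  if (fit_A$n_records != fit_AD$n_records ||
      fit_A$rank_X != fit_AD$rank_X ||
      length(fit_AD$random_solutions) <= length(fit_A$random_solutions))
    stop("fits are not nested on the same data", call. = FALSE)
  stat <- max(0, 2 * (fit_AD$loglik - fit_A$loglik))
  list(statistic = stat,
       p_value = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
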