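#' Centered additive marker coding
#'
#' Column `j` of `W` is the dosage minus `2 p_j`, i.e. dosages
#' `{2, 1, 0}` map to `{2 - 2p, 1 - 2p, -2p}`. When the frequencies are
#' computed from the same (imputed) matrix, the columns of `W` have mean
#' exactly zero.
#'
#' @param genotypes Complete (imputed) dosage matrix.
#' @param freqs Counted-allele frequencies, one per marker.
#' @return Numeric matrix of the same shape as `genotypes`.
#' @export
build_W <- function(genotypes, freqs) {
  stopifnot(is.matrix(genotypes), length(freqs) == ncol(genotypes))
  if (anyNA(genotypes))
    stop("genotypes must be imputed before building W", call. = FALSE)
  sweep(genotypes, 2, 2 * freqs)
}

#' Dominance genotype-class coding
#'
#' Genotype classes map to `{-2(1-p)^2, 2p(1-p), -2p^2}` for dosages
#' `{2, 1, 0}`. The coding is class-based, not linear in dosage, so
#' fractional (imputed) dosages have no interpolation: missing or
#' fractional cells receive code 0 (the HWE expectation of the centered
#' code) and their count is reported via a message. Build `S` from the
#' pre-imputation matrix.
#'
#' @param genotypes Dosage matrix with entries in `{0, 1, 2}`, possibly
#'   `NA`.
#' @param freqs Counted-allele frequencies, one per marker.
#' @return Numeric matrix of the same shape as `genotypes`.
#' @export
build_S <- function(genotypes, freqs) {
  stopifnot(is.matrix(genotypes), length(freqs) == ncol(genotypes))
  n <- nrow(genotypes)
  p <- matrix(freqs, n, ncol(genotypes), byrow = TRUE)
  S <- matrix(0, n, ncol(genotypes), dimnames = dimnames(genotypes))
  is0 <- !is.na(genotypes) & genotypes == 0
  is1 <- !is.na(genotypes) & genotypes == 1
  is2 <- !is.na(genotypes) & genotypes == 2
  S[is0] <- -2 * p[is0]^2
  S[is1] <- 2 * p[is1] * (1 - p[is1])
  S[is2] <- -2 * (1 - p[is2])^2
  n_zeroed <- sum(!(is0 | is1 | is2))
  if (n_zeroed > 0)
    message(n_zeroed,
            " missing or fractional dosage cell(s) coded 0 in S")
  S
}

#' VanRaden additive genomic relationship matrix
#'
#' `G = W W' / sum(2 p_j (1 - p_j))`. With frequencies estimated from the
#' data, rows of `G` sum to zero and the mean diagonal is close to 1 for an
#' unstructured panel.
#'
#' @param W Centered coding from [build_W()].
#' @param freqs The frequencies used to center `W`.
#' @return Symmetric positive-semidefinite matrix with attribute
#'   `kind = "additive"`.
#' @export
vanraden_G <- function(W, freqs) {
  denom <- sum(2 * freqs * (1 - freqs))
  if (denom <= .Machine$double.eps)
    stop("degenerate panel: sum(2pq) is zero", call. = FALSE)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  attr(G, "kind") <- "additive"
  G
}

#' Vitezica dominance genomic relationship matrix
#'
#' `D = S S' / (4 sum((p_j (1 - p_j))^2))`. Elementwise invariant to which
#' allele is counted.
#'
#' @param S Dominance coding from [build_S()].
#' @param freqs The frequencies used to code `S`.
#' @return Symmetric positive-semidefinite matrix with attribute
#'   `kind = "dominance"`.
#' @export
vitezica_D <- function(S, freqs) {
  denom <- 4 * sum((freqs * (1 - freqs))^2)
  if (denom <= .Machine$double.eps)
    stop("degenerate panel: sum((pq)^2) is zero", call. = FALSE)
  D <- tcrossprod(S) / denom
  D <- (D + t(D)) / 2
  attr(D, "kind") <- "dominance"
  D
}

#' Identity kernel for pedigree-free BLUP
#'
#' With no genealogy and no markers, the kinship matrix degenerates to the
#' identity: individuals are treated as unrelated and information never
#' flows between them.
#'
#' @param ids Individual labels.
#' @return Identity matrix with `ids` as dimnames and attribute
#'   `kind = "identity"`.
#' @export
identity_kernel <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  attr(K, "kind") <- "identity"
  K
}
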