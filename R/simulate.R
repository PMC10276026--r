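#' Simulation configuration for a genomic additive-dominance study
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the juçara palm (*Euterpe edulis*) population that motivates the package:
#' 275 unrelated genotypes, 8,112 post-QC SNPs, fruit-weight-per-bunch-like
#' variance components, and three phenotyping years with year-specific means
#' and incomplete coverage of the population.
#'
#' @param n_individuals Number of genotypes (>= 2).
#' @param n_markers Number of biallelic SNP markers (>= 1).
#' @param allele_freq_range Support of the uniform law for counted-allele
#'   frequencies, a length-2 numeric inside (0, 1). A degenerate range
#'   (`lo == hi`) gives a point mass.
#' @param missing_rate Fraction of genotype calls set missing completely at
#'   random, in `[0, 1)`.
#' @param sigma2_a,sigma2_d,sigma2_e Additive, dominance and residual
#'   variances on the trait scale (units squared); all `>= 0`, `sigma2_e > 0`.
#' @param year_effects Named numeric vector mapping year label to its fixed
#'   additive shift (the year mean for a cell-means model).
#' @param records_per_year Either a single number or a named vector aligned
#'   with `year_effects`. Values in (0, 1] are per-individual inclusion
#'   probabilities; integer values >= 2 are exact subset sizes. Models the
#'   unbalancedness of multi-year field phenotyping.
#' @param trait Trait label stamped on generated phenotype records.
#' @param seed Integer seed; every generator operation derives its stream
#'   from it so a full dataset is bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_markers = 200, seed = 1)
sim_config <- function(n_individuals = 275,
                       n_markers = 8112,
                       allele_freq_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       sigma2_a = 0.39,
                       sigma2_d = 0.62,
                       sigma2_e = 1.27,
                       year_effects = c("2018" = 3.05, "2019" = 3.45,
                                        "2021" = 3.68),
                       records_per_year = 0.8,
                       trait = "trait",
                       seed = 1L) {
  stopifnot(n_individuals >= 2, n_markers >= 1,
            sigma2_a >= 0, sigma2_d >= 0, sigma2_e >= 0,
            missing_rate >= 0, missing_rate < 1,
            length(allele_freq_range) %in% c(1L, 2L),
            length(year_effects) >= 1)
  if (length(allele_freq_range) == 1L)
    allele_freq_range <- rep(allele_freq_range, 2L)
  if (allele_freq_range[1] <= 0 || allele_freq_range[2] >= 1 ||
      allele_freq_range[1] > allele_freq_range[2])
    stop("allele frequency law must have support inside (0, 1)",
         call. = FALSE)
  if (is.null(names(year_effects)))
    stop("year_effects must be named by year label", call. = FALSE)
  if (length(records_per_year) == 1L && is.null(names(records_per_year)))
    records_per_year <- stats::setNames(rep(records_per_year,
                                            length(year_effects)),
                                        names(year_effects))
  if (!all(names(year_effects) %in% names(records_per_year)))
    stop("records_per_year must cover every year in year_effects",
         call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 allele_freq_range = allele_freq_range,
                 missing_rate = missing_rate,
                 sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                 sigma2_e = sigma2_e,
                 year_effects = year_effects,
                 records_per_year = records_per_year,
                 trait = trait,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw counted-allele frequencies for a simulated SNP panel
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `config$n_markers` with entries in the
#'   configured open support; identical across calls with the same seed.
#' @export
draw_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rng <- config$allele_freq_range
  if (rng[1] == rng[2]) rep(rng[1], config$n_markers)
  else stats::runif(config$n_markers, rng[1], rng[2])
}

#' Simulate a dosage matrix under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn per marker as Binomial(2, p_j), then missing calls are
#' inserted completely at random at the configured rate. Call with
#' `missing_rate = 0` in the config to obtain the complete panel underlying
#' a masked one: the dosage stream is drawn before the missingness mask, so
#' both configs agree on every observed cell.
#'
#' @param freqs Counted-allele frequencies in (0, 1), one per marker.
#' @param config A [sim_config()].
#' @return Integer matrix (individuals x markers, entries 0/1/2 or `NA`)
#'   with individual row names and marker column names.
#' @export
simulate_genotypes <- function(freqs, config) {
  stopifnot(inherits(config, "sim_config"),
            length(freqs) == config$n_markers)
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  n <- config$n_individuals
  m <- config$n_markers
  set.seed(config$seed + 1L)
  geno <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
  dim(geno) <- c(n, m)
  dimnames(geno) <- list(sprintf("G%03d", seq_len(n)),
                         sprintf("M%05d", seq_len(m)))
  if (config$missing_rate > 0) {
    mask <- stats::runif(n * m) < config$missing_rate
    geno[mask] <- NA_integer_
  }
  geno
}

#' Simulate marker effects and true genetic values
#'
#' Additive effects are i.i.d. normal with variance
#' `sigma2_a / sum(2 p q)` and act through the centered coding `W`
#' (dosage minus `2p`); dominance effects are i.i.d. normal with variance
#' `sigma2_d / (4 sum((p q)^2))` and act through the genotype-class coding
#' `S`. Because these are exactly the codings of the VanRaden G and
#' Vitezica D kernels (built from the same realized frequencies), the
#' configured variances are the REML estimands on the realized panel, which
#' is what makes parameter recovery a meaningful check.
#'
#' @param genotypes Complete dosage matrix (no missing cells) from
#'   [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return A list of class `sim_truth` with per-individual
#'   `breeding_values` and `dominance_values`, per-marker effect vectors,
#'   the realized frequencies used, and realized sample variances.
#' @export
simulate_effects_and_values <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(genotypes))
  if (anyNA(genotypes))
    stop("genotypes must be complete; simulate with missing_rate = 0 or impute first",
         call. = FALSE)
  p <- colMeans(genotypes) / 2
  q <- 1 - p
  sum2pq <- sum(2 * p * q)
  sumpq2 <- 4 * sum((p * q)^2)
  if (sum2pq <= 0 || sumpq2 <= 0)
    stop("degenerate panel: all markers monomorphic", call. = FALSE)
  set.seed(config$seed + 2L)
  m <- ncol(genotypes)
  alpha <- stats::rnorm(m, 0, sqrt(config$sigma2_a / sum2pq))
  delta <- if (config$sigma2_d > 0)
    stats::rnorm(m, 0, sqrt(config$sigma2_d / sumpq2)) else numeric(m)
  W <- build_W(genotypes, p)
  S <- build_S(genotypes, p)
  g <- drop(W %*% alpha)
  d <- drop(S %*% delta)
  names(g) <- names(d) <- rownames(genotypes)
  structure(list(breeding_values = g,
                 dominance_values = d,
                 marker_additive_effects = alpha,
                 marker_dominance_effects = delta,
                 freqs = p,
                 realized = c(var_g = stats::var(g), var_d = stats::var(d))),
            class = "sim_truth")
}

#' Simulate an unbalanced multi-year phenotype table
#'
#' One record is generated per retained (individual, year) pair:
#' `value = year effect + g_i + d_i + e`, with residuals i.i.d.
#' `N(0, sigma2_e)`. Repeated records of one individual share its genetic
#' values; there is no genotype-by-year interaction or permanent-environment
#' term, mirroring the repeated-records model the package fits.
#'
#' @param truth A `sim_truth` from [simulate_effects_and_values()].
#' @param config A [sim_config()].
#' @return Long-format `data.frame` with columns `genotype_id`, `year`,
#'   `trait`, `value`.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  ids <- names(truth$breeding_values)
  n <- length(ids)
  set.seed(config$seed + 3L)
  recs <- lapply(names(config$year_effects), function(yr) {
    rule <- config$records_per_year[[yr]]
    keep <- if (rule <= 1) which(stats::runif(n) < rule)
            else sample.int(n, min(as.integer(rule), n))
    if (length(keep) == 0L) return(NULL)
    data.frame(genotype_id = ids[keep], year = yr,
               trait = config$trait,
               value = config$year_effects[[yr]] +
                 truth$breeding_values[keep] + truth$dominance_values[keep] +
                 stats::rnorm(length(keep), 0, sqrt(config$sigma2_e)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out) || nrow(out) == 0L)
    stop("empty design: no phenotype records generated", call. = FALSE)
  out
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running the full generator: frequencies, complete
#' genotypes, true effects and values, the observed (masked) genotype
#' matrix, and the phenotype table.
#'
#' @param config A [sim_config()].
#' @return List with elements `genotypes` (observed, possibly with missing
#'   cells), `genotypes_complete`, `freqs`, `truth`, `phenotypes`.
#' @export
#' @examples
#' dat <- simulate_dataset(sim_config(n_individuals = 40, n_markers = 100,
#'                                    seed = 7))
#' str(dat$phenotypes)
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- draw_allele_frequencies(config)
  cfg_complete <- config
  cfg_complete$missing_rate <- 0
  complete <- simulate_genotypes(freqs, cfg_complete)
  observed <- simulate_genotypes(freqs, config)
  truth <- simulate_effects_and_values(complete, config)
  phen <- simulate_phenotypes(truth, config)
  list(genotypes = observed, genotypes_complete = complete,
       freqs = freqs, truth = truth, phenotypes = phen)
}
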