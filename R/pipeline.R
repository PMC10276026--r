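#' Derive composite pulp traits from fruit and seed weights
#'
#' For each (genotype, year) pair holding both the fruit-sample weight
#' (`WF`, weight of 25 fruits) and the seed-sample weight (`WS`, weight of
#' 25 seeds), appends the amount of pulp `AP = WF - WS` and the pulp yield
#' `PY = AP / WF * 100` (percent). Negative pulp amounts are kept but
#' flagged with a warning (they indicate a data error); records with
#' `WF = 0` cannot yield a `PY` and are skipped with a message.
#'
#' @param phenotypes Long-format phenotype table.
#' @param wf,ws Trait labels of the fruit and seed weights.
#' @return The phenotype table with `AP` and `PY` records appended.
#' @export
#' @examples
#' ph <- data.frame(genotype_id = "G1", year = "2018",
#'                  trait = c("WF", "WS"), value = c(40, 30))
#' derive_traits(ph)
derive_traits <- function(phenotypes, wf = "WF", ws = "WS") {
  wf_rec <- phenotypes[phenotypes$trait == wf, c("genotype_id", "year",
                                                 "value")]
  ws_rec <- phenotypes[phenotypes$trait == ws, c("genotype_id", "year",
                                                 "value")]
  if (nrow(wf_rec) == 0L || nrow(ws_rec) == 0L) return(phenotypes)
  names(wf_rec)[3] <- "wf"
  names(ws_rec)[3] <- "ws"
  pair <- merge(wf_rec, ws_rec, by = c("genotype_id", "year"))
  if (nrow(pair) == 0L) return(phenotypes)
  ap <- pair$wf - pair$ws
  if (any(ap < 0))
    warning(sum(ap < 0), " record(s) with negative pulp amount (WS > WF)")
  ap_rec <- data.frame(genotype_id = pair$genotype_id, year = pair$year,
                       trait = "AP", value = ap,
                       stringsAsFactors = FALSE)
  ok <- pair$wf != 0
  if (any(!ok))
    message(sum(!ok), " record(s) skipped for PY (WF = 0)")
  py_rec <- data.frame(genotype_id = pair$genotype_id[ok],
                       year = pair$year[ok],
                       trait = rep("PY", sum(ok)),
                       value = 100 * ap[ok] / pair$wf[ok],
                       stringsAsFactors = FALSE)
  rbind(phenotypes[, c("genotype_id", "year", "trait", "value")],
        ap_rec, py_rec)
}

#' Run the full additive-dominance genomic analysis
#'
#' Per trait: marker QC, mean imputation, VanRaden G and Vitezica D
#' construction, REML fits of the requested models (`BLUP` with the
#' identity kernel, `GBLUP-A` with G, `GBLUP-AD` with G + D), genetic
#' parameters and fit criteria, the boundary-corrected likelihood-ratio
#' test for dominance, and k-fold cross-validated predictive ability. A
#' failure in one trait is recorded and the remaining traits are still
#' analysed.
#'
#' @param genotypes Dosage matrix or path to a genotype file.
#' @param phenotypes Long-format phenotype table or path to its CSV.
#' @param traits Traits to analyse; defaults to all traits present.
#' @param models Subset of `c("BLUP", "GBLUP-A", "GBLUP-AD")`.
#' @param call_rate_min,maf_min QC thresholds (see [qc_filter()]).
#' @param cv_k Folds for cross-validation; `0` skips CV.
#' @param seed Seed for the CV fold partitions.
#' @param genotype_dialect Dialect for a genotype path (see
#'   [read_genotypes()]).
#' @param outdir Optional directory; when given, the report tables are
#'   written as CSV (`qc_report.csv`, `components_table.csv`,
#'   `dominance_ratios.csv`, `fit_criteria.csv`, `cv_results.csv`,
#'   `manifest.csv`).
#' @param ... Passed to [reml_fit()].
#' @return List of class `gblup_analysis`: `components` (per trait x model
#'   variance components and heritabilities), `dominance_ratios`,
#'   `fit_criteria` (PEV, r, LL, AIC, BIC), `lrt`, `cv`, `qc_report`,
#'   `errors`, `manifest`.
#' @export
run_analysis <- function(genotypes, phenotypes, traits = NULL,
                         models = c("BLUP", "GBLUP-A", "GBLUP-AD"),
                         call_rate_min = 0.90, maf_min = 0.05,
                         cv_k = 5, seed = 1,
                         genotype_dialect = "csv", outdir = NULL, ...) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.character(genotypes))
    genotypes <- read_genotypes(genotypes, dialect = genotype_dialect)
  if (is.character(phenotypes))
    phenotypes <- utils::read.csv(phenotypes, stringsAsFactors = FALSE,
                                  colClasses = c(year = "character"))
  phenotypes$year <- as.character(phenotypes$year)
  if (is.null(traits)) traits <- unique(phenotypes$trait)

  qc <- qc_filter(genotypes, call_rate_min, maf_min)
  freqs <- allele_frequency(qc$genotypes)
  imputed <- impute_missing(qc$genotypes, freqs)
  ids <- rownames(imputed)
  W <- build_W(imputed, freqs)
  G <- vanraden_G(W, freqs)
  S <- build_S(qc$genotypes, freqs)  # pre-imputation: class-based coding
  D <- vitezica_D(S, freqs)
  I_K <- identity_kernel(ids)
  model_kernels <- list(
    "BLUP" = list(genetic = I_K),
    "GBLUP-A" = list(additive = G),
    "GBLUP-AD" = list(additive = G, dominance = D))

  comp_rows <- crit_rows <- lrt_rows <- cv_rows <- ratio_rows <- list()
  errors <- list()
  for (tr in traits) {
    res <- tryCatch({
      fits <- list()
      for (mod in models) {
        design <- build_design(phenotypes, tr, model_kernels[[mod]])
        fits[[mod]] <- reml_fit(design, ...)
      }
      for (mod in models) {
        fit <- fits[[mod]]
        gp <- genetic_params(fit)
        ic <- information_criteria(fit)
        comp_rows[[paste(tr, mod)]] <- data.frame(
          trait = tr, model = mod,
          sigma2_a = gp[["sigma2_a"]],
          sigma2_d = if (mod == "GBLUP-AD") gp[["sigma2_d"]] else NA_real_,
          sigma2_e = gp[["sigma2_e"]],
          h2 = gp[["h2"]],
          H2 = if (mod == "GBLUP-AD") gp[["H2"]] else NA_real_,
          converged = fit$converged, stringsAsFactors = FALSE)
        crit_rows[[paste(tr, mod)]] <- data.frame(
          trait = tr, model = mod,
          PEV = gp[["PEV"]], r = gp[["r"]], LL = fit$loglik,
          AIC = ic[["AIC"]], BIC = ic[["BIC"]],
          stringsAsFactors = FALSE)
      }
      if (all(c("GBLUP-A", "GBLUP-AD") %in% models)) {
        dr <- dominance_ratios(fits[["GBLUP-AD"]], fits[["GBLUP-A"]])
        ratio_rows[[tr]] <- data.frame(trait = tr, d2 = dr[["d2"]],
                                        rl_aa = dr[["rl_aa"]],
                                        stringsAsFactors = FALSE)
        lt <- lrt_dominance(fits[["GBLUP-A"]], fits[["GBLUP-AD"]])
        lrt_rows[[tr]] <- data.frame(trait = tr,
                                      statistic = lt$statistic,
                                      p_value = lt$p_value,
                                      stringsAsFactors = FALSE)
      }
      if (cv_k >= 2) {
        for (mod in models) {
          cv <- cross_validate(phenotypes, tr, model_kernels[[mod]],
                               k = cv_k, seed = seed, ...)
          cv_rows[[paste(tr, mod)]] <- data.frame(
            trait = tr, model = mod, fold = cv$per_fold$fold,
            r = cv$per_fold$r, mean_r = cv$mean_r, se_r = cv$se_r,
            stringsAsFactors = FALSE)
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[tr]] <- res
  }

  out <- structure(list(
    components = .bind_rows(comp_rows),
    dominance_ratios = .bind_rows(ratio_rows),
    fit_criteria = .bind_rows(crit_rows),
    lrt = .bind_rows(lrt_rows),
    cv = .bind_rows(cv_rows),
    qc_report = qc$report,
    errors = errors,
    manifest = data.frame(
      key = c("n_individuals", "n_markers_in", "n_markers_out",
              "call_rate_min", "maf_min", "cv_k", "seed", "version"),
      value = c(length(ids), qc$report$n_markers_in,
                qc$report$n_markers_out, call_rate_min, maf_min, cv_k,
                seed, as.character(utils::packageVersion("gblupad"))),
      stringsAsFactors = FALSE)),
    class = "gblup_analysis")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(qc$report$markers,
                     file.path(outdir, "qc_report.csv"), row.names = FALSE)
    for (nm in c("components", "dominance_ratios", "fit_criteria", "lrt",
                 "cv", "manifest")) {
      tab <- if (nm == "components") out$components else out[[nm]]
      if (!is.null(tab) && nrow(tab) > 0)
        utils::write.csv(tab, file.path(outdir, paste0(
          switch(nm, components = "components_table", cv = "cv_results",
                 nm), ".csv")),
          row.names = FALSE)
    }
  }
  out
}

.bind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gblup_analysis <- function(x, ...) {
  cat("Additive-dominance genomic analysis\n")
  print(x$qc_report)
  if (!is.null(x$components)) {
    cat("\nVariance components and heritabilities:\n")
    tab <- x$components
    tab[] <- lapply(tab, function(col)
      if (is.numeric(col)) round(col, 2) else col)
    print(tab, row.names = FALSE)
  }
  if (length(x$errors) > 0) {
    cat("\nTraits with errors:\n")
    for (tr in names(x$errors)) cat("  ", tr, ": ", x$errors[[tr]], "\n")
  }
  invisible(x)
}
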