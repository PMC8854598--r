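#' Additive-dosage genetic association for a synthetic instrument
#'
#' Least-squares (continuous phenotype) or logistic (binary outcome)
#' regression of the phenotype on genotype dosage under a frequentist
#' additive model, adjusted for covariates.  Continuous phenotypes are
#' expected already standardized (beta is per allele in phenotype SD
#' units); binary outcomes give per-allele log-odds.
#'
#' @param data Subject-level data frame.
#' @param dosage Dosage column (values in `[0, 2]`).
#' @param phenotype Phenotype column.
#' @param covariates Adjustment columns (e.g. age, sex).
#' @param snp SNP identifier for the output row.
#' @param effect_allele,other_allele Allele labels attached to the output
#'   (the dosage counts `effect_allele` copies).
#' @param family `"gaussian"` or `"binomial"`.
#' @return One-row tibble: snp, effect_allele, other_allele, beta, se, p,
#'   n, eaf.
#' @export
snp_association <- function(data, dosage = "dosage", phenotype,
                            covariates = character(), snp = "rs0000001",
                            effect_allele = "A", other_allele = "G",
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  assert_columns(data, c(dosage, phenotype, covariates), "data")
  keep <- stats::complete.cases(data[, c(dosage, phenotype, covariates)])
  d0 <- data[keep, , drop = FALSE]
  n <- nrow(d0)
  if (n <= length(covariates) + 2) abort("too few observations")
  g <- d0[[dosage]]
  if (stats::var(g) == 0) abort("monomorphic SNP: dosage has no variation")
  eaf <- mean(g) / 2
  maf <- min(eaf, 1 - eaf)
  if (maf < 0.05) {
    abort(paste0("minor allele frequency ", format(maf, digits = 3),
                 " outside [0.05, 0.5]"))
  }
  covs <- c(dosage, covariates)
  d <- stats::setNames(as.data.frame(d0[, c(phenotype, covs), drop = FALSE]),
                       c(".y", paste0(".x", seq_along(covs))))
  fml <- stats::as.formula(paste(
    ".y ~", paste(paste0(".x", seq_along(covs)), collapse = " + ")))
  if (family == "gaussian") {
    fit <- stats::lm(fml, data = d)
    cf <- summary(fit)$coefficients[".x1", ]
    p <- 2 * stats::pt(-abs(cf["t value"]), df = fit$df.residual)
  } else {
    fit <- stats::glm(fml, data = d, family = stats::binomial())
    cf <- summary(fit)$coefficients[".x1", ]
    p <- 2 * pnorm(-abs(cf["z value"]))
  }
  tibble(snp = snp, effect_allele = effect_allele,
         other_allele = other_allele,
         beta = unname(cf["Estimate"]), se = unname(cf["Std. Error"]),
         p = unname(p), n = n, eaf = eaf)
}

#' Select the instrument SNP for Mendelian randomization
#'
#' Among associations significant below `threshold` and present in the
#' external `availability` set, returns the one with the smallest p-value
#' (ties broken lexically by SNP id).  The strongest overall signal is thus
#' skipped when it cannot be replicated externally.
#'
#' @param associations Tibble of [snp_association()]-style rows.
#' @param threshold Suggestive significance threshold (default 1e-5).
#' @param availability SNP ids available in the external datasets
#'   (NULL = all).
#' @return One-row tibble, or a zero-row tibble with attribute `reason`
#'   when nothing qualifies.
#' @export
select_instrument <- function(associations, threshold = 1e-5,
                              availability = NULL) {
  if (!nrow(associations)) abort("`associations` is empty")
  qual <- dplyr::filter(associations, .data$p < threshold)
  if (!is.null(availability)) {
    qual <- dplyr::filter(qual, .data$snp %in% availability)
  }
  if (!nrow(qual)) {
    out <- associations[0, , drop = FALSE]
    attr(out, "reason") <- paste0(
      "no SNP with p < ", format(threshold),
      if (!is.null(availability)) " among the externally available set")
    return(out)
  }
  dplyr::slice(dplyr::arrange(qual, .data$p, .data$snp), 1)
}

#' Harmonize exposure and outcome summary statistics for one SNP
#'
#' Aligns the outcome association to the exposure's effect allele: when the
#' outcome's effect allele equals the exposure's other allele, the outcome
#' beta is negated.  Incompatible allele pairs are rejected; palindromic
#' pairs (A/T, C/G), whose strand cannot be resolved from the alleles
#' alone, are flagged.
#'
#' @param exposure,outcome One-row tibbles with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`.
#' @return One-row tibble: snp, effect_allele, other_allele,
#'   beta_exposure, se_exposure, beta_outcome, se_outcome, palindromic.
#' @export
harmonize_sumstats <- function(exposure, outcome) {
  stopifnot(nrow(exposure) == 1, nrow(outcome) == 1)
  if (exposure$snp != outcome$snp) {
    abort("exposure and outcome rows refer to different SNPs")
  }
  ea <- toupper(exposure$effect_allele); oa <- toupper(exposure$other_allele)
  ea_o <- toupper(outcome$effect_allele); oa_o <- toupper(outcome$other_allele)
  if (!setequal(c(ea, oa), c(ea_o, oa_o))) {
    abort(paste0("incompatible allele pairs for ", exposure$snp, ": ",
                 ea, "/", oa, " vs ", ea_o, "/", oa_o))
  }
  flip <- ea_o == oa
  beta_o <- if (flip) -outcome$beta else outcome$beta
  palindromic <- setequal(c(ea, oa), c("A", "T")) ||
    setequal(c(ea, oa), c("C", "G"))
  if (palindromic) {
    warn(paste0(exposure$snp,
                " has a palindromic allele pair; strand unresolved"))
  }
  tibble(snp = exposure$snp, effect_allele = ea, other_allele = oa,
         beta_exposure = exposure$beta, se_exposure = exposure$se,
         beta_outcome = beta_o, se_outcome = outcome$se,
         palindromic = palindromic)
}

#' Wald-ratio Mendelian randomization estimate
#'
#' WR = beta_outcome / beta_exposure on the harmonized pair, with the
#' first-order standard error SE = se_outcome / |beta_exposure| (exposure
#' uncertainty ignored) and a two-sided normal p-value.  A second-order SE
#' additionally propagating the exposure SE is available behind
#' `second_order`.
#'
#' @param pair Harmonized one-row tibble from [harmonize_sumstats()].
#' @param second_order Use the second-order SE (default FALSE).
#' @return One-row tibble: snp, wr, se, p, method.
#' @export
#' @examples
#' pair <- tibble::tibble(snp = "rs1", beta_exposure = 0.4, se_exposure = 0.05,
#'                        beta_outcome = 0.2, se_outcome = 0.01)
#' wald_ratio(pair)   # WR 0.5, SE 0.025
wald_ratio <- function(pair, second_order = FALSE) {
  stopifnot(nrow(pair) == 1)
  be <- pair$beta_exposure
  if (!is.finite(be) || be == 0) {
    abort("exposure beta is zero; Wald ratio undefined (weak instrument)")
  }
  wr <- pair$beta_outcome / be
  se <- if (second_order) {
    sqrt(pair$se_outcome^2 / be^2 +
           pair$beta_outcome^2 * pair$se_exposure^2 / be^4)
  } else {
    pair$se_outcome / abs(be)
  }
  tibble(snp = pair$snp, wr = wr, se = se,
         p = 2 * pnorm(-abs(wr / se)),
         method = if (second_order) "wald_second_order" else "wald_first_order")
}

#' Read / write GWAS summary statistics as tab-separated text
#'
#' Header columns: snp, effect_allele, other_allele, beta, se, p, n (extra
#' columns pass through).  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_sumstats
#' @param x Summary-statistics tibble.
#' @export
write_sumstats <- function(x, path) {
  write_tsv_plain(x, path)
}
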