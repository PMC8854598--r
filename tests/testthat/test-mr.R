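test_that("Wald ratio arithmetic and guards", {
  pair <- tibble::tibble(snp = "rs1", beta_exposure = 0.4, se_exposure = 0.05,
                         beta_outcome = 0.2, se_outcome = 0.01)
  res <- wald_ratio(pair)
  expect_equal(res$wr, 0.5)
  expect_equal(res$se, 0.025)
  expect_equal(res$p, 2 * pnorm(-0.5 / 0.025))

  pair2 <- dplyr::mutate(pair, beta_exposure = 0.5)
  expect_equal(wald_ratio(pair2)$se, 0.02)
  # second-order SE additionally carries the exposure uncertainty
  expect_gt(wald_ratio(pair2, second_order = TRUE)$se,
            wald_ratio(pair2)$se)

  expect_error(wald_ratio(dplyr::mutate(pair, beta_exposure = 0)),
               "weak")
})

test_that("harmonization aligns effect alleles and flags palindromes", {
  ex <- tibble::tibble(snp = "rs1", effect_allele = "A", other_allele = "G",
                       beta = -0.201, se = 0.039)
  same <- tibble::tibble(snp = "rs1", effect_allele = "A", other_allele = "G",
                         beta = 0.014, se = 0.006)
  expect_equal(harmonize_sumstats(ex, same)$beta_outcome, 0.014)

  flipped <- dplyr::mutate(same, effect_allele = "G", other_allele = "A")
  expect_equal(harmonize_sumstats(ex, flipped)$beta_outcome, -0.014)

  # joint allele recode of both studies leaves the Wald ratio unchanged
  wr1 <- wald_ratio(harmonize_sumstats(ex, flipped))
  ex2 <- dplyr::mutate(ex, effect_allele = "G", other_allele = "A",
                       beta = -beta)
  wr2 <- wald_ratio(harmonize_sumstats(ex2, flipped))
  expect_equal(wr1$wr, wr2$wr, tolerance = 1e-12)

  bad <- dplyr::mutate(same, effect_allele = "T", other_allele = "C")
  expect_error(harmonize_sumstats(ex, bad), "incompatible")

  pal_ex <- dplyr::mutate(ex, effect_allele = "A", other_allele = "T")
  pal_out <- dplyr::mutate(same, effect_allele = "A", other_allele = "T")
  expect_warning(h <- harmonize_sumstats(pal_ex, pal_out), "palindromic")
  expect_true(h$palindromic)
})

test_that("instrument selection honours the availability constraint", {
  epic <- read_sumstats(system.file("extdata", "cer22_exposure_epic.tsv",
                                    package = "lipidnet"))
  avail <- readr::read_tsv(system.file("extdata", "cer22_availability.tsv",
                                       package = "lipidnet"),
                           comment = "#", show_col_types = FALSE)$snp
  # unconstrained: the overall strongest signal
  expect_equal(select_instrument(epic)$snp, "rs686548")
  # constrained: the strongest externally available signal
  expect_equal(select_instrument(epic, availability = avail)$snp, "rs680379")
  # nothing qualifies
  none <- select_instrument(epic, threshold = 1e-20)
  expect_equal(nrow(none), 0)
  expect_match(attr(none, "reason"), "no SNP")
  expect_error(select_instrument(epic[0, ]), "empty")
})

test_that("instrument selection breaks p-value ties lexically", {
  tied <- tibble::tibble(snp = c("rs9", "rs1"), effect_allele = "A",
                         other_allele = "G", beta = c(0.2, 0.2),
                         se = 0.02, p = c(1e-8, 1e-8), n = 1000)
  expect_equal(select_instrument(tied)$snp, "rs1")
})

test_that("additive dosage regression recovers the generator's effect", {
  truth <- quiet_truth(2, 2,
                       instrument = list(snp = "rs1", maf = 0.3, beta = 0.2,
                                         target = "Cer16:0"))
  cohort <- simulate_cohort(truth, 20000, seed = 91)
  panel <- log_z_transform(cohort, cols = "Cer16:0")
  assoc <- snp_association(panel, "dosage", "Cer16:0",
                           covariates = c("entry_age", "sex"), snp = "rs1")
  # standardization rescales the per-allele effect by the implied SD
  expected <- 0.2 / sqrt(implied_covariance(truth)["Cer16:0", "Cer16:0"])
  expect_lt(abs(assoc$beta - expected), 3 * assoc$se)
  expect_lt(abs(assoc$eaf - 0.3), 0.02)

  # recoding the dosage to the other allele exactly negates the effect
  flipped <- dplyr::mutate(panel, dosage = 2 - dosage)
  assoc2 <- snp_association(flipped, "dosage", "Cer16:0",
                            covariates = c("entry_age", "sex"), snp = "rs1",
                            effect_allele = "G", other_allele = "A")
  expect_equal(assoc2$beta, -assoc$beta, tolerance = 1e-10)
  expect_equal(assoc2$se, assoc$se, tolerance = 1e-10)

  mono <- dplyr::mutate(panel, dosage = 0)
  expect_error(snp_association(mono, "dosage", "Cer16:0"), "monomorphic")
  rare <- dplyr::mutate(panel, dosage = c(rep(1, 50), rep(0, nrow(panel) - 50)))
  expect_error(snp_association(rare, "dosage", "Cer16:0"), "0.05")
})

test_that("a null phenotype gives null association", {
  set.seed(92)
  d <- tibble::tibble(dosage = rbinom(5000, 2, 0.3), y = rnorm(5000))
  assoc <- snp_association(d, "dosage", "y")
  expect_lt(abs(assoc$beta), 3 * assoc$se)
})

test_that("summary statistics round-trip through the TSV interface", {
  x <- tibble::tibble(snp = "rs1", effect_allele = "A", other_allele = "G",
                      beta = -0.201, se = 0.039, p = 2.3e-7, n = 1094)
  path <- file.path(withr::local_tempdir(), "ss.tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-12)
})

test_that("the worked example reproduces the anchor cohort's published ratio", {
  ex <- mr_worked_example()
  expect_equal(nrow(ex), 3)
  anchor <- dplyr::filter(ex, cohort == "EUROSPAN")
  expect_equal(anchor$wr, 0.259, tolerance = 1e-12)
  expect_equal(anchor$se, 0.120, tolerance = 1e-12)
  # one common SNP-outcome effect: identical z and p across cohorts
  expect_equal(ex$p, rep(ex$p[1], 3), tolerance = 1e-12)
})
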