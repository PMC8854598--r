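test_that("proportion explainable follows its defining arithmetic", {
  expect_equal(proportion_explainable(0.3, 0.3)$pe, 0)
  expect_equal(proportion_explainable(0.3, 0)$pe, 100)
  # total HR 1.31 with adjusted log-HR 0.1026: 62% attenuation
  expect_equal(proportion_explainable(log(1.31), 0.1026)$pe, 62.0,
               tolerance = 0.02)
  # amplification and over-explanation are reported untruncated
  expect_lt(proportion_explainable(0.3, 0.4)$pe, 0)
  expect_gt(proportion_explainable(0.3, -0.05)$pe, 100)
  expect_error(proportion_explainable(0.005, 0.001), "floor")
})

test_that("the delta-method SE matches its closed form in the zero-adjusted case", {
  r <- proportion_explainable(0.5, 0, se_total = 0.1, se_adjusted = 0.08)
  # with la = 0 the gradient in lt vanishes: SE = 100 * se_adj / |lt|
  expect_equal(r$se, 100 * 0.08 / 0.5, tolerance = 1e-10)
  expect_true(is.na(proportion_explainable(0.5, 0.2)$se))
})

test_that("mediator selection applies the one-sided direction rule", {
  set.seed(71)
  n <- 3000
  E <- rnorm(n)
  d <- tibble::tibble(
    subject_id = as.character(1:n),
    entry_age = runif(n, 35, 65),
    red_meat = E,
    sex = rbinom(n, 1, 0.5),
    Mpos = as.numeric(scale(0.15 * E + rnorm(n))),
    Mnull = rnorm(n))
  d$exit_age <- d$entry_age + rexp(n, 0.1 * exp(0.2 * E))
  d$event <- as.integer(d$exit_age < d$entry_age + 10)
  d$exit_age <- pmin(d$exit_age, d$entry_age + 10)
  d$subcohort_member <- TRUE

  # positive total effect; Mpos raises risk: required sign positive
  sel <- select_mediators(d, "red_meat",
                          candidate_signs = c(Mpos = 1, Mnull = 1),
                          confounders = "sex")
  expect_true(dplyr::filter(sel, metabolite == "Mpos")$selected)
  expect_false(dplyr::filter(sel, metabolite == "Mnull")$selected)

  # flip the candidate's disease sign: direction now inconsistent
  sel2 <- select_mediators(d, "red_meat",
                           candidate_signs = c(Mpos = -1),
                           confounders = "sex")
  expect_false(sel2$selected)
  expect_gt(sel2$one_sided_p, 0.9)

  expect_error(select_mediators(d, "red_meat", c(Mpos = NA)), "no NA")
})

test_that("the bootstrap interval is fully determined by the seed", {
  med <- list(list(exposure = "red_meat", endpoint = "t2d",
                   coefs = c("Cer18:0" = 0.5), direct_log_hr = 0.15))
  truth <- generate_ground_truth(2, 2, effects = c("Cer18:0" = 0.4),
                                 mediation = med, seed = 72)
  panel <- cc_panel(truth, 2000, case_fraction = 0.15, seed = 73)
  ci1 <- pe_bootstrap_ci(panel, "red_meat", "Cer18:0", c("sex", "waist"),
                         B = 100, seed = 74)
  ci2 <- pe_bootstrap_ci(panel, "red_meat", "Cer18:0", c("sex", "waist"),
                         B = 100, seed = 74)
  expect_identical(ci1, ci2)
  ci3 <- pe_bootstrap_ci(panel, "red_meat", "Cer18:0", c("sex", "waist"),
                         B = 100, seed = 75)
  expect_false(identical(ci1$pe_low, ci3$pe_low))
  expect_lte(ci1$pe_high, 100)
  expect_error(pe_bootstrap_ci(panel, "red_meat", "Cer18:0", "sex", B = 50),
               "at least 100")
})

test_that("severed mediator paths give PE near zero on average", {
  med <- list(list(exposure = "red_meat", endpoint = "t2d",
                   coefs = c("Cer18:0" = 0), direct_log_hr = 0.3))
  truth <- quiet_truth(2, 2, effects = c("Cer18:0" = 0.4), mediation = med)
  pes <- vapply(1:12, function(i) {
    panel <- cc_panel(truth, 2500, subcohort_fraction = 1,
                      case_fraction = 0.15, seed = 80 + i)
    tot <- fit_prentice_cox(panel, "red_meat", c("sex", "waist"))
    adj <- fit_prentice_cox(panel, "red_meat", c("Cer18:0", "sex", "waist"))
    proportion_explainable(tot, adj, exposure = "red_meat")$pe
  }, numeric(1))
  expect_lt(abs(mean(pes)), 3 * sd(pes) / sqrt(length(pes)) + 1)
})

test_that("PE is invariant to affine rescaling of the exposure", {
  med <- list(list(exposure = "red_meat", endpoint = "t2d",
                   coefs = c("Cer18:0" = 0.5), direct_log_hr = 0.2))
  truth <- generate_ground_truth(2, 2, effects = c("Cer18:0" = 0.4),
                                 mediation = med, seed = 76)
  panel <- cc_panel(truth, 2000, seed = 77)
  pe_of <- function(p) {
    tot <- fit_prentice_cox(p, "red_meat", c("sex", "waist"))
    adj <- fit_prentice_cox(p, "red_meat", c("Cer18:0", "sex", "waist"))
    proportion_explainable(tot, adj, exposure = "red_meat")$pe
  }
  a <- pe_of(panel)
  panel$red_meat <- 2 * panel$red_meat + 3
  expect_equal(a, pe_of(panel), tolerance = 1e-6)
})

test_that("mediate_pe assembles a coherent per-unit report", {
  med <- list(list(exposure = "red_meat", endpoint = "t2d",
                   coefs = c("Cer18:0" = 0.5), direct_log_hr = 0.15))
  truth <- generate_ground_truth(2, 2, effects = c("Cer18:0" = 0.4),
                                 mediation = med, seed = 78)
  panel <- cc_panel(truth, 2500, seed = 79)
  res <- mediate_pe(panel, "red_meat", "Cer18:0", c("sex", "waist"),
                    B = 100, seed = 80)
  row <- tidy(res)
  expect_equal(row$pe, res$pe)
  expect_lte(row$pe_high, 100)
  expect_gt(row$hr_total, row$hr_adjusted)  # positive mediated share
  # reporting unit defaults to 2 SD of the exposure
  tot_row <- dplyr::filter(res$total$estimates, term == "red_meat")
  expect_equal(row$hr_total,
               unname(exp(2 * sd(panel$red_meat) * tot_row$log_hr)))
})
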