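test_that("elongation-chain topology has the edge count implied by biochemistry", {
  truth <- generate_ground_truth(3, 3, seed = 1)
  # 2 within-class elongation edges per class + 3 desaturation edges
  expect_equal(nrow(truth$edges), 7)
  within_cer <- sum(grepl("^Cer", truth$edges$from) &
                      grepl("^Cer", truth$edges$to))
  within_dh <- sum(grepl("^dhCer", truth$edges$from) &
                     grepl("^dhCer", truth$edges$to))
  cross <- sum(grepl("^dhCer", truth$edges$from) &
                 grepl("^Cer", truth$edges$to))
  expect_equal(c(within_cer, within_dh, cross), c(2, 2, 3))
  expect_equal(length(unique(truth$nodes$metabolite)), 6)
})

test_that("cyclic custom edge requests are rejected, acyclic ones accepted", {
  nodes <- generate_ground_truth(2, 2, seed = 1)$nodes$metabolite
  cyc <- data.frame(from = c(nodes[1], nodes[2]), to = c(nodes[2], nodes[1]),
                    weight = c(0.5, 0.5))
  expect_error(generate_ground_truth(2, 2, topology = "custom", edges = cyc),
               "cyclic")
  ok <- data.frame(from = nodes[1], to = nodes[2], weight = 0.5)
  expect_s3_class(generate_ground_truth(2, 2, topology = "custom", edges = ok),
                  "lipid_truth")
})

test_that("zero edge weights make the metabolites mutually independent", {
  truth <- quiet_truth(3, 3, edge_weight_range = c(0, 0))
  expect_true(all(truth$edges$weight == 0))
  sigma <- implied_covariance(truth)
  expect_equal(sigma[upper.tri(sigma)], rep(0, 15))
  sk <- pc_skeleton(cor = stats::cov2cor(sigma), n = 1e6)
  expect_equal(nrow(sk$edges), 0)
})

test_that("random_sparse topology is reproducible under a fixed seed", {
  t1 <- generate_ground_truth(5, 5, topology = "random_sparse",
                              density = 0.2, seed = 7)
  t2 <- generate_ground_truth(5, 5, topology = "random_sparse",
                              density = 0.2, seed = 7)
  expect_identical(t1$edges, t2$edges)
})

test_that("empirical log-scale covariance matches the closed form at n = 20000", {
  med <- list(list(exposure = "red_meat", endpoint = "t2d",
                   coefs = c("Cer18:0" = 0.4), direct_log_hr = 0.1))
  truth <- generate_ground_truth(
    3, 3, effects = c("Cer18:0" = 0.3), mediation = med,
    instrument = list(snp = "rs1", maf = 0.3, beta = 0.2,
                      target = "dhCer16:0"),
    seed = 11)
  cohort <- simulate_cohort(truth, 20000, seed = 12)
  X <- log(as.matrix(cohort[, truth$nodes$metabolite]))
  emp <- stats::cov(X)
  expect_lt(max(abs(emp - implied_covariance(truth))), 0.12)
})

test_that("instrument dosage and effect size are recovered by regression", {
  truth <- quiet_truth(3, 3,
                       instrument = list(snp = "rs1", maf = 0.3, beta = 0.2,
                                         target = "Cer16:0"))
  cohort <- simulate_cohort(truth, 20000, seed = 5)
  # allele frequency within binomial Monte-Carlo error
  expect_lt(abs(mean(cohort$dosage) / 2 - 0.3),
            3 * sqrt(0.3 * 0.7 / (2 * 20000)))
  # per-allele effect on the log scale, ordinary least squares oracle
  fit <- lm(log(cohort$`Cer16:0`) ~ cohort$dosage)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.2), 3 * est["Std. Error"])
})

test_that("event generation respects ages, censoring and the case fraction", {
  truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.4), seed = 2)
  cohort <- simulate_cohort(truth, 5000, case_fraction = 0.2,
                            admin_censor_years = 10, seed = 3)
  expect_true(all(cohort$exit_age_t2d > cohort$entry_age))
  expect_true(all(cohort$exit_age_t2d <= cohort$entry_age + 10 + 1e-9))
  expect_true(all(cohort$event_t2d %in% 0:1))
  expect_true(all(cohort$entry_age >= 35 & cohort$entry_age <= 65))
  expect_lt(abs(mean(cohort$event_t2d) - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
  expect_true(all(as.matrix(cohort[, truth$nodes$metabolite]) > 0))
})

test_that("seeds give bit-identical cohorts and different seeds differ", {
  truth <- generate_ground_truth(2, 2, seed = 1)
  expect_identical(simulate_cohort(truth, 200, seed = 9),
                   simulate_cohort(truth, 200, seed = 9))
  expect_false(identical(simulate_cohort(truth, 200, seed = 9),
                         simulate_cohort(truth, 200, seed = 10)))
  expect_error(simulate_cohort(truth, 10), ">= 50")
})

test_that("case-cohort draw is subcohort union all cases, with exact flags", {
  truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.6), seed = 4)
  cohort <- simulate_cohort(truth, 3000, case_fraction = 0.15, seed = 5)

  # identity at fraction 1
  full <- draw_case_cohort(cohort, 1, seed = 1)
  expect_equal(nrow(full), nrow(cohort))
  expect_true(all(full$subcohort_member))

  cc <- draw_case_cohort(cohort, 0.1, seed = 6)
  n_cases <- sum(cohort$event_t2d)
  n_sub <- round(0.1 * nrow(cohort))
  cases_outside <- n_cases - attr(cc, "cases_in_subcohort")
  expect_equal(nrow(cc), n_sub + cases_outside)
  expect_true(all(cc$case == (cc$event == 1)))
  # non-cases are all subcohort members
  expect_true(all(cc$subcohort_member[!cc$case]))
  # determinism
  expect_identical(cc, draw_case_cohort(cohort, 0.1, seed = 6))
  expect_false(identical(cc$subject_id,
                         draw_case_cohort(cohort, 0.1, seed = 7)$subject_id))

  # endpoint with zero cases: warning, subcohort only
  cohort0 <- cohort
  cohort0$event_t2d <- 0L
  expect_warning(cc0 <- draw_case_cohort(cohort0, 0.1, seed = 6), "no cases")
  expect_equal(nrow(cc0), n_sub)
})

test_that("repeat-measure substudy matches the pilot design and ICC targets", {
  truth <- generate_ground_truth(3, 3, seed = 1)
  cohort <- simulate_cohort(truth, 2000, seed = 2)
  mets <- truth$nodes$metabolite

  pairs <- simulate_repeat_measures(cohort, mets, icc_target = 0.6,
                                    n_subjects = 35, seed = 3)
  expect_equal(nrow(pairs), 35 * length(mets))

  # icc_target = 1: both members reproduce the original measurement
  p1 <- simulate_repeat_measures(cohort, mets[1], icc_target = 1,
                                 n_subjects = 50, seed = 4)
  orig <- cohort[[mets[1]]][match(p1$subject_id, cohort$subject_id)]
  expect_equal(p1$measurement_1, orig)
  expect_equal(p1$measurement_2, orig)

  expect_error(simulate_repeat_measures(cohort, mets[1], icc_target = 0,
                                        n_subjects = 10), "icc_target")
})

test_that("a null generating model yields null screening behaviour", {
  truth <- quiet_truth(3, 3)
  ps <- unlist(lapply(1:5, function(i) {
    panel <- cc_panel(truth, 1500, subcohort_fraction = 1, seed = 100 + i)
    vapply(truth$nodes$metabolite, function(m) {
      fit <- fit_prentice_cox(panel, m, c("sex", "waist"))
      dplyr::filter(tidy(fit), term == m)$p
    }, numeric(1))
  }))
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
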