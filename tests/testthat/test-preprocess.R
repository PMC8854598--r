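test_that("log-z transform matches the closed-form example and its contract", {
  d <- tibble::tibble(subject_id = c("a", "b", "c"),
                      `Cer16:0` = exp(c(0, 1, 2)))
  z <- log_z_transform(d)
  expect_equal(z$`Cer16:0`, c(-1, 0, 1), tolerance = 1e-12)

  set.seed(1)
  d2 <- tibble::tibble(`Cer16:0` = rlnorm(500, 1, 0.7),
                       `dhCer18:0` = rlnorm(500, 2, 0.3))
  z2 <- log_z_transform(d2)
  for (m in c("Cer16:0", "dhCer18:0")) {
    expect_lt(abs(mean(z2[[m]])), 1e-10)
    expect_lt(abs(sd(z2[[m]]) - 1), 1e-10)     # sample SD, denominator n-1
    expect_equal(rank(z2[[m]]), rank(d2[[m]])) # monotone per column
  }
  pars <- transform_params(z2)
  expect_named(pars, c("metabolite", "mean_log", "sd_log"))
})

test_that("subjects with missing or non-positive values are excluded with reasons", {
  d <- tibble::tibble(subject_id = c("s1", "s2", "s3", "s4", "s5"),
                      `Cer16:0` = c(1, 2, NA, -1, 3),
                      `Cer18:0` = c(2, 1, 5, 4, 2))
  z <- log_z_transform(d)
  expect_equal(nrow(z), 3)
  ex <- excluded_subjects(z)
  expect_equal(ex$subject_id, c("s3", "s4"))
  expect_equal(ex$reason, c("missing metabolite value",
                            "non-positive concentration"))
  # per-analysis exclusion: selecting only the clean column keeps all rows
  expect_equal(nrow(log_z_transform(d, cols = "Cer18:0")), 5)

  expect_error(log_z_transform(tibble::tibble(`Cer16:0` = rep(2, 10))),
               "constant")
})

test_that("log transform symmetrizes a lognormal sample", {
  set.seed(7)
  d <- tibble::tibble(`Cer16:0` = rlnorm(10000, 0, 1))
  z <- log_z_transform(d)$`Cer16:0`
  skew <- mean(z^3)  # already centred and scaled
  expect_lt(abs(skew), 0.1)
})

test_that("one-way ICC matches its variance-components oracle and Rosner classes", {
  # identical pairs with between-subject spread: perfect reliability
  pairs <- tibble::tibble(metabolite = "m", subject = 1:50,
                          measurement_1 = exp(rnorm(50)),
                          measurement_2 = NA_real_)
  pairs$measurement_2 <- pairs$measurement_1
  r <- icc_one_way(pairs)
  expect_equal(r$icc, 1)
  expect_equal(r$class, "excellent")

  # sigma2_between = sigma2_within: ICC 0.5, fair to good
  set.seed(3)
  n <- 2000
  subj <- rnorm(n, 0, 1)
  pairs2 <- tibble::tibble(metabolite = "m",
                           measurement_1 = exp(subj + rnorm(n, 0, 1)),
                           measurement_2 = exp(subj + rnorm(n, 0, 1)))
  r2 <- icc_one_way(pairs2)
  expect_lt(abs(r2$icc - 0.5), 0.05)
  expect_equal(r2$class, "fair_to_good")

  # generator calibration hits the Rosner class boundaries' sides
  truth <- generate_ground_truth(2, 2, seed = 1)
  cohort <- simulate_cohort(truth, 4000, seed = 2)
  m <- truth$nodes$metabolite[1]
  icc_lo <- icc_one_way(simulate_repeat_measures(cohort, m, 0.3,
                                                 n_subjects = 2000, seed = 3))
  icc_hi <- icc_one_way(simulate_repeat_measures(cohort, m, 0.8,
                                                 n_subjects = 2000, seed = 4))
  expect_lt(abs(icc_lo$icc - 0.3), 0.06)
  expect_equal(icc_lo$class, "poor")
  expect_lt(abs(icc_hi$icc - 0.8), 0.04)
  expect_equal(icc_hi$class, "excellent")
})

test_that("ICC is invariant to affine rescaling of the measurements", {
  set.seed(9)
  pairs <- tibble::tibble(metabolite = "m",
                          measurement_1 = rnorm(200, 10, 2),
                          measurement_2 = rnorm(200, 10, 2))
  a <- icc_one_way(pairs, log = FALSE)$icc
  rescaled <- dplyr::mutate(pairs,
                            measurement_1 = 3 * measurement_1 + 7,
                            measurement_2 = 3 * measurement_2 + 7)
  b <- icc_one_way(rescaled, log = FALSE)$icc
  expect_equal(a, b, tolerance = 1e-12)

  expect_error(icc_one_way(pairs[1:2, ]), "at least 3")
})

test_that("partial correlations isolate direct dependencies in a chain", {
  nodes <- c("X", "Y", "Z")
  edges <- tibble::tibble(from = c("X", "Y"), to = c("Y", "Z"),
                          weight = c(0.9, 0.9))
  truth <- quiet_truth(2, 1, topology = "custom",
                       edges = data.frame(
                         from = c("Cer16:0", "Cer18:0"),
                         to = c("Cer18:0", "dhCer16:0"),
                         weight = c(0.9, 0.9)))
  cohort <- simulate_cohort(truth, 4000, seed = 21)
  panel <- log_z_transform(cohort)
  pc <- panel_correlations(panel)
  # closed-form marginal correlation of chain ends
  expected <- sem_cor(nodes, edges)["X", "Z"]
  expect_lt(abs(pc$pearson["Cer16:0", "dhCer16:0"] - expected), 0.05)
  expect_gt(pc$pearson["Cer16:0", "dhCer16:0"], 0.5)
  expect_lt(abs(pc$partial["Cer16:0", "dhCer16:0"]), 0.05)
  expect_true(isSymmetric(pc$partial))
  expect_equal(unname(diag(pc$partial)), rep(1, 3))
})

test_that("precision-based partial correlations equal the residual-regression oracle", {
  set.seed(5)
  x <- matrix(rnorm(300 * 5), 300, 5) %*% matrix(rnorm(25), 5)
  colnames(x) <- paste0("v", 1:5)
  d <- tibble::as_tibble(x)
  pc <- panel_correlations(d, cols = colnames(x))
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    i <- pair[1]; j <- pair[2]
    rest <- setdiff(1:5, pair)
    ri <- residuals(lm(x[, i] ~ x[, rest]))
    rj <- residuals(lm(x[, j] ~ x[, rest]))
    expect_equal(pc$partial[i, j], cor(ri, rj), tolerance = 1e-8)
  }
})

test_that("two-variable panels and singular panels behave as specified", {
  set.seed(6)
  d <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  pc <- panel_correlations(d, cols = c("a", "b"))
  # empty conditioning remainder: partial equals pairwise
  expect_equal(pc$partial[1, 2], pc$pearson[1, 2], tolerance = 1e-12)

  d$c <- d$a  # exact collinearity
  expect_error(panel_correlations(d, cols = c("a", "b", "c")), "singular")
  expect_error(panel_correlations(d[1:4, ], cols = c("a", "b", "c")),
               "n > p \\+ 2")
})
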