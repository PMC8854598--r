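#' Simulate a prospective cohort from a known generating model
#'
#' Draws subject-level data with the statistical structure the downstream
#' analysis assumes: log-scale metabolite concentrations from the linear
#' Gaussian network in `truth` (exponentiated to right-tailed raw nM values),
#' observed confounders loading on both metabolites and hazard, standard
#' normal diet exposures shifting their designated mediator metabolites,
#' a binomial(2, MAF) genotype dosage shifting the instrumented metabolite,
#' and event ages from a proportional-hazards model with a Weibull baseline
#' hazard on the age axis, left truncation at the baseline age and
#' administrative censoring `admin_censor_years` later.
#'
#' The Weibull scale is calibrated numerically per endpoint so that the
#' expected fraction of subjects with an observed event equals
#' `case_fraction`.  The hazard's linear predictor uses metabolites
#' standardized by their model-implied SD, so the true log hazard ratios in
#' `truth$effects` are per 1 SD, matching the analysis scale.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param n Number of subjects (>= 50).
#' @param baseline_age_range Entry-age interval, drawn uniformly (years).
#' @param admin_censor_years Administrative censoring horizon (years).
#' @param case_fraction Target expected fraction of observed events per
#'   endpoint (recycled over endpoints).
#' @param weibull_shape Shape of the baseline age-axis hazard.
#' @param missing_rate Completely-at-random missingness rate applied to raw
#'   metabolite concentrations (default 0).
#' @param seed Integer seed.
#'
#' @return A tibble with one row per subject: `subject_id`, `entry_age`,
#'   confounders, diet exposure columns, `dosage` (if instrumented),
#'   per-endpoint `exit_age_<endpoint>` / `event_<endpoint>`, and raw
#'   metabolite concentrations in nM (strictly positive where observed).
#' @export
#' @examples
#' truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.4), seed = 1)
#' cohort <- simulate_cohort(truth, n = 500, seed = 2)
#' dplyr::count(cohort, event_t2d)
simulate_cohort <- function(truth, n,
                            baseline_age_range = c(35, 65),
                            admin_censor_years = 10,
                            case_fraction = 0.15,
                            weibull_shape = 5,
                            missing_rate = 0,
                            seed = NULL) {
  stopifnot(inherits(truth, "lipid_truth"))
  if (!is.numeric(n) || length(n) != 1 || n < 50) {
    abort("`n` must be a single number >= 50")
  }
  n <- as.integer(n)
  nodes <- truth$nodes$metabolite
  p <- length(nodes)
  case_fraction <- rep_len(case_fraction, length(truth$endpoints))

  with_seed(seed, {
    entry_age <- runif(n, baseline_age_range[1], baseline_age_range[2])
    conf <- matrix(0, n, nrow(truth$confounders),
                   dimnames = list(NULL, truth$confounders$confounder))
    for (k in seq_len(nrow(truth$confounders))) {
      nm <- truth$confounders$confounder[k]
      conf[, k] <- if (nm == "sex") rbinom(n, 1, 0.5) - 0.5 else
        rnorm(n, 0, sqrt(truth$confounders$var[k]))
    }

    diet <- NULL
    if (!is.null(truth$mediation)) {
      exposures <- unique(purrr::map_chr(truth$mediation, "exposure"))
      diet <- matrix(rnorm(n * length(exposures)), n,
                     dimnames = list(NULL, exposures))
    }
    dosage <- NULL
    if (!is.null(truth$instrument)) {
      dosage <- rbinom(n, 2, truth$instrument$maf)
    }

    # structural equations in topological order, log scale
    ord <- topo_order(nodes, truth$edges)
    X <- matrix(0, n, p, dimnames = list(NULL, nodes))
    for (v in ord) {
      j <- match(v, nodes)
      mu <- conf %*% truth$confounder_loadings[, j, drop = FALSE]
      parents <- truth$edges[truth$edges$to == v, ]
      if (nrow(parents)) {
        mu <- mu + X[, parents$from, drop = FALSE] %*% parents$weight
      }
      if (!is.null(truth$mediation)) {
        for (m in truth$mediation) {
          if (v %in% names(m$coefs)) {
            mu <- mu + m$coefs[[v]] * diet[, m$exposure]
          }
        }
      }
      if (!is.null(truth$instrument) && truth$instrument$target == v) {
        mu <- mu + truth$instrument$beta * dosage
      }
      X[, j] <- mu + rnorm(n, 0, truth$noise_sd[j])
    }

    sigma <- implied_covariance(truth)
    Z <- sweep(X, 2, sqrt(diag(sigma)), "/")

    out <- tibble(
      subject_id = sprintf("S%06d", seq_len(n)),
      entry_age = entry_age
    )
    conf_out <- conf
    if ("sex" %in% colnames(conf_out)) {
      conf_out[, "sex"] <- conf_out[, "sex"] + 0.5   # report as 0/1
    }
    out <- dplyr::bind_cols(out, as_tibble(conf_out))
    if (!is.null(diet)) out <- dplyr::bind_cols(out, as_tibble(diet))
    if (!is.null(dosage)) out$dosage <- dosage

    censor_age <- entry_age + admin_censor_years
    for (k in seq_along(truth$endpoints)) {
      ep <- truth$endpoints[k]
      beta <- truth$effects$log_hr[truth$effects$endpoint == ep]
      lp <- drop(Z %*% beta) + drop(conf %*% truth$confounders$log_hr)
      if (!is.null(truth$mediation)) {
        for (m in truth$mediation) {
          if (identical(m$endpoint %||% truth$endpoints[1], ep) &&
              !is.null(m$direct_log_hr)) {
            lp <- lp + m$direct_log_hr * diet[, m$exposure]
          }
        }
      }
      hr <- exp(lp)
      lambda <- calibrate_weibull_scale(entry_age, censor_age, hr,
                                        weibull_shape, case_fraction[k])
      u <- runif(n)
      t_event <- lambda * ((entry_age / lambda)^weibull_shape -
                             log(u) / hr)^(1 / weibull_shape)
      event <- as.integer(t_event <= censor_age)
      exit_age <- pmin(t_event, censor_age)
      out[[paste0("exit_age_", ep)]] <- exit_age
      out[[paste0("event_", ep)]] <- event
    }

    raw <- exp(sweep(X, 2, truth$nodes$log_median, "+"))
    if (missing_rate > 0) {
      raw[matrix(runif(n * p) < missing_rate, n, p)] <- NA_real_
    }
    dplyr::bind_cols(out, as_tibble(raw))
  })
}

# Find the Weibull scale whose expected observed-event fraction matches the
# target, given each subject's entry age, censoring age and hazard ratio.
calibrate_weibull_scale <- function(entry, censor, hr, shape, target) {
  expected <- function(log_lambda) {
    lambda <- exp(log_lambda)
    dh <- (censor / lambda)^shape - (entry / lambda)^shape
    mean(1 - exp(-dh * hr)) - target
  }
  exp(uniroot(expected, lower = log(10), upper = log(1e6),
              extendInt = "downX", tol = 1e-10)$root)
}

#' Draw a case-cohort sample: random subcohort plus all incident cases
#'
#' Implements the case-cohort design: a random subcohort of the stated
#' fraction is drawn without replacement, and all subjects with an observed
#' event for `endpoint` are added (cases are oversampled relative to the
#' full cohort).  Per-endpoint `exit_age_*` / `event_*` columns are collapsed
#' to plain `exit_age` / `event` for the selected endpoint.
#'
#' @param cohort A cohort tibble from [simulate_cohort()] (or any table with
#'   `exit_age`/`event` columns, optionally endpoint-suffixed).
#' @param subcohort_fraction Proportion in (0, 1] sampled into the subcohort.
#' @param endpoint Endpoint label selecting the event columns.
#' @param seed Integer seed for the subcohort draw.
#'
#' @return A tibble flagged with logical `subcohort_member` and `case`
#'   columns, carrying attributes `endpoint`, `n_source`,
#'   `cases_in_subcohort`.
#' @export
draw_case_cohort <- function(cohort, subcohort_fraction, endpoint = "t2d",
                             seed = NULL) {
  if (!(subcohort_fraction > 0 && subcohort_fraction <= 1)) {
    abort("`subcohort_fraction` must lie in (0, 1]")
  }
  ec <- paste0("event_", endpoint)
  xc <- paste0("exit_age_", endpoint)
  if (!ec %in% names(cohort)) {
    assert_columns(cohort, c("event", "exit_age"), "cohort")
    ec <- "event"; xc <- "exit_age"
  }
  n <- nrow(cohort)
  sub_idx <- with_seed(seed, sort(sample.int(n, size = round(subcohort_fraction * n))))
  is_sub <- seq_len(n) %in% sub_idx
  is_case <- cohort[[ec]] == 1
  if (!any(is_case)) {
    warn(paste0("no cases for endpoint '", endpoint,
                "'; returning subcohort only"))
  }
  keep <- is_sub | is_case
  out <- cohort[keep, , drop = FALSE]
  out$exit_age <- out[[xc]]
  out$event <- out[[ec]]
  out <- out[, !grepl("^(exit_age|event)_", names(out)), drop = FALSE]
  out$subcohort_member <- is_sub[keep]
  out$case <- is_case[keep]
  out <- as_tibble(out)
  attr(out, "endpoint") <- endpoint
  attr(out, "n_source") <- n
  attr(out, "cases_in_subcohort") <- sum(is_sub & is_case)
  out
}

#' Simulate a repeat-measurement reliability substudy
#'
#' For `n_subjects` randomly chosen subjects, emits a pair of measurements
#' per metabolite whose log-scale within-person noise variance is calibrated
#' so that the one-way ANOVA intraclass correlation targets `icc_target`:
#' \eqn{\sigma^2_w = \sigma^2_b (1 - \rho) / \rho} where \eqn{\sigma^2_b} is
#' the cohort's between-person log-scale variance.  Noise is applied
#' symmetrically to both pair members; with `icc_target = 1` both equal the
#' original measurement.
#'
#' @param cohort Cohort tibble containing the metabolite columns.
#' @param metabolites Character vector of metabolite column names.
#' @param icc_target Target ICC in (0, 1], recycled per metabolite.
#' @param n_subjects Number of subjects re-measured.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `subject_id`, `metabolite`,
#'   `measurement_1`, `measurement_2` (raw concentration scale).
#' @export
simulate_repeat_measures <- function(cohort, metabolites, icc_target,
                                     n_subjects = 35, seed = NULL) {
  if (any(icc_target <= 0) || any(icc_target > 1)) {
    abort("`icc_target` must lie in (0, 1]")
  }
  assert_columns(cohort, metabolites, "cohort")
  icc_target <- rep_len(icc_target, length(metabolites))
  with_seed(seed, {
    idx <- sort(sample.int(nrow(cohort), n_subjects))
    purrr::map_dfr(seq_along(metabolites), function(j) {
      m <- metabolites[j]
      x <- log(cohort[[m]][idx])
      s2b <- var(log(cohort[[m]]), na.rm = TRUE)
      s2w <- s2b * (1 - icc_target[j]) / icc_target[j]
      tibble(
        subject_id = cohort$subject_id[idx],
        metabolite = m,
        measurement_1 = exp(x + rnorm(n_subjects, 0, sqrt(s2w))),
        measurement_2 = exp(x + rnorm(n_subjects, 0, sqrt(s2w)))
      )
    })
  })
}
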