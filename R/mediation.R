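#' Select metabolite mediators of a dietary exposure
#'
#' A disease-related candidate metabolite is selected as a potential
#' mediator when its confounder-adjusted linear association with the
#' exposure is significant one-sided at 0.05 in the direction consistent
#' with mediation: the sign of the exposure-metabolite path times the sign
#' of the metabolite-disease path must match the sign of the exposure's
#' total disease association.
#'
#' @param sample Case-cohort tibble with standardized metabolites and the
#'   exposure column.
#' @param exposure Continuous exposure column name.
#' @param candidate_signs Named numeric: per candidate metabolite, the sign
#'   (or signed log-HR) of its disease association, taken from the
#'   mutually adjusted joint model of [netcoupler()].  An NA sign is
#'   rejected - candidates must come from the effect-classification step.
#' @param confounders Adjustment columns for the exposure-metabolite
#'   regressions.
#' @param total_sign Sign of the exposure's total (confounder-adjusted)
#'   log-HR on the endpoint; if NULL it is estimated with
#'   [fit_prentice_cox()].
#' @param alpha One-sided level (default 0.05).
#' @return Tibble: metabolite, coef, se, statistic, one_sided_p,
#'   required_sign, selected.
#' @export
select_mediators <- function(sample, exposure, candidate_signs,
                             confounders = character(), total_sign = NULL,
                             alpha = 0.05) {
  if (is.null(names(candidate_signs)) || any(is.na(candidate_signs))) {
    abort("`candidate_signs` must be a named vector with no NA; take the disease-association signs from the joint model")
  }
  assert_columns(sample, c(exposure, names(candidate_signs), confounders),
                 "sample")
  if (is.null(total_sign)) {
    tot <- fit_prentice_cox(sample, exposure, confounders)
    total_sign <- sign(dplyr::filter(tot$estimates,
                                     .data$term == !!exposure)$log_hr)
  }
  purrr::map_dfr(names(candidate_signs), function(m) {
    covs <- c(exposure, confounders)
    d <- stats::setNames(
      as.data.frame(sample[, c(m, covs), drop = FALSE]),
      c(".y", paste0(".x", seq_along(covs))))
    fit <- stats::lm(stats::as.formula(
      paste(".y ~", paste(paste0(".x", seq_along(covs)), collapse = " + "))),
      data = d)
    cf <- summary(fit)$coefficients[".x1", ]
    req <- sign(total_sign) * sign(candidate_signs[[m]])
    tstat <- unname(cf["t value"])
    p_one <- stats::pt(req * tstat, df = fit$df.residual, lower.tail = FALSE)
    tibble(metabolite = m, coef = unname(cf["Estimate"]),
           se = unname(cf["Std. Error"]), statistic = tstat,
           one_sided_p = p_one, required_sign = req,
           selected = p_one < alpha)
  })
}

#' Proportion explainable: percentage attenuation of a log hazard ratio
#'
#' PE = 100 (1 - logHR_adjusted / logHR_total), the difference method on
#' the log-HR scale.  The point estimate is never truncated (it may be
#' negative under amplification, or exceed 100); interval truncation is a
#' reporting concern handled by [pe_bootstrap_ci()].  A delta-method SE is
#' available when both fits' standard errors are supplied; the covariance
#' between the two nested fits defaults to 0 (independence approximation),
#' so the bootstrap interval is the primary uncertainty statement.
#'
#' @param total,adjusted Either [`cc_cox`] fits (the exposure's first term
#'   is used) or bare log-HR numerics.
#' @param exposure Exposure term name, required when passing `cc_cox` fits
#'   with several exposures.
#' @param floor Minimum |logHR_total| below which mediation is undefined
#'   (ratio blow-up guard, default 0.01).
#' @param se_total,se_adjusted Optional standard errors for the delta SE.
#' @param cov Covariance of the two estimates for the delta SE (default 0).
#' @return One-row tibble: `pe` (percent), `se` (NA unless SEs supplied).
#' @export
#' @examples
#' proportion_explainable(log(1.31), 0.1026)  # PE = 62.0
proportion_explainable <- function(total, adjusted, exposure = NULL,
                                   floor = 0.01,
                                   se_total = NULL, se_adjusted = NULL,
                                   cov = 0) {
  pick <- function(obj) {
    if (inherits(obj, "cc_cox")) {
      term <- exposure %||% obj$exposures[1]
      row <- dplyr::filter(obj$estimates, .data$term == !!term)
      c(row$log_hr, row$se)
    } else {
      c(obj, NA_real_)
    }
  }
  tot <- pick(total); adj <- pick(adjusted)
  lt <- tot[1]; la <- adj[1]
  se_total <- se_total %||% tot[2]
  se_adjusted <- se_adjusted %||% adj[2]
  if (abs(lt) < floor) {
    abort(paste0("total log-HR (", format(lt, digits = 3),
                 ") is below the floor ", floor,
                 "; proportion explainable is undefined"))
  }
  pe <- 100 * (1 - la / lt)
  se <- NA_real_
  if (!is.na(se_total) && !is.na(se_adjusted)) {
    # delta method on g(la, lt) = 1 - la/lt
    g <- c(-1 / lt, la / lt^2)
    V <- matrix(c(se_adjusted^2, cov, cov, se_total^2), 2)
    se <- 100 * sqrt(drop(t(g) %*% V %*% g))
  }
  tibble(pe = pe, se = se)
}

#' BCa bootstrap confidence interval for the proportion explainable
#'
#' Subjects are resampled with replacement at `sampling_fraction` of the
#' sample size; per replicate both Cox fits (total and mediator-adjusted)
#' are refit and PE recomputed.  The interval is bias-corrected and
#' accelerated: the bias correction z0 comes from the bootstrap
#' distribution's position relative to the point estimate, the acceleration
#' from a grouped jackknife (delete-one-group estimates).  The seed fully
#' determines the interval.  The reported upper bound is truncated at 100%.
#'
#' @param sample Case-cohort tibble.
#' @param exposure Exposure column.
#' @param mediators Mediator metabolite columns.
#' @param confounders Adjustment columns.
#' @param B Bootstrap replicates (>= 100; default 1000).
#' @param sampling_fraction Resample size as a fraction of n (default 2/3).
#' @param seed Integer seed.
#' @param jack_groups Number of jackknife groups for the acceleration.
#' @param floor Passed to [proportion_explainable()].
#' @param level Interval coverage (default 0.95).
#' @return One-row tibble: pe_low, pe_high, b, sampling_fraction, seed,
#'   n_failed.  Errors if more than 5% of replicates fail.
#' @export
pe_bootstrap_ci <- function(sample, exposure, mediators, confounders,
                            B = 1000, sampling_fraction = 2/3, seed = NULL,
                            jack_groups = 20, floor = 0.01, level = 0.95) {
  if (B < 100) abort("B must be at least 100")
  # the floor applies to the point estimate (mediation undefined for a null
  # total effect); resampled totals may come arbitrarily close to zero and
  # then simply fatten the bootstrap tails, as in bcajack
  pe_of <- function(dat, fl = 1e-12) {
    tot <- fit_prentice_cox(dat, exposure, confounders)
    adj <- fit_prentice_cox(dat, exposure, c(mediators, confounders))
    if (!tot$converged || !adj$converged) abort("non-convergence")
    proportion_explainable(tot, adj, exposure = exposure, floor = fl)$pe
  }
  theta_hat <- pe_of(sample, fl = floor)
  n <- nrow(sample)
  m <- round(sampling_fraction * n)

  res <- with_seed(seed, {
    theta_b <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = TRUE)
      theta_b[b] <- tryCatch(pe_of(sample[idx, , drop = FALSE]),
                             error = function(e) NA_real_)
    }
    # grouped jackknife for the acceleration constant
    perm <- sample.int(n)
    groups <- split(perm, rep_len(seq_len(jack_groups), n))
    theta_j <- purrr::map_dbl(groups, function(g) {
      tryCatch(pe_of(sample[-g, , drop = FALSE]), error = function(e) NA_real_)
    })
    list(theta_b = theta_b, theta_j = theta_j)
  })

  failed <- sum(is.na(res$theta_b))
  if (failed > 0.05 * B) {
    abort(paste0(failed, " of ", B, " bootstrap replicates failed (> 5%); ",
                 "interval not computed"))
  }
  tb <- res$theta_b[!is.na(res$theta_b)]
  tj <- res$theta_j[!is.na(res$theta_j)]

  if (stats::sd(tb) < 1e-12) {
    low <- high <- tb[1]
  } else {
    prop <- (sum(tb < theta_hat) + 0.5 * sum(tb == theta_hat)) / length(tb)
    prop <- min(max(prop, 1 / (length(tb) + 1)), length(tb) / (length(tb) + 1))
    z0 <- qnorm(prop)
    jm <- mean(tj)
    num <- sum((jm - tj)^3)
    den <- 6 * (sum((jm - tj)^2))^1.5
    a <- if (den > 0) num / den else 0
    alpha2 <- c((1 - level) / 2, 1 - (1 - level) / 2)
    zq <- qnorm(alpha2)
    adj_q <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    ci <- unname(stats::quantile(tb, adj_q, type = 7))
    low <- ci[1]; high <- ci[2]
  }
  tibble(pe_low = low, pe_high = min(high, 100), b = B,
         sampling_fraction = sampling_fraction,
         seed = seed %||% NA_integer_, n_failed = failed)
}

#' Full mediation analysis of one exposure: fits, PE and bootstrap CI
#'
#' Convenience wrapper: fits the total (exposure + confounders) and
#' mediator-adjusted Prentice-weighted Cox models, computes the proportion
#' explainable and its BCa bootstrap interval, and reports hazard ratios
#' per `exposure_unit` raw exposure units (e.g. 2 SD of a diet quantity,
#' or 2 cups of coffee).
#'
#' @inheritParams pe_bootstrap_ci
#' @param exposure_unit Reporting unit in raw exposure units; default
#'   `2 * sd(exposure)`.  PE itself is invariant to this scaling.
#' @return Object of class `pe_result`; `tidy()` gives the one-row report.
#' @export
mediate_pe <- function(sample, exposure, mediators, confounders,
                       exposure_unit = NULL, B = 1000,
                       sampling_fraction = 2/3, seed = NULL,
                       jack_groups = 20, floor = 0.01) {
  assert_columns(sample, c(exposure, mediators, confounders), "sample")
  exposure_unit <- exposure_unit %||% (2 * stats::sd(sample[[exposure]]))
  total <- fit_prentice_cox(sample, exposure, confounders)
  adjusted <- fit_prentice_cox(sample, exposure, c(mediators, confounders))
  pe <- proportion_explainable(total, adjusted, exposure = exposure,
                               floor = floor)
  ci <- pe_bootstrap_ci(sample, exposure, mediators, confounders, B = B,
                        sampling_fraction = sampling_fraction, seed = seed,
                        jack_groups = jack_groups, floor = floor)
  structure(list(exposure = exposure, mediators = mediators,
                 total = total, adjusted = adjusted,
                 pe = pe$pe, pe_ci = ci, exposure_unit = exposure_unit),
            class = "pe_result")
}

#' @method tidy pe_result
#' @export
tidy.pe_result <- function(x, ...) {
  u <- x$exposure_unit
  row <- function(fit) {
    r <- dplyr::filter(fit$estimates, .data$term == x$exposure)
    c(exp(u * r$log_hr),
      exp(u * (r$log_hr - 1.96 * r$se)),
      exp(u * (r$log_hr + 1.96 * r$se)))
  }
  t <- row(x$total); a <- row(x$adjusted)
  tibble(exposure = x$exposure,
         mediators = paste(x$mediators, collapse = ","),
         hr_total = t[1], ci_low_total = t[2], ci_high_total = t[3],
         hr_adjusted = a[1], ci_low_adjusted = a[2],
         ci_high_adjusted = a[3],
         pe = x$pe, pe_low = x$pe_ci$pe_low, pe_high = x$pe_ci$pe_high,
         b = x$pe_ci$b, sampling_fraction = x$pe_ci$sampling_fraction,
         seed = x$pe_ci$seed)
}

#' @export
print.pe_result <- function(x, ...) {
  cat("<pe_result> exposure: ", x$exposure, " via ",
      paste(x$mediators, collapse = ", "), "\n", sep = "")
  cat(sprintf("PE = %.1f%% (95%% BCa CI %.1f to %.1f)\n",
              x$pe, x$pe_ci$pe_low, x$pe_ci$pe_high))
  invisible(x)
}
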