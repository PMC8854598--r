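#' Prentice-weighted Cox model for case-cohort samples
#'
#' Fits a Cox proportional-hazards model with age as the underlying time
#' scale (left truncation at `entry_age`, exit at `exit_age`) under the
#' Prentice pseudolikelihood for case-cohort data: subcohort members are at
#' risk over their whole observed age interval, while cases outside the
#' subcohort enter the risk set only immediately before their own event age.
#' When every row is a subcohort member the fit reduces exactly to the
#' standard partial likelihood on the full cohort.  Variance is always the
#' robust (sandwich) estimator, since the pseudolikelihood invalidates the
#' model-based one; ties use Efron's approximation.
#'
#' @param sample Case-cohort tibble (see [draw_case_cohort()]) with columns
#'   `entry_age`, `exit_age`, `event`, optionally a logical
#'   `subcohort_member` (absent means full cohort).
#' @param exposures Character vector of exposure columns (one or several for
#'   a mutually adjusted joint model).
#' @param confounders Character vector of adjustment columns.
#' @param strata_age_bands If TRUE, additionally stratify the baseline
#'   hazard by bands of baseline age of width `band_width` years (off by
#'   default; age is already the time scale).
#' @param band_width Age-band width in years for the optional strata.
#' @return Object of class `cc_cox`: list with the underlying
#'   [survival::coxph()] fit, an `estimates` tibble (term, log_hr, se, hr,
#'   ci_low, ci_high, p, exposure flag), `n`, `n_events`, `converged`.
#'   `tidy()` returns the estimates, `glance()` the fit summary.
#' @export
#' @examples
#' truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.5), seed = 1)
#' cohort <- simulate_cohort(truth, 2000, seed = 2)
#' cc <- draw_case_cohort(cohort, 0.2, seed = 3)
#' panel <- log_z_transform(cc)
#' fit <- fit_prentice_cox(panel, "Cer18:0", c("sex", "waist"))
#' tidy(fit)
fit_prentice_cox <- function(sample, exposures, confounders = character(),
                             strata_age_bands = FALSE, band_width = 5) {
  assert_columns(sample, c("entry_age", "exit_age", "event",
                           exposures, confounders), "sample")
  overlap <- intersect(exposures, confounders)
  if (length(overlap)) {
    abort(paste("exposure(s) also listed as confounders:",
                paste(overlap, collapse = ", ")))
  }
  if (sum(sample$event) < 1) abort("no events in the sample")

  sub <- if ("subcohort_member" %in% names(sample)) {
    as.logical(sample$subcohort_member)
  } else {
    rep(TRUE, nrow(sample))
  }
  # Prentice risk sets: out-of-subcohort cases enter just before their event
  eps <- 1e-6 * diff(range(sample$exit_age))
  start <- ifelse(sub, sample$entry_age, sample$exit_age - eps)
  covs <- c(exposures, confounders)
  safe <- paste0(".v", seq_along(covs))   # metabolite labels like Cer16:0
  df <- dplyr::bind_cols(tibble(.t0 = start, .t1 = sample$exit_age,
                                .ev = as.integer(sample$event)),
                         stats::setNames(sample[, covs, drop = FALSE], safe))

  mm <- stats::model.matrix(~ ., data = df[, safe, drop = FALSE])[, -1, drop = FALSE]
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dep_safe <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    dep <- covs[match(sub("^(\\.v[0-9]+).*$", "\\1", dep_safe), safe)]
    abort(paste("model matrix is rank deficient; collinear column(s):",
                paste(unique(dep), collapse = ", ")))
  }

  rhs <- paste(safe, collapse = " + ")
  if (strata_age_bands) {
    df$.age_band <- floor(sample$entry_age / band_width)
    rhs <- paste(rhs, "+ survival::strata(.age_band)")
  }
  fml <- stats::as.formula(paste("survival::Surv(.t0, .t1, .ev) ~", rhs))

  df$.id <- if ("subject_id" %in% names(sample)) sample$subject_id else
    seq_len(nrow(sample))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron", robust = TRUE,
                    cluster = .id),
    warning = function(w) {
      if (grepl("Ran out of iterations|did not converge|infinite",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(is.na(coef(fit)))) {
    abort(paste("coefficients inestimable for:",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }

  s <- summary(fit)
  raw_terms <- rownames(s$coefficients)
  # map .vK (and .vKlevel for factors) back to the original column names
  terms <- covs[match(sub("^(\\.v[0-9]+).*$", "\\1", raw_terms), safe)]
  terms[is.na(terms)] <- raw_terms[is.na(terms)]
  se_rob <- s$coefficients[, "robust se"]
  est <- s$coefficients[, "coef"]
  estimates <- tibble(
    term = terms,
    log_hr = unname(est),
    se = unname(se_rob),
    hr = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se_rob)),
    ci_high = exp(unname(est) + 1.96 * unname(se_rob)),
    p = 2 * pnorm(-abs(unname(est) / unname(se_rob))),
    exposure = terms %in% exposures
  )
  structure(list(fit = fit, estimates = estimates,
                 exposures = exposures, confounders = confounders,
                 n = nrow(sample), n_events = sum(df$.ev),
                 converged = converged),
            class = "cc_cox")
}

#' @export
print.cc_cox <- function(x, ...) {
  cat("<cc_cox> n = ", x$n, ", events = ", x$n_events,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(as.data.frame(dplyr::filter(x$estimates, .data$exposure)),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method tidy cc_cox
#' @export
tidy.cc_cox <- function(x, exposures_only = FALSE, ...) {
  if (exposures_only) dplyr::filter(x$estimates, .data$exposure) else x$estimates
}

#' @method glance cc_cox
#' @export
glance.cc_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, converged = x$converged,
         concordance = unname(summary(x$fit)$concordance[1]))
}

#' Single-metabolite association screen with FDR control
#'
#' Fits one Prentice-weighted Cox model per metabolite and per adjustment
#' model, and computes Benjamini-Hochberg q-values within each model family,
#' flagging associations at FDR < `fdr`.
#'
#' @param sample Case-cohort tibble whose metabolite columns are already
#'   standardized (see [log_z_transform()]).
#' @param metabolites Metabolite columns to screen.
#' @param models Named list of confounder vectors, one per model family
#'   (e.g. `list(minimal = "sex", full = c("sex", "waist"))`).
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @return Tibble: metabolite, model, log_hr, se, hr, ci_low, ci_high, p, q,
#'   significant.
#' @export
single_lipid_screen <- function(sample, metabolites, models, fdr = 0.05) {
  stopifnot(is.list(models), !is.null(names(models)))
  out <- purrr::map_dfr(names(models), function(mod) {
    purrr::map_dfr(metabolites, function(m) {
      fit <- fit_prentice_cox(sample, m, models[[mod]])
      row <- dplyr::filter(fit$estimates, .data$term == m)
      dplyr::mutate(dplyr::select(row, -"exposure", -"term"),
                    metabolite = m, model = mod, .before = 1)
    }) |>
      dplyr::mutate(q = p.adjust(.data$p, method = "BH"),
                    significant = .data$q < fdr)
  })
  out
}

#' Sensitivity-analysis exclusion filters for a case-cohort sample
#'
#' `drop_lipid_lowering_users` removes subjects flagged in `medication_col`;
#' `drop_events_first_2y` removes subjects whose event occurs within 2 years
#' of entry (reverse-causation guard).
#'
#' @param sample Case-cohort tibble with `entry_age`, `exit_age`, `event`.
#' @param filter One of `"drop_lipid_lowering_users"`,
#'   `"drop_events_first_2y"`.
#' @param medication_col Column with the lipid-lowering-use indicator.
#' @return The filtered sample; errors with count diagnostics if the filter
#'   would remove every case.
#' @export
apply_sensitivity_filters <- function(sample,
                                      filter = c("drop_lipid_lowering_users",
                                                 "drop_events_first_2y"),
                                      medication_col = "lipid_lowering") {
  filter <- match.arg(filter)
  drop <- if (filter == "drop_lipid_lowering_users") {
    assert_columns(sample, medication_col, "sample")
    sample[[medication_col]] == 1
  } else {
    assert_columns(sample, c("entry_age", "exit_age", "event"), "sample")
    sample$event == 1 & (sample$exit_age - sample$entry_age) < 2
  }
  out <- sample[!drop, , drop = FALSE]
  if (sum(out$event) == 0) {
    abort(paste0("filter '", filter, "' removed all cases (",
                 sum(sample$event), " cases before, 0 after; ",
                 sum(drop), " rows dropped)"))
  }
  for (a in c("endpoint", "n_source")) {
    attr(out, a) <- attr(sample, a)
  }
  out
}
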