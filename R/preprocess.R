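#' Log-transform and z-scale a metabolite panel
#'
#' Raw concentrations are natural-log transformed (right-tailed nM values
#' become approximately normal) and each column is centred and scaled by its
#' sample SD (denominator n - 1), so downstream regression estimates are per
#' 1 SD of the log concentration.  Subjects with a missing or non-positive
#' value in any of the selected columns are excluded from the returned panel,
#' with the reason recorded; exclusion is therefore per-analysis, driven by
#' the columns the caller selects.
#'
#' In a case-cohort sample, cases are oversampled, so means and SDs computed
#' on the analysis sample are not representative of the cohort; pass `params`
#' derived from the random subcohort (or full cohort) to standardize on the
#' representative scale instead of re-estimating it.
#'
#' @param data Subject-level data frame.
#' @param cols Character vector of metabolite columns to transform; default
#'   NULL means every numeric column whose name starts with `Cer` or `dhCer`.
#' @param params Optional transform-parameter tibble (metabolite, mean_log,
#'   sd_log) from a previous [transform_params()] call, applied as-is.
#' @return A tibble with the selected columns transformed, carrying
#'   attributes `transform_params` (tibble: metabolite, mean_log, sd_log) and
#'   `excluded` (tibble: subject_id, reason).  Retrieve them with
#'   [transform_params()] and [excluded_subjects()].
#' @export
#' @examples
#' d <- tibble::tibble(subject_id = c("a", "b", "c"),
#'                     `Cer16:0` = exp(c(0, 1, 2)))
#' z <- log_z_transform(d)
#' z$`Cer16:0`   # -1, 0, 1
log_z_transform <- function(data, cols = NULL, params = NULL) {
  if (!is.null(params)) {
    cols <- cols %||% params$metabolite
    stopifnot(all(cols %in% params$metabolite))
  }
  if (is.null(cols)) {
    cols <- names(data)[grepl("^(Cer|dhCer)", names(data)) &
                          vapply(data, is.numeric, logical(1))]
  }
  if (!length(cols)) abort("no metabolite columns selected")
  assert_columns(data, cols, "data")

  id <- if ("subject_id" %in% names(data)) data$subject_id else
    as.character(seq_len(nrow(data)))
  vals <- as.matrix(data[, cols, drop = FALSE])
  bad_missing <- rowSums(is.na(vals)) > 0
  bad_nonpos <- !bad_missing & rowSums(vals <= 0, na.rm = TRUE) > 0
  reason <- dplyr::case_when(
    bad_missing ~ "missing metabolite value",
    bad_nonpos ~ "non-positive concentration",
    TRUE ~ NA_character_
  )
  excluded <- tibble(subject_id = id[!is.na(reason)],
                     reason = reason[!is.na(reason)])
  keep <- !(bad_missing | bad_nonpos)
  out <- as_tibble(data[keep, , drop = FALSE])
  if (is.null(params)) {
    params <- purrr::map_dfr(cols, function(m) {
      lx <- log(out[[m]])
      s <- sd(lx)
      if (!is.finite(s) || s == 0) {
        abort(paste0("column '", m,
                     "' is constant; SD undefined for standardization"))
      }
      tibble(metabolite = m, mean_log = mean(lx), sd_log = s)
    })
  } else {
    params <- params[match(cols, params$metabolite), , drop = FALSE]
  }
  for (k in seq_along(cols)) {
    out[[cols[k]]] <- (log(out[[cols[k]]]) - params$mean_log[k]) / params$sd_log[k]
  }
  attr(out, "transform_params") <- params
  attr(out, "excluded") <- excluded
  attr(out, "metabolites") <- cols
  out
}

#' @rdname log_z_transform
#' @param panel A panel returned by [log_z_transform()].
#' @export
transform_params <- function(panel) attr(panel, "transform_params")

#' @rdname log_z_transform
#' @export
excluded_subjects <- function(panel) attr(panel, "excluded")

#' One-way random-effects intraclass correlation with Rosner classes
#'
#' Quantifies measurement reliability from paired repeat measurements as
#' ICC = (MSB - MSW) / (MSB + (k - 1) MSW) with k = 2 measurements per
#' subject, computed on the log scale by default.  Reliability classes follow
#' Rosner's cutoffs: below 0.40 poor, 0.40-0.75 fair to good, above 0.75
#' excellent.
#'
#' @param pairs Tibble from [simulate_repeat_measures()] or any table with
#'   columns `metabolite`, `measurement_1`, `measurement_2` (one row per
#'   subject and metabolite).
#' @param log Log-transform measurements before the variance decomposition
#'   (default TRUE, matching the analysis scale of the panel).
#' @return A tibble: `metabolite`, `icc`, `class`.
#' @export
icc_one_way <- function(pairs, log = TRUE) {
  assert_columns(pairs, c("metabolite", "measurement_1", "measurement_2"),
                 "pairs")
  pairs |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(icc = {
      m1 <- if (log) base::log(.data$measurement_1) else .data$measurement_1
      m2 <- if (log) base::log(.data$measurement_2) else .data$measurement_2
      n <- length(m1)
      if (n < 3) abort("ICC requires at least 3 subjects with repeat pairs")
      grand <- mean(c(m1, m2))
      means <- (m1 + m2) / 2
      msb <- 2 * sum((means - grand)^2) / (n - 1)
      msw <- sum((m1 - means)^2 + (m2 - means)^2) / n
      (msb - msw) / (msb + msw)
    }, .groups = "drop") |>
    dplyr::mutate(class = rosner_class(.data$icc))
}

rosner_class <- function(icc) {
  dplyr::case_when(
    icc < 0.40 ~ "poor",
    icc <= 0.75 ~ "fair_to_good",
    TRUE ~ "excellent"
  )
}

#' Pairwise and full partial correlation matrices of a standardized panel
#'
#' Pairwise Pearson correlations, and partial correlations of each pair
#' conditioning on all remaining panel variables via the precision matrix:
#' \eqn{\rho_{ij \cdot rest} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}}.
#'
#' @param data Standardized panel (e.g. from [log_z_transform()]).
#' @param cols Metabolite columns; default: the panel's recorded metabolites,
#'   else every `Cer`/`dhCer` numeric column.
#' @return An object of class `lipid_cor`: list with symmetric unit-diagonal
#'   matrices `pearson` and `partial`, plus `n`.
#' @export
panel_correlations <- function(data, cols = NULL) {
  cols <- cols %||% attr(data, "metabolites") %||%
    names(data)[grepl("^(Cer|dhCer)", names(data)) &
                  vapply(data, is.numeric, logical(1))]
  assert_columns(data, cols, "data")
  x <- as.matrix(data[, cols, drop = FALSE])
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p + 2) abort("need n > p + 2 observations for partial correlations")
  cmat <- cor(x)
  rk <- qr(cmat)$rank
  if (rk < p) {
    abort(paste0("covariance is singular (rank ", rk, " < ", p,
                 "); partial correlations undefined"))
  }
  omega <- solve(cmat)
  d <- 1 / sqrt(diag(omega))
  partial <- -omega * tcrossprod(d)
  diag(partial) <- 1
  dimnames(partial) <- dimnames(cmat)
  structure(list(pearson = cmat, partial = partial, n = n),
            class = "lipid_cor")
}

#' @export
print.lipid_cor <- function(x, ...) {
  cat("<lipid_cor> ", ncol(x$pearson), " variables, n = ", x$n, "\n", sep = "")
  cat("mean |pairwise r| = ",
      round(mean(abs(x$pearson[upper.tri(x$pearson)])), 3),
      "; mean |partial r| = ",
      round(mean(abs(x$partial[upper.tri(x$partial)])), 3), "\n", sep = "")
  invisible(x)
}
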