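#' Enumerate neighbour-subset adjustment sets for a node
#'
#' All `2^d` subsets of the node's skeleton neighbours excluding the fixed
#' adjustment set (which is always adjusted for and never enumerated over),
#' in a deterministic order: by subset size, then lexicographically.
#'
#' @param skeleton A [pc_skeleton()] object.
#' @param node Node label.
#' @param fixed_set Labels always adjusted for (excluded from enumeration).
#' @param max_sets Refuse enumeration beyond this many subsets
#'   (default 2^10); exponential blow-up guard for dense nodes.
#' @return List of character vectors, first `character(0)`, last the full
#'   neighbour set.
#' @export
enumerate_adjustment_sets <- function(skeleton, node, fixed_set = character(),
                                      max_sets = 1024) {
  nbrs <- sort(setdiff(skeleton_neighbors(skeleton, node), fixed_set))
  d <- length(nbrs)
  if (2^d > max_sets) {
    abort(paste0("node '", node, "' has ", d, " free neighbours (2^", d,
                 " submodels exceeds the cap of ", max_sets, ")"))
  }
  sets <- list(character(0))
  if (d > 0) {
    for (k in seq_len(d)) {
      sets <- c(sets, utils::combn(nbrs, k, simplify = FALSE))
    }
  }
  sets
}

#' Classify one metabolite's link to disease risk as direct or not
#'
#' Fits one Prentice-weighted Cox model per enumerated neighbour subset,
#' each adjusted for the base confounders, the fixed set, and the subset.
#' The metabolite is classified `direct` when every submodel is significant
#' at `alpha` with one common coefficient sign, `none` when no submodel is
#' significant, and `ambiguous` otherwise.  Any non-convergent submodel
#' makes the decision `unresolved` rather than silently absent.
#'
#' @param sample Case-cohort tibble with standardized metabolites.
#' @param node Metabolite to classify.
#' @param skeleton Skeleton over the same panel.
#' @param confounders Base adjustment columns (e.g. confounder list plus
#'   total ceramide / total dihydroceramide concentrations).
#' @param fixed_set Previously selected direct effectors, always adjusted.
#' @param alpha Per-submodel significance level (default 0.05).
#' @param max_sets Submodel cap per node (see
#'   [enumerate_adjustment_sets()]).
#' @return One-row tibble: metabolite, classification, n_submodels,
#'   log_hr_min, log_hr_max, p_max, sign_consistent.
#' @export
classify_direct_effect <- function(sample, node, skeleton, confounders,
                                   fixed_set = character(), alpha = 0.05,
                                   max_sets = 1024) {
  sets <- enumerate_adjustment_sets(skeleton, node, fixed_set, max_sets)
  fits <- purrr::map(sets, function(S) {
    fit_prentice_cox(sample, node,
                     unique(c(confounders, fixed_set, S)))
  })
  rows <- purrr::map_dfr(fits, function(f) {
    dplyr::filter(f$estimates, .data$term == node)
  })
  if (!all(purrr::map_lgl(fits, "converged"))) {
    cls <- "unresolved"
  } else {
    all_sig <- all(rows$p < alpha)
    none_sig <- all(rows$p >= alpha)
    consistent <- length(unique(sign(rows$log_hr))) == 1
    cls <- if (all_sig && consistent) "direct" else
      if (none_sig) "none" else "ambiguous"
  }
  tibble(metabolite = node,
         classification = cls,
         n_submodels = length(sets),
         log_hr_min = min(rows$log_hr),
         log_hr_max = max(rows$log_hr),
         p_max = max(rows$p),
         sign_consistent = length(unique(sign(rows$log_hr))) == 1)
}

#' Iterative network-neighbour direct-effect selection
#'
#' Round-based loop over the panel: each round classifies every
#' not-yet-selected metabolite with the current fixed adjustment set
#' ([classify_direct_effect()]); all metabolites newly classified `direct`
#' join the fixed set together at round end (batch update, making the result
#' invariant to metabolite ordering).  Selected effectors can only act as
#' confounders, not mediators, of the remaining candidates, which justifies
#' conditioning on them.  The loop stops when a round selects nothing;
#' termination is guaranteed in at most p rounds.  Finally all selected
#' metabolites enter one mutually adjusted joint Cox model.
#'
#' @inheritParams classify_direct_effect
#' @param max_rounds Optional hard round cap (defaults to panel size).
#' @return Object of class `netcoupler_result`: `decisions` (tibble with an
#'   `iteration` column; a metabolite re-examined in later rounds appears
#'   once per round until selected), `selected`, `joint` (a [`cc_cox`]
#'   mutually adjusted fit, or NULL when nothing was selected), `rounds`,
#'   `alpha`.
#' @export
#' @examples
#' \donttest{
#' truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.5), seed = 1)
#' cohort <- simulate_cohort(truth, 3000, seed = 2)
#' cc <- draw_case_cohort(cohort, 0.25, seed = 3)
#' panel <- log_z_transform(cc)
#' sk <- pc_skeleton(panel)
#' netcoupler(panel, sk, confounders = c("sex", "waist"))
#' }
netcoupler <- function(sample, skeleton, confounders, alpha = 0.05,
                       max_sets = 1024, max_rounds = NULL) {
  nodes <- skeleton$nodes
  assert_columns(sample, nodes, "sample")
  max_rounds <- max_rounds %||% length(nodes)
  selected <- character(0)
  decisions <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    candidates <- setdiff(nodes, selected)
    if (!length(candidates) || round > max_rounds) break
    dec <- purrr::map_dfr(candidates, function(g) {
      classify_direct_effect(sample, g, skeleton, confounders,
                             fixed_set = selected, alpha = alpha,
                             max_sets = max_sets)
    })
    dec$iteration <- round
    decisions[[round]] <- dec
    new_direct <- dec$metabolite[dec$classification == "direct"]
    if (!length(new_direct)) break
    selected <- c(selected, sort(new_direct))
  }
  decisions <- dplyr::bind_rows(decisions)
  joint <- if (length(selected)) {
    joint_model(sample, selected, confounders)
  } else {
    NULL
  }
  structure(list(decisions = decisions, selected = sort(selected),
                 joint = joint, rounds = round, alpha = alpha),
            class = "netcoupler_result")
}

#' Final mutually adjusted joint Cox model over selected effectors
#'
#' One Prentice-weighted Cox fit including all selected metabolites as
#' simultaneous exposures plus the base confounders.  Collinearity among
#' the selected metabolites is diagnosed via the model-matrix condition
#' number before fitting.
#'
#' @param sample Case-cohort tibble with standardized metabolites.
#' @param selected Non-empty set of metabolite labels.
#' @param confounders Base adjustment columns.
#' @param max_condition Condition-number threshold (default 1e6).
#' @return A [`cc_cox`] object.
#' @export
joint_model <- function(sample, selected, confounders,
                        max_condition = 1e6) {
  if (!length(selected)) abort("`selected` must be non-empty")
  x <- as.matrix(sample[, selected, drop = FALSE])
  if (length(selected) > 1) {
    kappa_val <- kappa(crossprod(scale(x)), exact = TRUE)
    if (!is.finite(kappa_val) || kappa_val > max_condition) {
      abort(paste0("selected metabolites are (near-)collinear: ",
                   "condition number ", format(kappa_val, digits = 3)))
    }
  }
  fit_prentice_cox(sample, selected, confounders)
}

#' @export
print.netcoupler_result <- function(x, ...) {
  cat("<netcoupler_result> ", x$rounds, " round(s); selected: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
      "\n", sep = "")
  if (!is.null(x$joint)) print(x$joint)
  invisible(x)
}

#' @method tidy netcoupler_result
#' @export
tidy.netcoupler_result <- function(x, ...) x$decisions

#' @method glance netcoupler_result
#' @export
glance.netcoupler_result <- function(x, ...) {
  tibble(selected = length(x$selected), rounds = x$rounds, alpha = x$alpha)
}

#' Add total ceramide and dihydroceramide concentrations
#'
#' Per-class totals are computed on the raw concentration scale (sums of the
#' component species in nM) and appended as `total_Cer` / `total_dhCer`
#' columns; callers typically pass them through [log_z_transform()] so they
#' can serve as "total concentration" adjustment covariates.
#'
#' @param data Cohort tibble with raw metabolite columns.
#' @param cols Metabolite columns; defaults to every `Cer`/`dhCer` column.
#' @return `data` with `total_Cer` and `total_dhCer` columns appended.
#' @export
add_class_totals <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[grepl("^(Cer|dhCer)", names(data)) &
                                  vapply(data, is.numeric, logical(1))]
  dh <- cols[grepl("^dhCer", cols)]
  cer <- setdiff(cols, dh)
  if (length(cer)) {
    data$total_Cer <- rowSums(as.matrix(data[, cer, drop = FALSE]))
  }
  if (length(dh)) {
    data$total_dhCer <- rowSums(as.matrix(data[, dh, drop = FALSE]))
  }
  data
}
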