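#' Validate a pipeline run configuration
#'
#' Checks structure, thresholds and column references before any
#' computation; every problem found is reported at once.
#'
#' @param config Named list (or path to a YAML file) with elements
#'   `input` (either `type = "synthetic"` plus generator settings, or
#'   `type = "files"` plus `cohort` path), `endpoints`, `confounders`,
#'   `alpha` (`network`, `netcoupler`, `fdr`, `gwas`), `subcohort_fraction`,
#'   optional `mediation` (`exposure`, optional `unit`), optional
#'   `bootstrap` (`b`, `fraction`), `degree_cap`, `adjust_totals` (include
#'   log-z class totals in the base adjustment; default on for panels of 10+
#'   species, where a single species is a small share of its class total),
#'   `seed`, `output_dir`.
#' @return The normalised config list, invisibly; errors enumerate every
#'   validation failure.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)

  need(is.list(config$input), "`input` block missing")
  type <- config$input$type %||% "synthetic"
  need(type %in% c("synthetic", "files"), "input$type must be 'synthetic' or 'files'")
  config$input$type <- type

  config$endpoints <- config$endpoints %||% "t2d"
  config$confounders <- config$confounders %||% c("sex", "waist")
  config$subcohort_fraction <- config$subcohort_fraction %||% 0.25
  config$degree_cap <- config$degree_cap %||% 1024
  config$adjust_totals <- config$adjust_totals %||%
    (length(config$input$truth$nodes$metabolite %||% character(0)) >= 10)
  config$seed <- config$seed %||% 1L
  alpha <- config$alpha %||% list()
  config$alpha <- list(network = alpha$network %||% 0.05,
                       netcoupler = alpha$netcoupler %||% 0.05,
                       fdr = alpha$fdr %||% 0.05,
                       gwas = alpha$gwas %||% 1e-5)
  for (a in names(config$alpha)) {
    need(config$alpha[[a]] > 0 && config$alpha[[a]] < 1,
         paste0("alpha$", a, " must be in (0, 1)"))
  }
  need(config$subcohort_fraction > 0 && config$subcohort_fraction <= 1,
       "subcohort_fraction must be in (0, 1]")
  bs <- config$bootstrap %||% list()
  config$bootstrap <- list(b = bs$b %||% 1000, fraction = bs$fraction %||% 2/3)

  # column references must resolve before anything is computed
  known <- if (type == "synthetic") {
    tr <- config$input$truth
    need(is.null(tr) || inherits(tr, "lipid_truth"),
         "input$truth must be a lipid_truth object when given")
    conf_names <- if (inherits(tr, "lipid_truth")) {
      tr$confounders$confounder
    } else {
      c("sex", "waist")
    }
    conf_names
  } else {
    need(is.character(config$input$cohort), "input$cohort path missing")
    if (is.character(config$input$cohort) && file.exists(config$input$cohort)) {
      names(readr::read_tsv(config$input$cohort, n_max = 0,
                            show_col_types = FALSE))
    } else {
      need(FALSE, paste0("cohort file not found: ", config$input$cohort))
      character(0)
    }
  }
  unknown <- setdiff(config$confounders, known)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown confounder(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(config)
}

#' Run the full analysis pipeline from one declarative configuration
#'
#' Executes the stages in dependency order - simulate (or load), transform,
#' skeleton, single-metabolite screen, direct-effect classification,
#' mediation (if configured), Mendelian randomization (if the generating
#' model carries an instrument) - writing each stage's table to
#' `output_dir` as tab-separated text plus a machine-readable run manifest
#' (stage, output, seed, rows, seconds).  A failure in one endpoint's
#' branch is recorded in the manifest and does not disturb the other
#' endpoints' outputs.  Given the same configuration and seed, all output
#' tables are byte-identical across runs.
#'
#' @param config See [validate_config()].
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return Invisibly, a list with per-endpoint results and the manifest
#'   tibble.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir %||%
    stop("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, output, rows, secs) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, output = output, seed = config$seed,
      rows = rows, seconds = round(secs, 3))
  }
  timed <- function(stage, file, expr) {
    t0 <- proc.time()[3]
    val <- force(expr)
    rows <- if (is.data.frame(val)) nrow(val) else NA_integer_
    note(stage, file, rows, proc.time()[3] - t0)
    val
  }

  ## stage: cohort
  if (config$input$type == "synthetic") {
    truth <- config$input$truth %||% default_pipeline_truth()
    cohort <- timed("simulate", "cohort.tsv",
                    simulate_cohort(truth,
                                    n = config$input$n %||% 4000,
                                    case_fraction = config$input$case_fraction %||% 0.15,
                                    seed = config$seed))
  } else {
    truth <- NULL
    cohort <- timed("load", "cohort.tsv",
                    readr::read_tsv(config$input$cohort,
                                    show_col_types = FALSE))
  }
  write_tsv_plain(cohort, file.path(out_dir, "cohort.tsv"))
  if (!is.null(truth)) {
    write_tsv_plain(truth$edges, file.path(out_dir, "truth_edges.tsv"))
  }

  metabolites <- names(cohort)[grepl("^(Cer|dhCer)", names(cohort))]
  results <- list()
  for (ep in config$endpoints) {
    results[[ep]] <- tryCatch(
      run_endpoint_branch(config, cohort, metabolites, ep, out_dir,
                          truth, timed),
      error = function(e) {
        note(paste0("endpoint_", ep), NA_character_, NA_integer_, 0)
        warn(paste0("endpoint '", ep, "' failed: ", conditionMessage(e)))
        list(error = conditionMessage(e))
      })
  }

  manifest <- dplyr::bind_rows(manifest)
  write_tsv_plain(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(results = results, manifest = manifest,
                 output_dir = out_dir))
}

run_endpoint_branch <- function(config, cohort, metabolites, ep, out_dir,
                                truth, timed) {
  pref <- function(f) file.path(out_dir, paste0(ep, "_", f))
  cc <- timed("case_cohort", paste0(ep, "_sample.tsv"),
              draw_case_cohort(cohort, config$subcohort_fraction,
                               endpoint = ep, seed = config$seed))
  cc_tot <- add_class_totals(cc)
  tot_cols <- intersect(c("total_Cer", "total_dhCer"), names(cc_tot))
  # standardize on the representative scale: parameters from the random
  # subcohort, applied to the case-enriched analysis sample
  sub_params <- transform_params(
    log_z_transform(cc_tot[cc_tot$subcohort_member, , drop = FALSE],
                    cols = c(metabolites, tot_cols)))
  panel <- timed("transform", paste0(ep, "_panel_params.tsv"),
                 log_z_transform(cc_tot, cols = c(metabolites, tot_cols),
                                 params = sub_params))
  write_tsv_plain(transform_params(panel), pref("panel_params.tsv"))

  skel <- timed("network", paste0(ep, "_skeleton_edges.tsv"),
                pc_skeleton(panel, cols = metabolites,
                            alpha = config$alpha$network))
  write_skeleton(skel, file.path(out_dir, paste0(ep, "_skeleton")))

  # class totals as "total concentration" adjustments; identifiable only when
  # each species is a small share of its class, hence switchable
  base_conf <- if (isTRUE(config$adjust_totals)) {
    unique(c(config$confounders,
             intersect(c("total_Cer", "total_dhCer"), names(panel))))
  } else {
    config$confounders
  }
  screen <- timed("screen", paste0(ep, "_screen.tsv"),
                  single_lipid_screen(panel, metabolites,
                                      models = list(minimal = config$confounders[1],
                                                    full = base_conf),
                                      fdr = config$alpha$fdr))
  write_tsv_plain(screen, pref("screen.tsv"))

  nc <- timed("netcoupler", paste0(ep, "_decisions.tsv"),
              netcoupler(panel, skel, base_conf,
                         alpha = config$alpha$netcoupler,
                         max_sets = config$degree_cap))
  write_tsv_plain(nc$decisions, pref("decisions.tsv"))
  if (!is.null(nc$joint)) {
    write_tsv_plain(nc$joint$estimates, pref("joint_model.tsv"))
  }

  med <- NULL
  if (!is.null(config$mediation) && length(nc$selected)) {
    mcfg <- config$mediation
    joint_rows <- dplyr::filter(nc$joint$estimates, .data$exposure)
    signs <- stats::setNames(sign(joint_rows$log_hr), joint_rows$term)
    sel <- select_mediators(panel, mcfg$exposure, signs,
                            confounders = config$confounders)
    mediators <- sel$metabolite[sel$selected]
    if (length(mediators)) {
      med <- timed("mediation", paste0(ep, "_mediation.tsv"),
                   tidy(mediate_pe(panel, mcfg$exposure, mediators,
                                   config$confounders,
                                   exposure_unit = mcfg$unit %||% NULL,
                                   B = config$bootstrap$b,
                                   sampling_fraction = config$bootstrap$fraction,
                                   seed = config$seed)))
      write_tsv_plain(med, pref("mediation.tsv"))
    }
  }

  mr <- NULL
  if (!is.null(truth) && !is.null(truth$instrument)) {
    mr <- timed("mr", paste0(ep, "_mr.tsv"),
                synthetic_two_sample_mr(truth, config, ep))
    write_tsv_plain(mr, pref("mr.tsv"))
  }

  list(sample = cc, skeleton = skel, screen = screen, netcoupler = nc,
       mediation = med, mr = mr)
}

# Two independent samples from the same generating model: one for the
# SNP-exposure association (linear), one for SNP-outcome (logistic).
synthetic_two_sample_mr <- function(truth, config, ep,
                                    n_each = NULL) {
  n_each <- n_each %||% (config$input$n %||% 4000)
  s1 <- simulate_cohort(truth, n_each, seed = config$seed + 1000L)
  s2 <- simulate_cohort(truth, n_each, seed = config$seed + 2000L)
  target <- truth$instrument$target
  p1 <- log_z_transform(s1, cols = target)
  expo <- snp_association(p1, "dosage", target,
                          covariates = c("entry_age", "sex"),
                          snp = truth$instrument$snp,
                          effect_allele = truth$instrument$effect_allele,
                          other_allele = truth$instrument$other_allele)
  outc <- snp_association(s2, "dosage", paste0("event_", ep),
                          covariates = c("entry_age", "sex"),
                          snp = truth$instrument$snp,
                          effect_allele = truth$instrument$effect_allele,
                          other_allele = truth$instrument$other_allele,
                          family = "binomial")
  wald_ratio(harmonize_sumstats(expo, outc))
}

default_pipeline_truth <- function() {
  generate_ground_truth(
    p_cer = 4, p_dhcer = 4,
    effects = c("Cer18:0" = 0.4, "dhCer20:0" = 0.35),
    seed = 20260101)
}
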