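#' Construct the generating ground truth for a synthetic lipid cohort
#'
#' Builds the weighted directed acyclic graph (DAG) over a panel of ceramides
#' (`Cer`) and dihydroceramides (`dhCer`), together with the true per-1-SD log
#' hazard ratios, confounder loadings, diet-mediation structure and an optional
#' genetic instrument.  The object is the oracle against which network
#' recovery, effect classification, mediation and Mendelian-randomization
#' estimates are tested.
#'
#' Two built-in topologies are available.  `"elongation_chain"` mimics lipid
#' biochemistry: fatty-acid elongation links consecutive chain lengths within
#' each class, and desaturation links each dihydroceramide to the ceramide of
#' the same chain length.  `"random_sparse"` draws each forward edge
#' independently with probability `density`.  A custom edge list may be given
#' instead; it is rejected if cyclic.
#'
#' @param p_cer,p_dhcer Number of ceramide / dihydroceramide species (>= 1).
#' @param topology `"elongation_chain"`, `"random_sparse"`, or `"custom"`.
#' @param edge_weight_range Interval from which edge weights (log-scale linear
#'   effects) are drawn uniformly.  `c(0, 0)` produces an edgeless-equivalent
#'   model in which all metabolites are mutually independent given exogenous
#'   inputs.
#' @param density Forward-edge probability for `topology = "random_sparse"`.
#' @param edges Custom edge list (`data.frame` with `from`, `to`, optional
#'   `weight`) for `topology = "custom"`.
#' @param effects Named numeric vector of true direct log hazard ratios per
#'   1 SD (unnamed metabolites get 0), or a named list of such vectors, one
#'   per endpoint.
#' @param endpoints Endpoint labels; defaults to `"t2d"`.
#' @param confounders Data frame with columns `confounder`, `log_hr`, `var`
#'   (exogenous variance) describing observed confounders that load on both
#'   the metabolites and the hazard.  Default: `sex` (Bernoulli(0.5), hazard
#'   log-HR 0.3) and `waist` (standard normal, log-HR 0.4).
#' @param confounder_loadings Matrix (confounders x metabolites) of linear
#'   loadings on the log-metabolite scale; defaults to 0.2 for `sex`, 0.3 for
#'   `waist` on every metabolite.
#' @param mediation List of mediation blocks, each a list with `exposure`
#'   (label), `endpoint`, `coefs` (named numeric, exposure -> metabolite
#'   log-scale coefficients), and `direct_log_hr` (the non-mediated exposure
#'   effect).  Exposures are standard-normal diet variables.
#' @param instrument Optional list with `snp`, `maf` (in `[0.05, 0.5]`),
#'   `beta` (per-allele effect on the target metabolite's log scale, in units
#'   of its structural noise SD), `target` (metabolite label), and optional
#'   `effect_allele` / `other_allele`.
#' @param noise_sd Structural noise SD, recycled over metabolites.
#' @param seed Integer seed for the random topology / weights.
#'
#' @return An object of class `lipid_truth`: a list with `nodes`, `edges`,
#'   `effects`, `confounders`, `confounder_loadings`, `mediation`,
#'   `instrument`, `noise_sd`, `endpoints` and `seed`.
#' @seealso [simulate_cohort()], [implied_covariance()]
#' @export
#' @examples
#' truth <- generate_ground_truth(3, 3, effects = c("Cer18:0" = 0.4), seed = 1)
#' truth$edges
generate_ground_truth <- function(p_cer = 3, p_dhcer = 3,
                                  topology = c("elongation_chain",
                                               "random_sparse", "custom"),
                                  edge_weight_range = c(0.3, 0.6),
                                  density = 0.2,
                                  edges = NULL,
                                  effects = NULL,
                                  endpoints = "t2d",
                                  confounders = NULL,
                                  confounder_loadings = NULL,
                                  mediation = NULL,
                                  instrument = NULL,
                                  noise_sd = 1,
                                  seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(p_cer >= 1, p_dhcer >= 1, length(edge_weight_range) == 2,
            edge_weight_range[1] <= edge_weight_range[2])

  chains_cer <- seq(16, by = 2, length.out = p_cer)
  chains_dh  <- seq(16, by = 2, length.out = p_dhcer)
  nodes <- tibble(
    metabolite = c(paste0("Cer", chains_cer, ":0"),
                   paste0("dhCer", chains_dh, ":0")),
    class = rep(c("Cer", "dhCer"), c(p_cer, p_dhcer)),
    chain = c(chains_cer, chains_dh),
    double_bonds = 0L
  )
  if (anyDuplicated(nodes$metabolite)) abort("metabolite names must be unique")
  p <- nrow(nodes)
  # median concentrations spread over the observed nM range (0.2 - 42 nM)
  nodes$log_median <- log(seq(0.5, 40, length.out = p))

  draw_weight <- function(k) {
    runif(k, edge_weight_range[1], edge_weight_range[2])
  }

  edge_tbl <- with_seed(seed, {
    if (topology == "elongation_chain") {
      from <- to <- character(0)
      for (cl in c("Cer", "dhCer")) {
        m <- nodes$metabolite[nodes$class == cl]
        if (length(m) > 1) {
          from <- c(from, m[-length(m)])
          to <- c(to, m[-1])
        }
      }
      common <- intersect(chains_cer, chains_dh)
      from <- c(from, paste0("dhCer", common, ":0"))
      to <- c(to, paste0("Cer", common, ":0"))
      tibble(from = from, to = to, weight = draw_weight(length(from)))
    } else if (topology == "random_sparse") {
      idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
      keep <- runif(nrow(idx)) < density
      tibble(from = nodes$metabolite[idx[keep, 1]],
             to = nodes$metabolite[idx[keep, 2]],
             weight = draw_weight(sum(keep)))
    } else {
      if (is.null(edges)) abort("topology = 'custom' requires `edges`")
      e <- as_tibble(edges)
      assert_columns(e, c("from", "to"), "edges")
      if (!"weight" %in% names(e)) e$weight <- draw_weight(nrow(e))
      bad <- setdiff(c(e$from, e$to), nodes$metabolite)
      if (length(bad)) abort(paste("unknown nodes in edges:",
                                   paste(bad, collapse = ", ")))
      e
    }
  })

  if (is.null(topo_order(nodes$metabolite, edge_tbl))) {
    abort("requested edge structure is cyclic; the generating graph must be a DAG")
  }

  if (is.null(confounders)) {
    confounders <- tibble(confounder = c("sex", "waist"),
                          log_hr = c(0.3, 0.4),
                          var = c(0.25, 1))
  } else {
    confounders <- as_tibble(confounders)
    assert_columns(confounders, c("confounder", "log_hr", "var"), "confounders")
  }
  if (is.null(confounder_loadings)) {
    confounder_loadings <- matrix(
      rep(c(0.2, 0.3), length.out = nrow(confounders) * p),
      nrow = nrow(confounders), ncol = p, byrow = FALSE,
      dimnames = list(confounders$confounder, nodes$metabolite))
    if (all(c("sex", "waist") %in% confounders$confounder)) {
      confounder_loadings["sex", ] <- 0.2
      confounder_loadings["waist", ] <- 0.3
    }
  } else {
    stopifnot(nrow(confounder_loadings) == nrow(confounders),
              ncol(confounder_loadings) == p)
    dimnames(confounder_loadings) <- list(confounders$confounder,
                                          nodes$metabolite)
  }

  if (!is.list(effects) || is.null(names(effects)) ||
      is.numeric(effects)) {
    effects <- stats::setNames(rep(list(effects), length(endpoints)), endpoints)
  }
  eff_tbl <- purrr::map_dfr(endpoints, function(ep) {
    v <- stats::setNames(rep(0, p), nodes$metabolite)
    given <- effects[[ep]]
    if (!is.null(given)) {
      bad <- setdiff(names(given), nodes$metabolite)
      if (length(bad)) abort(paste("unknown metabolites in effects:",
                                   paste(bad, collapse = ", ")))
      v[names(given)] <- given
    }
    tibble(metabolite = names(v), endpoint = ep, log_hr = unname(v))
  })

  if (!is.null(mediation)) {
    for (m in mediation) {
      stopifnot(is.list(m), !is.null(m$exposure), !is.null(m$coefs))
      bad <- setdiff(names(m$coefs), nodes$metabolite)
      if (length(bad)) abort(paste("unknown mediator metabolites:",
                                   paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(instrument)) {
    stopifnot(!is.null(instrument$maf), !is.null(instrument$beta),
              !is.null(instrument$target))
    if (instrument$maf < 0.05 || instrument$maf > 0.5) {
      abort("instrument MAF must lie in [0.05, 0.5]")
    }
    if (!instrument$target %in% nodes$metabolite) {
      abort("instrument target is not in the metabolite panel")
    }
    instrument$snp <- instrument$snp %||% "rs0000001"
    instrument$effect_allele <- instrument$effect_allele %||% "A"
    instrument$other_allele <- instrument$other_allele %||% "G"
  }

  structure(list(
    nodes = nodes,
    edges = edge_tbl,
    effects = eff_tbl,
    confounders = confounders,
    confounder_loadings = confounder_loadings,
    mediation = mediation,
    instrument = instrument,
    noise_sd = rep_len(noise_sd, p),
    endpoints = endpoints,
    seed = seed
  ), class = "lipid_truth")
}

# Kahn topological sort; NULL if cyclic.
topo_order <- function(nodes, edges) {
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0)
  avail <- nodes[indeg == 0L]
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    if (nrow(edges)) {
      for (w in edges$to[edges$from == v]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) avail <- c(avail, w)
      }
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

#' @export
print.lipid_truth <- function(x, ...) {
  cat("<lipid_truth> ", nrow(x$nodes), " metabolites, ",
      nrow(x$edges), " edges; endpoints: ",
      paste(x$endpoints, collapse = ", "), "\n", sep = "")
  eff <- dplyr::filter(x$effects, .data$log_hr != 0)
  if (nrow(eff)) {
    cat("direct effects:\n")
    print(as.data.frame(eff), row.names = FALSE)
  }
  invisible(x)
}

#' Closed-form log-scale covariance implied by the generating model
#'
#' Solves the linear structural model for the stationary covariance of the
#' log-metabolite vector, accounting for network edges, confounder loadings,
#' diet exposures and the genetic instrument:
#' \eqn{\Sigma = (I - B^\top)^{-1} (\Lambda \Sigma_\xi \Lambda^\top + D)
#' (I - B^\top)^{-\top}} where \eqn{B} holds edge weights, \eqn{\Lambda}
#' exogenous loadings and \eqn{D} the structural noise variances.
#'
#' @param truth A [generate_ground_truth()] object.
#' @return A p x p covariance matrix with metabolite dimnames.
#' @export
implied_covariance <- function(truth) {
  stopifnot(inherits(truth, "lipid_truth"))
  nodes <- truth$nodes$metabolite
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(truth$edges)) {
    B[cbind(match(truth$edges$from, nodes),
            match(truth$edges$to, nodes))] <- truth$edges$weight
  }
  # exogenous inputs: confounders, diet exposures, instrument dosage
  lam <- t(truth$confounder_loadings)          # p x n_conf
  xi_var <- truth$confounders$var
  if (!is.null(truth$mediation)) {
    for (m in truth$mediation) {
      v <- rep(0, p)
      v[match(names(m$coefs), nodes)] <- m$coefs
      lam <- cbind(lam, v)
      xi_var <- c(xi_var, 1)
    }
  }
  if (!is.null(truth$instrument)) {
    v <- rep(0, p)
    v[match(truth$instrument$target, nodes)] <- truth$instrument$beta
    lam <- cbind(lam, v)
    xi_var <- c(xi_var, 2 * truth$instrument$maf * (1 - truth$instrument$maf))
  }
  inner <- lam %*% (diag(xi_var, length(xi_var)) %*% t(lam)) +
    diag(truth$noise_sd^2, p)
  A <- solve(diag(p) - t(B))
  sigma <- A %*% inner %*% t(A)
  dimnames(sigma) <- list(nodes, nodes)
  sigma
}
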