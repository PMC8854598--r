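# Shared fixture builders.  All data are generated in code at test time.

# Ground truth whose confounders neither load on metabolites nor on the
# hazard: isolates the network / effect machinery under test.
quiet_truth <- function(p_cer = 3, p_dhcer = 3, ...) {
  p <- p_cer + p_dhcer
  generate_ground_truth(
    p_cer, p_dhcer, ...,
    confounders = tibble::tibble(confounder = c("sex", "waist"),
                                 log_hr = c(0, 0), var = c(0.25, 1)),
    confounder_loadings = matrix(0, 2, p))
}

# Population correlation matrix of a linear-Gaussian SEM with unit noise,
# computed directly from the path coefficients (independent closed form).
sem_cor <- function(nodes, edges) {
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    B[cbind(match(edges$from, nodes), match(edges$to, nodes))] <- edges$weight
  }
  A <- solve(diag(p) - t(B))
  stats::cov2cor(A %*% t(A))
}

# Standardized case-cohort panel from a truth object, one call.  Transform
# parameters come from the representative random subcohort and are applied
# to the case-enriched sample (cases are oversampled, so sample-level
# standardization would inflate the scale).
cc_panel <- function(truth, n, subcohort_fraction = 0.25,
                     case_fraction = 0.15, seed = 1,
                     endpoint = "t2d") {
  cohort <- simulate_cohort(truth, n, case_fraction = case_fraction,
                            seed = seed)
  cc <- draw_case_cohort(cohort, subcohort_fraction, endpoint = endpoint,
                         seed = seed + 1L)
  params <- transform_params(
    log_z_transform(cc[cc$subcohort_member, , drop = FALSE]))
  log_z_transform(cc, params = params)
}

# Two columns with an exact sample correlation r (n-point construction).
exact_cor_pair <- function(n, r, seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  zx <- as.numeric(scale(x))
  ze <- as.numeric(scale(e))
  tibble::tibble(x = zx, y = r * zx + sqrt(1 - r^2) * ze)
}

# Hand-built skeleton object (for enumeration tests that need a fixed graph).
manual_skeleton <- function(nodes, edge_pairs, alpha = 0.05, n = 1000) {
  edges <- if (length(edge_pairs)) {
    do.call(rbind, lapply(edge_pairs, function(e) {
      data.frame(from = min(e), to = max(e))
    })) |> tibble::as_tibble()
  } else {
    tibble::tibble(from = character(), to = character())
  }
  structure(list(nodes = nodes, edges = edges, sepsets = list(),
                 alpha = alpha, n = n),
            class = "lipid_skeleton")
}
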