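#' Fisher-z test of conditional independence
#'
#' Tests whether variables `x` and `y` are conditionally independent given
#' the set `given`, from the partial correlation r computed via the precision
#' of the correlation submatrix.  The test statistic is
#' \eqn{\sqrt{n - |S| - 3}\,|z|} with \eqn{z = \tfrac12 \log\{(1+r)/(1-r)\}},
#' referred to the standard normal (two-sided).
#'
#' Either a data frame or a precomputed correlation matrix with its sample
#' size may be supplied; the latter enables population-oracle tests from a
#' model-implied covariance.
#'
#' @param data Data frame holding the variables (ignored if `cor` given).
#' @param x,y Variable names.
#' @param given Character vector of conditioning variables (may be empty).
#' @param alpha Significance level; independence is declared when p > alpha.
#' @param cor Optional correlation matrix with dimnames.
#' @param n Sample size (required with `cor`).
#' @return One-row tibble: `x`, `y`, `r` (partial correlation), `statistic`,
#'   `p`, `independent`.
#' @export
#' @examples
#' d <- tibble::tibble(a = rnorm(100), b = rnorm(100))
#' fisher_z_test(d, "a", "b")
fisher_z_test <- function(data = NULL, x, y, given = character(),
                          alpha = 0.05, cor = NULL, n = NULL) {
  if (x == y) abort("x and y must differ")
  if (x %in% given || y %in% given) {
    abort("conditioning set must not contain x or y")
  }
  if (is.null(cor)) {
    vars <- c(x, y, given)
    assert_columns(data, vars, "data")
    n <- nrow(data)
    cor <- stats::cor(as.matrix(data[, vars, drop = FALSE]))
  }
  if (n - length(given) - 3 <= 0) {
    abort("need n - |S| - 3 > 0 for the Fisher-z test")
  }
  r <- partial_cor_from_cor(cor, x, y, given)
  res <- fisher_z_eval(r, n, length(given), alpha)
  tibble(x = x, y = y, r = r, statistic = res$statistic, p = res$p,
         independent = res$independent)
}

partial_cor_from_cor <- function(cmat, x, y, given) {
  sub <- cmat[c(x, y, given), c(x, y, given), drop = FALSE]
  omega <- tryCatch(solve(sub), error = function(e) {
    MASS_ginv_fallback(sub)
  })
  -omega[1, 2] / sqrt(omega[1, 1] * omega[2, 2])
}

# pseudo-inverse fallback for numerically singular conditioning sets
MASS_ginv_fallback <- function(m) {
  s <- svd(m)
  tol <- max(dim(m)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

fisher_z_eval <- function(r, n, s_size, alpha) {
  if (!is.finite(r)) r <- 0
  if (abs(r) >= 1) {
    # perfectly collinear pair: dependent with p = 0, no transform overflow
    return(list(statistic = Inf, p = 0, independent = FALSE))
  }
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - s_size - 3) * abs(z)
  p <- 2 * pnorm(-stat)
  list(statistic = stat, p = p, independent = p > alpha)
}

#' Estimate the conditional-independence skeleton (stable PC variant)
#'
#' Learns the undirected skeleton of the metabolite panel: an edge joins two
#' variables whose covariance cannot be explained away by conditioning on any
#' subset of the remaining variables at significance level `alpha`.  Uses the
#' order-independent ("stable") PC variant: at each conditioning-set size the
#' neighbour sets are frozen at the start of the level and edge deletions are
#' applied only after the level completes, so the edge set is invariant to
#' the input column order.  Separation sets are recorded for every deleted
#' edge.
#'
#' @param data Standardized panel data frame (ignored when `cor` supplied).
#' @param cols Panel columns; defaults to the panel's recorded metabolites,
#'   else every `Cer`/`dhCer` numeric column, else all numeric columns.
#' @param alpha Significance level of the Fisher-z tests (default 0.05).
#' @param max_order Maximum conditioning-set size (default unlimited).
#' @param cor Optional correlation matrix with dimnames (population-oracle
#'   use); requires `n`.
#' @param n Sample size accompanying `cor`.
#' @return Object of class `lipid_skeleton`: list with `nodes`, `edges`
#'   (tibble `from` < `to`), `sepsets` (named list), `alpha`, `n`.
#' @export
#' @examples
#' truth <- generate_ground_truth(3, 3, seed = 1)
#' sk <- pc_skeleton(cor = stats::cov2cor(implied_covariance(truth)), n = 1e6)
#' tidy(sk)
pc_skeleton <- function(data = NULL, cols = NULL, alpha = 0.05,
                        max_order = Inf, cor = NULL, n = NULL) {
  if (is.null(cor)) {
    cols <- cols %||% attr(data, "metabolites") %||% {
      cands <- names(data)[grepl("^(Cer|dhCer)", names(data)) &
                             vapply(data, is.numeric, logical(1))]
      if (length(cands)) cands else
        names(data)[vapply(data, is.numeric, logical(1))]
    }
    assert_columns(data, cols, "data")
    n <- nrow(data)
    if (n <= length(cols) + 3) abort("need n > p + 3 for skeleton estimation")
    cor <- stats::cor(as.matrix(data[, cols, drop = FALSE]))
  } else {
    if (is.null(n)) abort("`n` is required when `cor` is supplied")
    cols <- colnames(cor)
  }
  p <- length(cols)
  adj <- matrix(TRUE, p, p, dimnames = list(cols, cols))
  diag(adj) <- FALSE
  sepsets <- list()

  l <- 0L
  repeat {
    snapshot <- adj
    nbr_count <- function(i, j) sum(snapshot[i, ]) - as.integer(snapshot[i, j])
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs) == 0) break
    testable <- apply(pairs, 1, function(pr) {
      max(nbr_count(pr[1], pr[2]), nbr_count(pr[2], pr[1])) >= l
    })
    if (!any(testable) || l > max_order) break
    remove <- matrix(integer(0), ncol = 2)
    for (k in which(testable)) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      found <- FALSE
      for (anchor in list(c(i, j), c(j, i))) {
        nbrs <- setdiff(which(snapshot[anchor[1], ]), anchor[2])
        if (length(nbrs) < l) next
        subsets <- if (l == 0L) list(integer(0)) else
          utils::combn(sort(nbrs), l, simplify = FALSE)
        for (S in subsets) {
          r <- partial_cor_from_cor(cor, cols[i], cols[j], cols[S])
          res <- fisher_z_eval(r, n, length(S), alpha)
          if (res$independent) {
            key <- paste(sort(c(cols[i], cols[j])), collapse = "|")
            sepsets[[key]] <- cols[S]
            remove <- rbind(remove, c(i, j))
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    if (nrow(remove)) {
      for (k in seq_len(nrow(remove))) {
        adj[remove[k, 1], remove[k, 2]] <- FALSE
        adj[remove[k, 2], remove[k, 1]] <- FALSE
      }
    }
    l <- l + 1L
  }

  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble(from = cols[e[, 1]], to = cols[e[, 2]]) |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(nodes = cols, edges = edges, sepsets = sepsets,
                 alpha = alpha, n = n),
            class = "lipid_skeleton")
}

#' Direct network neighbours of a node
#'
#' @param skeleton A [pc_skeleton()] object.
#' @param node Node label.
#' @return Character vector of adjacent nodes (possibly empty).
#' @export
skeleton_neighbors <- function(skeleton, node) {
  stopifnot(inherits(skeleton, "lipid_skeleton"))
  if (!node %in% skeleton$nodes) {
    abort(paste0("unknown node '", node, "'"))
  }
  e <- skeleton$edges
  sort(unique(c(e$to[e$from == node], e$from[e$to == node])))
}

#' @export
print.lipid_skeleton <- function(x, ...) {
  cat("<lipid_skeleton> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (alpha = ", x$alpha, ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @method tidy lipid_skeleton
#' @export
tidy.lipid_skeleton <- function(x, ...) x$edges

#' @method glance lipid_skeleton
#' @export
glance.lipid_skeleton <- function(x, ...) {
  tibble(nodes = length(x$nodes), edges = nrow(x$edges),
         alpha = x$alpha, n = x$n)
}

#' Write / read a skeleton as plain text
#'
#' The edge list goes to `<stem>_edges.tsv` (`node_a`, `node_b`) and the
#' separation-set log to `<stem>_sepsets.tsv` (`node_a`, `node_b`,
#' `separation_set` comma-joined).
#'
#' @param skeleton A [pc_skeleton()] object.
#' @param stem Path stem (no extension).
#' @return The stem, invisibly.
#' @export
write_skeleton <- function(skeleton, stem) {
  write_tsv_plain(
    dplyr::rename(skeleton$edges, node_a = "from", node_b = "to"),
    paste0(stem, "_edges.tsv"))
  ss <- skeleton$sepsets
  sep_tbl <- if (length(ss)) {
    parts <- strsplit(names(ss), "|", fixed = TRUE)
    tibble(node_a = purrr::map_chr(parts, 1),
           node_b = purrr::map_chr(parts, 2),
           separation_set = purrr::map_chr(ss, paste, collapse = ","))
  } else {
    tibble(node_a = character(), node_b = character(),
           separation_set = character())
  }
  write_tsv_plain(sep_tbl, paste0(stem, "_sepsets.tsv"))
  invisible(stem)
}
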