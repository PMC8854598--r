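#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by ungroup summarise across all_of pull row_number n
#' @importFrom stats var sd cor qnorm pnorm pt rnorm runif rbinom rweibull quantile lm glm coef vcov complete.cases uniroot p.adjust model.matrix as.formula binomial setNames
#' @importFrom utils combn head
NULL

# Seeded evaluation that restores the caller's RNG state afterwards, so
# package functions never disturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Column(s) not found in ", what, ": ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Tab-separated writer used by every stage so that re-runs are byte-identical.
write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
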