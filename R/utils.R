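# Internal helpers: classed conditions and scoped RNG state.

config_error <- function(msg, field = NULL) {
  abort(msg, class = "convotrace_config_error", field = field)
}

data_error <- function(msg, class = NULL) {
  abort(msg, class = c(class, "convotrace_data_error"))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' generator calls are reproducible without clobbering the session stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# truncated normal via inverse-CDF; vectorised over mean
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    data_error(sprintf("%s is missing required column(s): %s", what,
                       paste(missing, collapse = ", ")),
               class = "convotrace_schema_error")
  }
  invisible(df)
}
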