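#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif median sd setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom tools file_path_sans_ext
NULL

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_not_scalar_prob <- function(x, what) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
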