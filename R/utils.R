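#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rpois sd lm glm coef pnorm prcomp
#'   chisq.test fisher.test t.test setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

## Run an expression under a fixed RNG seed, restoring the caller's RNG
## state afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))
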