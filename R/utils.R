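#' @importFrom methods is
#' @importFrom stats cor cor.test loess median p.adjust pnorm predict quantile
#'   rbinom rnbinom rpois runif sd setNames var wilcox.test
#' @importFrom utils read.table write.table
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
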