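#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rnbinom rlnorm runif quantile sd var predict
#'   setNames
#' @importFrom utils read.csv write.csv read.delim write.table head
#' @importFrom graphics abline barplot hist par
#' @importFrom methods as is
NULL

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_validation <- function(...) {
  stop(structure(class = c("reactcr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("reactcr_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Round half away from zero at `digits` decimals (display convention for
# reported metrics; R's round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
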