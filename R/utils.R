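#' @importFrom stats rbinom rnbinom rpois runif rnorm kmeans pchisq setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods as
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a named per-stage random seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' (tissue generation, contamination, clustering, ...) draws from its own
#' substream so stages can be re-run in isolation reproducibly.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31, a deterministic function of both
#'   arguments.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Library-size normalisation to a common target sum per cell (CP10K-style).
# Cells with zero total are left at zero.
normalize_counts <- function(counts, target = 1e4) {
  cs <- Matrix::colSums(counts)
  sf <- ifelse(cs > 0, target / cs, 0)
  counts %*% Matrix::Diagonal(x = sf, n = length(sf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
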