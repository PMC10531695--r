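#' @importFrom stats cor dnorm median pnorm prcomp qnorm quantile rbeta rbinom
#'   rchisq rnorm runif sd setNames t.test var p.adjust predict kmeans rgamma
#' @importFrom utils head read.table write.table
#' @importFrom rlang %||% abort warn
NULL

# Run code under a temporary RNG state; the caller's stream is untouched.
local_rng <- function(seed, code) {
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

# Deterministic per-stage substream seeds derived from one global seed.
# Keeps results of one stage invariant to RNG consumption in another.
seed_stream <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483587L)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

# Stable default identifiers
genotype_ids <- function(n) sprintf("G%03d", seq_len(n))
marker_ids <- function(m) sprintf("M%05d", seq_len(m))
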