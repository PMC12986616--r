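#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm qnorm rnorm runif rpois rbinom uniroot median
#'   sd var fft kmeans prcomp pchisq pt qt setNames aggregate complete.cases
#'   kruskal.test chisq.test t.test lm shapiro.test rlnorm mvfft
#' @importFrom utils read.csv write.csv head tail
NULL

# Deterministic per-module substream seeds: a single study seed is expanded by
# hashing the stream label, so adding a modality never perturbs another
# modality's draws. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 1013904223) %% 2147483563) + 1L
}

# Run an expression under a locally-seeded RNG without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  force(seed)  # evaluate caller RNG draws in `seed` before saving state
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) stop(sprintf(...), call. = FALSE)
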