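#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats var sd cor lm coef pt pf qnorm quantile rnorm runif setNames
#' @importFrom utils head tail
NULL

# Derive a reproducible 32-bit sub-seed from a master seed and a stream index.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() never overflows.
substream_seed <- function(master, stream) {
  master <- as.numeric(master)
  stream <- as.numeric(stream)
  ((master %% 2147483629) * 48271 + stream * 1000003 + 12345) %% 2147483629 + 1
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not <- function(cond, msg, class = "ttcqtl_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

# Haldane map function: recombination fraction from distance in cM.
haldane_r <- function(d_cM) 0.5 * (1 - exp(-d_cM / 50))

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
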