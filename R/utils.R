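#' Derive a per-stage random seed from a run seed
#'
#' All stochastic stages draw their seed deterministically from a single run
#' seed plus the stage name, so an entire sweep is reproducible from one
#' integer. The rule is a 31-ary polynomial hash of the stage name folded
#' into the run seed modulo 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage character stage name, e.g. `"extract"` or `"train:3"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1L, "extract")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 65011
  as.integer((abs(as.numeric(seed)) * 69821 + h * 131071) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero: the single quantization rule used wherever
# intensities are mapped back to integers (bit-stable across platforms,
# unlike base round()'s banker's rounding).
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(x) all(x == 0 | x == 1)

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
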