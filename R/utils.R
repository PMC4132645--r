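#' Derive a stage-specific random seed
#'
#' Every stochastic operation in the package draws from its own seeded stream.
#' Stage seeds are derived deterministically from a global seed and a stage
#' name so that a single top-level seed reproduces an entire pipeline while
#' stages remain statistically decoupled.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"cohort"` or `"subject-17"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "cohort")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage),
            length(stage) == 1L)
  x <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    x <- (x * 31 + ch) %% 2147483647
  }
  as.integer(x)
}

# population-style standard deviation (denominator n)
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# dispatchable sd used in sweep summaries
sd_by_type <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  if (type == "population") sd_pop(x) else stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# index matrix (n x 3) -> linear indices into an array of dimension dims
linear_index <- function(idx, dims) {
  stopifnot(is.matrix(idx), ncol(idx) == 3L)
  as.integer(idx[, 1L] + (idx[, 2L] - 1L) * dims[1L] +
               (idx[, 3L] - 1L) * dims[1L] * dims[2L])
}
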