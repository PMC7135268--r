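#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package functions never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Counter-based derivation: child seeds for shuffle `index` (and an optional
#' stream id) are a deterministic function of the master seed, so every
#' shuffle is independently re-runnable.  Result stays below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param index Non-negative counter (e.g. shuffle number).
#' @param stream Optional second counter separating uses within one shuffle.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, 3)
derive_seed <- function(master, index, stream = 0L) {
  m <- 2147483647
  x <- (abs(as.double(master)) %% m)
  # two rounds of a Lehmer-style mix keep nearby (master, index) pairs apart
  x <- (x * 48271 + as.double(index) * 9973 + as.double(stream) * 997 + 1) %% m
  x <- (x * 16807 + 12345) %% m
  as.integer(x)
}

sigmoid <- function(x) plogis(x)

#' @noRd
assert_binary <- function(y, arg = "y") {
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary 0/1 vector without missing values.", arg))
  }
  invisible(y)
}

#' @noRd
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    abort("`X` must be a numeric matrix or a data frame of numeric columns.")
  }
  X
}

#' Feature order used across the package
#' @return Character vector of the seven clinical covariate names.
#' @export
cohort_features <- function() {
  c("age", "sex", "nihss", "cardiac", "diabetes",
    "hypercholesterolemia", "thrombolysis")
}
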