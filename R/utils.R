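#' Derive a reproducible substream seed from a global seed and string keys
#'
#' Expands one global seed into independent per-entity random streams by a
#' stable polynomial hash of the key strings, so that generation order never
#' affects the numbers an entity receives.
#'
#' @param seed integer global seed.
#' @param ... character or numeric keys identifying the substream
#'   (e.g. sample id, antibody id).
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @keywords internal
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m)
  for (key in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(key)))) {
      # h * 127 + ch stays < 2^53, so double arithmetic is exact
      h <- (h * 127 + ch) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

#' Run code under a local RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check that a value is a single finite number
#' @keywords internal
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}
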