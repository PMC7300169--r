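#' Physical decay constant of 177Lu
#'
#' Decay constant in 1/h corresponding to the 6.647-day physical half-life
#' of 177Lu: `log(2) / (6.647 * 24)`.
#'
#' @return Decay constant in 1/h (about 0.0043450).
#' @export
#' @examples
#' log(2) / lu177_lambda_phys() / 24  # physical half-life in days
lu177_lambda_phys <- function() {
  log(2) / (6.647 * 24)
}

## Deterministic stream seed from a base seed and a vector of integer ids.
## Polynomial mixing mod (2^31 - 1); intermediate products stay below 2^53
## so double arithmetic is exact.
.mix_seed <- function(seed, ids) {
  m <- 2147483647
  h <- as.double(seed) %% m
  for (k in as.double(ids)) {
    h <- (h * 69069 + abs(k) + 1) %% m
  }
  as.integer(h)
}

## Triangular variates; mode equals the distribution's most likely value.
.rtriangular <- function(n, min, mode, max) {
  stopifnot(min < max, min <= mode, mode <= max)
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  lower <- u < fc
  x <- numeric(n)
  x[lower] <- min + sqrt(u[lower] * (max - min) * (mode - min))
  x[!lower] <- max - sqrt((1 - u[!lower]) * (max - min) * (max - mode))
  x
}

## Short fingerprint of an arbitrary R object (for output provenance
## headers). Polynomial rolling hash over the deparsed object.
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (i in seq_along(b)) {
    h <- (h * 31 + b[i]) %% m
  }
  sprintf("%08x", as.integer(h))
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
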