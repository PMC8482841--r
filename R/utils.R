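#' @keywords internal
"_PACKAGE"

# Small internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ef <- function(...) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

is_prop <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

# Central-difference numerical Hessian.  Used for observed-information
# standard errors; step scales with parameter magnitude.
num_hessian <- function(fn, x, eps = 1e-4, ...) {
  k <- length(x)
  h <- eps * (abs(x) + 1)
  H <- matrix(0, k, k)
  f0 <- fn(x, ...)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- h[i]; ej[j] <- h[j]
      fpp <- fn(x + ei + ej, ...)
      fpm <- fn(x + ei - ej, ...)
      fmp <- fn(x - ei + ej, ...)
      fmm <- fn(x - ei - ej, ...)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
    }
  }
  H
}

num_gradient <- function(fn, x, eps = 1e-6, ...) {
  h <- eps * (abs(x) + 1)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (fn(x + e, ...) - fn(x - e, ...)) / (2 * h[i])
  }, numeric(1))
}

# Cheap string hash (djb2-style, mod 2^31) used for provenance stamps so
# runs can be matched to their configuration without extra dependencies.
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_hash <- function(cfg) {
  string_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE))
}

#' @importFrom stats predict coef vcov simulate residuals
NULL
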