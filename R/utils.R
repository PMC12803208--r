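# Internal helpers shared across modules.

# Deterministic 32-bit seed derived from a base seed plus arbitrary tags
# (strings or integers). Polynomial rolling hash mod (2^31 - 1); all
# intermediate values stay below 2^53 so double arithmetic is exact.
mix_seed <- function(seed, ...) {
  parts <- unlist(list(...), use.names = FALSE)
  h <- as.double(as.integer(seed) %% 2147483647L)
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.integer(p)
    for (cd in codes) h <- (h * 31 + as.double(cd) + 1) %% 2147483647
  }
  as.integer(h)
}

# Analytic signal of a real series via the frequency-domain construction:
# zero the negative frequencies, double the positive ones, inverse FFT.
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Column-standardize so that crossprod() of two standardized matrices gives
# Pearson correlations: center each column and scale to unit 2-norm.
standardize_columns <- function(m, what = "matrix") {
  m <- sweep(m, 2L, colMeans(m))
  nrm <- sqrt(colSums(m^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop(sprintf("constant column(s) in %s (undefined correlation): %s",
                 what, paste(utils::head(bad, 5L), collapse = ", ")))
  }
  sweep(m, 2L, nrm, "/")
}

upper_tri_values <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a
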