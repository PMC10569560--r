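# Small numerical helpers shared across modules.

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector.
#' @return scalar log-sum-exp.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Shift a vector forward by k bins, zero-padding at the start, so that
# lag0(v, k)[t] == v[t - k] for t > k and 0 otherwise.
lag0 <- function(v, k) {
  if (k == 0L) return(v)
  n <- length(v)
  if (k >= n) return(numeric(n))
  c(numeric(k), v[seq_len(n - k)])
}

# Deterministic child seed derived from a master seed and a stream index.
# Keeps results reproducible when one master seed drives many independent
# random sub-tasks (restarts, neurons, trials). Stays below 2^31.
derive_seed <- function(master, stream) {
  m <- as.double(master) %% 2147483647
  s <- as.double(stream) %% 2147483647
  as.integer((m * 48271 + s * 16807 + 12345) %% 2147483629) + 1L
}

# Population variance (divide by length, not length - 1); used by the
# explained-variance statistic so the ratio is fixed under one convention.
pop_var <- function(x) mean((x - mean(x))^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
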