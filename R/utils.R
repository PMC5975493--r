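#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Reporting convention for percentages: round half-up to a fixed number of
#' decimals (base R's \code{round()} rounds half to even, which would turn
#' 14.85 into 14.8 rather than 14.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage, per-tissue seeds through a
#' fixed polynomial string hash, so any stage can be re-run in isolation and
#' reproduce the full run's draws. Results stay within the 32-bit integer
#' range R requires of \code{set.seed()}.
#'
#' @param seed integer global seed.
#' @param key character label of the stage (e.g. \code{"cohort:liver"}).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  m <- 2147483647
  h <- as.double(abs(as.integer(seed))) %% m
  for (ch in utf8ToInt(as.character(key))) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# Largest-remainder apportionment: integer counts summing to n with
# proportions p (deterministic; remainders broken by order of p).
apportion <- function(n, p) {
  if (abs(sum(p) - 1) > 1e-8) stopf("proportions must sum to 1 (got %.6f)", sum(p))
  if (any(p < 0)) stopf("proportions must be non-negative")
  k <- floor(n * p)
  r <- n * p - k
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(r, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

# Structured one-line stage log (message-based so callers can suppress).
log_stage <- function(stage, ...) {
  kv <- list(...)
  body <- paste(sprintf("%s=%s", names(kv), unlist(kv, use.names = FALSE)),
                collapse = " ")
  message(sprintf("[%s] %s", stage, body))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
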