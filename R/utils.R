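# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check x is a probability-like scalar
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

# row-normalise a non-negative matrix onto the simplex
row_normalise <- function(m) m / rowSums(m)

# clip frequencies away from {0,1} so log terms stay finite
clip_freq <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Standard error from a Wald confidence interval
#'
#' Recovers the standard error of an estimate from a symmetric Wald interval,
#' `SE = (high - low) / (2 * z)`. For odds-ratio intervals apply on the log
#' scale (take `log()` of the endpoints first).
#'
#' @param low,high interval endpoints, `high > low`.
#' @param level confidence level of the interval (default 0.95).
#' @return A positive scalar standard error.
#' @examples
#' se_from_ci(-1.96, 1.96) # 1
#' @export
se_from_ci <- function(low, high, level = 0.95) {
  if (!is.numeric(low) || !is.numeric(high) || high <= low)
    stop_named("se_from_ci: 'high' (%s) must exceed 'low' (%s)",
               format(high), format(low))
  if (!is_prob(level) || level <= 0 || level >= 1)
    stop_named("se_from_ci: 'level' must be in (0,1)")
  (high - low) / (2 * stats::qnorm((1 + level) / 2))
}
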