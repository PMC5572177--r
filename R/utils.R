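# Shared numerical helpers.
#
# Discounting convention used throughout the package: annual-step weights
# (1 + rate)^(-k) for follow-up year k (0-indexed), so the first year is
# undiscounted. All estimators (RMST, costs, extrapolation, Markov) share it.

discount_weight <- function(year, rate) (1 + rate)^(-year)

stop_if_not_scalar <- function(x, name, lower = -Inf, upper = Inf,
                               allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' must be supplied", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' = %g outside [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  invisible(NULL)
}

# Integral of a right-continuous step function over [0, tau] with yearly
# discount weights: sum over segments of w(floor(a)) * S(a) * (b - a).
# `times`/`values`: step function S(t) = values[i] on [times[i], times[i+1]).
# Segments are split at integer year marks so each lies in one discount year.
step_discounted_integral <- function(times, values, tau, rate) {
  stopifnot(length(times) == length(values), tau > 0)
  cuts <- sort(unique(c(0, times[times < tau], seq_len(ceiling(tau)) - 1, tau)))
  cuts <- cuts[cuts >= 0 & cuts <= tau]
  a <- cuts[-length(cuts)]
  b <- cuts[-1]
  sf <- if (length(times) == 0L) function(t) rep(1, length(t))
        else stepfun(times, c(1, values), right = FALSE)
  sum(discount_weight(floor(a), rate) * sf(a) * (b - a))
}

# Polynomial rolling hash (mod 2^31 - 1, exact in doubles) of a character
# vector; used to stamp outputs with a configuration digest.
text_digest <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}
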