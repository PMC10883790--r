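## Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prop <- function(x, open_lo = FALSE, open_hi = FALSE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (open_lo) x > 0 else x >= 0) && (if (open_hi) x < 1 else x <= 1)
}

#' Largest-remainder apportionment
#'
#' Distributes `n` integer units over categories proportionally to `weights`,
#' using the largest-remainder rule so the result sums exactly to `n`.
#' Ties in the remainders are broken toward earlier categories.
#'
#' @param weights non-negative numeric weights, at least one positive
#' @param n total count to distribute
#' @return integer vector, same length as `weights`, summing to `n`
#' @keywords internal
largest_remainder <- function(weights, n) {
  stopifnot(all(weights >= 0), sum(weights) > 0, is_count(n) || n == 0)
  share <- weights / sum(weights) * n
  base <- floor(share)
  left <- as.integer(round(n - sum(base)))
  if (left > 0L) {
    # rank() with ties.method = "first" keeps the allocation deterministic
    extra <- rank(-(share - base), ties.method = "first") <= left
    base <- base + as.integer(extra)
  }
  as.integer(base)
}

## Sample skewness (Fisher-Pearson, no small-sample correction).
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

## Decimal years between two Date vectors (365.25-day years).
decimal_years <- function(from, to) {
  as.numeric(difftime(to, from, units = "days")) / 365.25
}
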