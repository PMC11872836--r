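#' @importFrom stats pt qnorm cor sd var rnorm runif plogis qlogis setNames
#' @importFrom utils head
NULL

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

#' Significance stars for a p-value
#'
#' Maps p-values onto the conventional star annotation used on enrichment
#' figures: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001,
#' empty string otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of the same length.
#' @export
#' @examples
#' p_stars(c(0.2, 0.04, 0.004, 4e-4, 4e-5))
p_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[p < 0.05]   <- "*"
  out[p < 0.01]   <- "**"
  out[p < 0.001]  <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

# Welch two-sample t-test computed explicitly so degenerate (zero-variance)
# inputs follow a defined policy instead of erroring:
#   both groups constant, equal means    -> t = 0, p = 1, flagged
#   zero pooled SE but different means   -> t = +/-Inf, p = 0, flagged
# Orientation: positive t means mean(x) > mean(y).
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2L, ny >= 2L)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  flagged <- FALSE
  if (se2 <= 0) {
    flagged <- TRUE
    if (mx == my) {
      t <- 0; df <- nx + ny - 2; p <- 1
    } else {
      t <- sign(mx - my) * Inf; df <- nx + ny - 2; p <- 0
    }
  } else {
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  }
  list(mean_x = mx, mean_y = my, mean_diff = mx - my,
       se = sqrt(max(se2, 0)), t = t, df = df, p = p, flagged = flagged)
}

# Signed standard-normal statistic from a two-sided p and a sign:
# z = sign * qnorm(1 - p/2), capped so p underflow never yields Inf.
z_from_p <- function(p, sign_of, cap = 40) {
  z <- qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
  z <- pmin(z, cap)
  z * sign(sign_of)
}
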