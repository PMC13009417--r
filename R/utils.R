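#' @importFrom data.table := data.table as.data.table setDT setorder setnames
#'   copy rbindlist CJ nafill shift fifelse setkey .N .SD set setattr uniqueN
#' @importFrom stats plogis qlogis rnorm runif rbinom pnorm quantile sd
#'   uniroot complete.cases
NULL

# day grid: all dates are integer day offsets from 2010-01-01 ("epoch day 0");
# months are half-open 30-day windows [30t, 30(t+1)) from the baseline day
DAYS_PER_MONTH <- 30L
FOLLOWUP_MONTHS <- 24L
FOLLOWUP_DAYS <- 720L

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop2("configuration error: '", name, "' must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop2("configuration error: '", name, "' must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# inverse-ECDF (type 1) quantile: an order statistic of x, optionally with
# nonnegative case weights (used so the truncation cap is an observed weight)
quantile_type1 <- function(x, prob, w = NULL) {
  stopifnot(length(prob) == 1L, prob >= 0, prob <= 1)
  if (is.null(w)) {
    sx <- sort(x)
    return(sx[max(1L, ceiling(prob * length(sx)))])
  }
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= prob - 1e-12)[1L]]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# floor of the probability scale used before inverting fitted probabilities
PROB_FLOOR <- 1e-6

month_of_day <- function(day) as.integer(day %/% DAYS_PER_MONTH)

# weighted mean and its (Hajek) standard error; w are sampling weights
weighted_mean_se <- function(y, w) {
  sw <- sum(w)
  m <- sum(w * y) / sw
  se <- sqrt(sum((w * (y - m))^2)) / sw
  c(mean = m, se = se)
}
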