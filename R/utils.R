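#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft lm mad median pf pt qt quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv head tail
NULL

# Angular (great-circle) distance in degrees between rows of two unit-vector
# matrices, or between one vector and a matrix of unit vectors.
angular_distance <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  d <- tcrossprod(a, b)
  d[d > 1] <- 1
  d[d < -1] <- -1
  deg <- acos(d) * 180 / pi
  if (nrow(a) == 1L || nrow(b) == 1L) as.vector(deg) else deg
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Lower median: for even n returns the n/2-th order statistic.
lower_median_index <- function(x) {
  order(x)[(length(x) + 1L) %/% 2L]
}

# Strict local maxima of a numeric vector (interior samples only).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

# Strict local minima.
local_minima <- function(x) local_maxima(-x)
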