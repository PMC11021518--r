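## Brute-force oracles, independent of the package implementations.

## quantile by explicit order-statistic interpolation, h = (n - 1) p + 1
bruteQuantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

bruteQCD <- function(x) {
  q1 <- bruteQuantile(x, 0.25); q3 <- bruteQuantile(x, 0.75)
  (q3 - q1) / (q3 + q1)
}

bruteCV <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

## closed-form simple OLS from sums
bruteOLS <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

## all-pairs maximum distance between pixel centres
bruteFeret <- function(mask) {
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) == 1) return(0)
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

## default calibrated parameters (memoised inside the package)
wtParams <- function() wildTypeParams()
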