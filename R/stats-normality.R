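#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino (1970) transformed skewness statistic and the
#' Anscombe-Glynn (1983) transformed kurtosis statistic into the omnibus
#' K^2 = Zs^2 + Zk^2, referred to a chi-squared distribution with 2 df.
#' Quantile-quantile coordinates against the standard normal are attached
#' for the visual screen that conventionally accompanies this test.
#'
#' @param x numeric sample, n >= 8.
#' @return object of class `htest` with `statistic` (K2), `p.value`,
#'   `parameter` (df = 2), components `z_skew`, `z_kurt`, and `qq` (a
#'   data.frame of theoretical and sample quantiles).
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("dagostino_pearson: need at least 8 observations")
  if (sd(x) == 0) stop("dagostino_pearson: constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  p <- pchisq(k2, df = 2, lower.tail = FALSE)

  qq <- data.frame(theoretical = qnorm(stats::ppoints(n)),
                   sample = sort((x - m) / sqrt(m2 * n / (n - 1))))

  structure(list(statistic = c(K2 = k2), parameter = c(df = 2),
                 p.value = p, z_skew = z_skew, z_kurt = z_kurt, qq = qq,
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}
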