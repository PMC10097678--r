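#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor cor.test dnorm fft lm median nls optim
#'   pnorm predict qchisq qnorm qt quantile rbinom residuals rnorm runif sd
#'   t.test uniroot var vcov mad setNames p.adjust
#' @importFrom utils head tail read.csv write.csv
#' @importFrom graphics lines
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap angles (degrees) into [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

## signed circular difference a - b in (-180, 180]
circ_diff_deg <- function(a, b) {
  d <- wrap360(a - b)
  ifelse(d > 180, d - 360, d)
}

#' Circular mean and resultant length of angles in degrees
#'
#' @param deg numeric vector of angles in degrees.
#' @return list with `mean_deg` in [0, 360) and resultant length `R` in [0, 1].
#' @export
circular_mean_deg <- function(deg) {
  stopifnot(length(deg) >= 1, all(is.finite(deg)))
  th <- deg2rad(deg)
  s <- mean(sin(th)); c <- mean(cos(th))
  list(mean_deg = wrap360(rad2deg(atan2(s, c))), R = sqrt(s^2 + c^2))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is uniformly distributed on the circle.
#' The statistic is z = n * Rbar^2 with the standard small-sample correction
#' for the p-value, p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n)),
#' where Rn = n * Rbar.
#'
#' @param deg numeric vector of angles in degrees.
#' @return list with `z`, `p`, `n`, `Rbar`.
#' @export
rayleigh_test <- function(deg) {
  n <- length(deg)
  stopifnot(n >= 2, all(is.finite(deg)))
  Rbar <- circular_mean_deg(deg)$R
  Rn <- n * Rbar
  z <- n * Rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(max(p, 0), 1)
  list(z = z, p = p, n = n, Rbar = Rbar)
}

## von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform.
## mu in degrees; returns degrees in [0, 360).
rvonmises_deg <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap360(mu_deg + rad2deg(out))
}

## ray-casting point-in-polygon; polygon as two numeric vectors
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((poly_y[i] > py) != (poly_y[j] > py)) &&
        (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
           (poly_y[j] - poly_y[i]) + poly_x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
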