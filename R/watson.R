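## Dimroth-Watson axial distribution on the sphere: density proportional to
## exp(kappa * (mu . x)^2). The natural nematic analogue of the
## von-Mises-Fisher distribution; used by the synthetic generator for axis
## dispersion about the reference field.

#' Sample axes from a Watson distribution
#'
#' Rejection sampling of the bipolar Dimroth-Watson distribution with mean
#' axis `mu` and concentration `kappa >= 0` (`kappa = 0` is the isotropic
#' axis distribution). Returned vectors are unit length; as axes they are
#' defined up to sign.
#'
#' @param n number of samples.
#' @param mu length-3 mean axis (any nonzero length).
#' @param kappa concentration (dimensionless, >= 0).
#' @return n x 3 matrix of unit vectors.
#' @export
rwatson <- function(n, mu = c(0, 0, 1), kappa = 0) {
  stopifnot(kappa >= 0, n >= 0)
  mu <- as.numeric(mu) / sqrt(sum(mu^2))
  t <- numeric(n)
  filled <- 0
  while (filled < n) {
    m <- max(2 * (n - filled), 16)
    prop <- stats::runif(m, -1, 1)
    acc <- stats::runif(m) < exp(kappa * (prop^2 - 1))
    got <- prop[acc]
    take <- min(length(got), n - filled)
    if (take > 0) t[filled + seq_len(take)] <- got[seq_len(take)]
    filled <- filled + take
  }
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - t^2))
  ## orthonormal frame about mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- as.numeric(cross_rows(mu, ref)); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- as.numeric(cross_rows(mu, e1))
  outer(t, mu) + outer(s * cos(phi), e1) + outer(s * sin(phi), e2)
}

#' Expected nematic order of a Watson ensemble
#'
#' `E[(3 cos^2(theta) - 1) / 2]` for `cos(theta)` distributed with density
#' proportional to `exp(kappa t^2)` on `[-1, 1]`, computed by numerical
#' quadrature. This is the alignment parameter S obtained when Watson-
#' distributed axes are compared against their mean axis.
#'
#' @param kappa concentration (>= 0).
#' @return scalar expected order parameter.
#' @export
watson_order_parameter <- function(kappa) {
  ## integrand scaled by exp(-kappa) for numerical stability at large kappa
  num <- stats::integrate(function(t) (1.5 * t^2 - 0.5) * exp(kappa * (t^2 - 1)),
                          -1, 1, rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) exp(kappa * (t^2 - 1)),
                          -1, 1, rel.tol = 1e-10)$value
  num / den
}

#' Sample directions uniformly on the unit sphere
#' @param n number of samples.
#' @return n x 3 matrix of unit vectors.
#' @export
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}
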