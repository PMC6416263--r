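#' Associated Legendre function P_l^m
#'
#' Evaluates the associated Legendre function by the standard stable upward
#' recurrence (with the Condon-Shortley phase), vectorized over `x`.
#'
#' @param l degree (non-negative integer).
#' @param m order, `0 <= m <= l`.
#' @param x evaluation points in `[-1, 1]`.
#' @return numeric vector of `P_l^m(x)`.
#' @keywords internal
.assocLegendre <- function(l, m, x) {
  stopifnot(m >= 0, m <= l)
  # P_m^m = (-1)^m (2m-1)!! (1 - x^2)^(m/2)
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in seq(m + 2, l)) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Real part of the orthonormal spherical harmonic Y_l^m
#'
#' Evaluates `Re{Y_l^m(theta, phi)}` with the orthonormal normalization
#' `sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!) * P_l^m(cos theta) * cos(m phi)`,
#' where `P_l^m` is the associated Legendre function.  This is the angular
#' law whose lobes become the spiculations of the tumor phantoms.
#'
#' @param degreeL harmonic degree `l` (non-negative integer).
#' @param orderM harmonic order `m`, `0 <= m <= l`.
#' @param theta polar angle(s) in radians, in `[0, pi]`.
#' @param phi azimuthal angle(s) in radians.
#' @return numeric vector of `Re{Y_l^m}` values (recycled over
#'   `theta`/`phi`).
#' @examples
#' sphericalHarmonicY(0, 0, 0.3, 1.2) # 1/sqrt(4*pi)
#' @export
sphericalHarmonicY <- function(degreeL, orderM, theta, phi) {
  degreeL <- as.integer(degreeL)
  orderM <- as.integer(orderM)
  if (length(degreeL) != 1L || length(orderM) != 1L || degreeL < 0L ||
      orderM < 0L || orderM > degreeL) {
    stop("invalid harmonic parameters: need 0 <= orderM <= degreeL")
  }
  if (any(theta < -1e-12 | theta > pi + 1e-12)) {
    stop("theta must lie in [0, pi]")
  }
  norm <- sqrt(
    (2 * degreeL + 1) / (4 * pi) *
      exp(lfactorial(degreeL - orderM) - lfactorial(degreeL + orderM))
  )
  norm * .assocLegendre(degreeL, orderM, cos(theta)) * cos(orderM * phi)
}

#' Radial profile of a spiculated phantom
#'
#' The phantom surface is the star-shaped radial law
#' `rho(theta, phi) = d + A * Re{Y_l^m(theta, phi)} / normalizer`, where the
#' normalizer is the maximum of `|Re{Y_l^m}|` over the sampling grid used
#' for meshing, so that the spikes have amplitude exactly `A` on the sampled
#' surface and `d - A <= rho <= d + A` everywhere.
#'
#' @param spec a [HarmonicSpec-class].
#' @param theta polar angle(s) in radians.
#' @param phi azimuthal angle(s) in radians.
#' @param normalizer positive scalar, `max |Re{Y_l^m}|` over the sampling
#'   grid.
#' @return radius values in model units.
#' @export
radialProfile <- function(spec, theta, phi, normalizer) {
  stopifnot(is(spec, "HarmonicSpec"))
  if (!is.numeric(normalizer) || length(normalizer) != 1L || normalizer <= 0) {
    stop("normalizer must be a single positive number")
  }
  y <- sphericalHarmonicY(spec@degreeL, spec@orderM, theta, phi)
  spec@spiculationD + spec@amplitudeA * y / normalizer
}
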