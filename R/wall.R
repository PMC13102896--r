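#' Olufsen arterial wall model
#'
#' The elastic wall behaviour of every 1D vessel is described by the
#' Olufsen stiffness-radius law together with an elastic pressure-area
#' relation. The effective stiffness is
#' \deqn{Eh/r_0 = k_1 \exp(k_2 r_0) + k_3,}
#' so small vessels (large \eqn{\exp(k_2 r_0)} for negative \eqn{k_2})
#' are relatively stiffer than central elastic arteries. The transmural
#' pressure follows
#' \deqn{p(A) = p_0 + \tfrac{4}{3}\,(Eh/r_0)\,(1 - \sqrt{A_0/A}),}
#' where \eqn{A_0} is the reference (zero-distension) lumen area at
#' pressure \eqn{p_0}.
#'
#' @param k1,k2,k3 Olufsen coefficients. `k1` and `k3` in Pa, `k2` in 1/m
#'   (negative for the physiological stiffness increase towards small
#'   radii).
#' @param rho blood density in kg/m^3.
#' @param p0 reference pressure in Pa at which the lumen area equals the
#'   reference area `A0`.
#' @return `wall_model()` returns a list of class `cvpd_wall` holding the
#'   coefficients.
#' @examples
#' w <- wall_model()
#' olufsen_stiffness(5e-3, w)
#' tube_law(1.1 * 7e-5, 7e-5, 4.7e-3, w)
#' @export
wall_model <- function(k1 = 2.0e6, k2 = -2253, k3 = 8.65e4,
                       rho = 1055, p0 = 1.0e4) {
  w <- list(k1 = k1, k2 = k2, k3 = k3, rho = rho, p0 = p0)
  class(w) <- "cvpd_wall"
  w
}

#' @param r0 reference radius in m (scalar or vector).
#' @param wall a `cvpd_wall` object from [wall_model()].
#' @rdname wall_model
#' @export
olufsen_stiffness <- function(r0, wall) {
  stopifnot(all(r0 > 0))
  f0 <- wall$k1 * exp(wall$k2 * r0) + wall$k3
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stop("invalid wall: non-positive stiffness Eh/r0 at r0 = ",
         paste(signif(r0[f0 <= 0 | !is.finite(f0)], 4), collapse = ", "),
         call. = FALSE)
  }
  f0
}

#' @param A lumen cross-sectional area in m^2.
#' @param A0 reference lumen area in m^2.
#' @rdname wall_model
#' @export
tube_law <- function(A, A0, r0, wall) {
  stopifnot(all(A > 0), all(A0 > 0))
  f0 <- olufsen_stiffness(r0, wall)
  wall$p0 + (4 / 3) * f0 * (1 - sqrt(A0 / A))
}

#' Inverse of the pressure-area relation
#'
#' Returns the lumen area at a given transmural pressure. Only defined
#' below the finite pressure asymptote `p0 + (4/3) Eh/r0`.
#'
#' @inheritParams tube_law
#' @param p transmural pressure in Pa.
#' @export
tube_law_inverse <- function(p, A0, r0, wall) {
  f0 <- olufsen_stiffness(r0, wall)
  s <- 1 - 3 * (p - wall$p0) / (4 * f0)
  if (any(s <= 0)) {
    stop("pressure at or beyond the tube-law asymptote", call. = FALSE)
  }
  A0 / s^2
}

#' Local pulse wave speed of the elastic tube
#'
#' \eqn{c = \sqrt{(A/\rho)\,dp/dA}} with the closed-form derivative of
#' the Olufsen pressure-area relation,
#' \eqn{dp/dA = \tfrac{2}{3}(Eh/r_0)\sqrt{A_0}\,A^{-3/2}}.
#'
#' @inheritParams tube_law
#' @param rho blood density in kg/m^3; defaults to the wall model value.
#' @export
wave_speed <- function(A, A0, r0, wall, rho = wall$rho) {
  f0 <- olufsen_stiffness(r0, wall)
  dpdA <- (2 / 3) * f0 * sqrt(A0) / A^1.5
  sqrt(A / rho * dpdA)
}
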