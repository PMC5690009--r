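#' TG-43 line-source geometry function G_L(r, theta)
#'
#' Evaluates the line-source approximation geometry function
#' \deqn{G_L(r,\theta) = \beta / (L\, r \sin\theta)}
#' where \eqn{\beta} is the angle (radians) subtended by the active length
#' \eqn{L} at the calculation point, computed from the two endpoint angles.
#' On the source long axis (\eqn{\theta = 0} or \eqn{180} degrees, where the
#' general expression is 0/0) the closed form
#' \eqn{G_L = (r^2 - L^2/4)^{-1}} is used; the two poles are equivalent by
#' symmetry of the line segment.
#'
#' @param r distance from the source center, cm. Vectorised.
#' @param theta polar angle from the source long axis, degrees in
#'   \[0, 180\]. Vectorised (recycled against `r`).
#' @param L active source length, cm.
#' @param pole_eps angles within `pole_eps` degrees of 0 or 180 are routed to
#'   the on-axis branch. Default 1e-4 degrees.
#' @return G_L(r, theta) in cm^-2.
#' @examples
#' geometry_factor(1, 0, L = 0.5)            # 1 / (1 - 0.0625)
#' geometry_factor(2, 90, L = 1e-4)          # ~ 1/r^2 point-source limit
#' @export
geometry_factor <- function(r, theta, L, pole_eps = 1e-4) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("active length L must be a single positive number (cm)")
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(!is.finite(r)) || any(!is.finite(theta)))
    stop("r and theta must be finite")
  if (any(theta < 0 | theta > 180))
    stop("theta outside [0, 180] degrees")
  if (any(r <= 0))
    stop("r must be positive")

  pole <- theta <= pole_eps | theta >= 180 - pole_eps
  # a point lies on the source segment iff it is on the axis with |z| <= L/2
  if (any(pole & r <= L / 2 + .Machine$double.eps))
    stop("point lies on the source segment (r*sin(theta)=0, |r*cos(theta)| <= L/2)")

  out <- numeric(n)
  out[pole] <- 1 / (r[pole]^2 - L^2 / 4)

  gen <- !pole
  if (any(gen)) {
    th <- theta[gen] * pi / 180
    rg <- r[gen]
    cth <- cos(th)
    sth <- sin(th)
    # distances from the point to the two source ends (z = +L/2 and -L/2)
    d_plus <- sqrt(rg^2 + L^2 / 4 - L * rg * cth)
    d_minus <- sqrt(rg^2 + L^2 / 4 + L * rg * cth)
    a1 <- acos(pmin(1, pmax(-1, (rg * cth - L / 2) / d_plus)))
    a2 <- acos(pmin(1, pmax(-1, (rg * cth + L / 2) / d_minus)))
    beta <- a1 - a2
    out[gen] <- beta / (L * rg * sth)
  }
  out
}
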