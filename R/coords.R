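#' Convert away/along Cartesian coordinates to polar source coordinates
#'
#' The Cartesian frame is centered on the middle of the source active core:
#' `y` is the away (transverse) coordinate and `z` the along coordinate
#' (signed, along the source long axis). The polar angle theta is measured
#' from the configured 0-degree end of the axis: `zero_toward = "+z"` puts
#' theta = 0 in the +z direction, `"-z"` in the -z direction.
#'
#' @param y away coordinate(s), cm.
#' @param z along coordinate(s), cm.
#' @param zero_toward `"+z"` or `"-z"`: direction of the 0-degree pole.
#' @return data.frame with columns `r` (cm) and `theta` (degrees in
#'   \[0, 180\]).
#' @examples
#' cartesian_to_polar(0.25, -2, zero_toward = "-z")  # ~ (2 cm, 7 deg)
#' @export
cartesian_to_polar <- function(y, z, zero_toward = c("+z", "-z")) {
  zero_toward <- match.arg(zero_toward)
  n <- max(length(y), length(z))
  y <- rep_len(as.numeric(y), n)
  z <- rep_len(as.numeric(z), n)
  if (any(y == 0 & z == 0))
    stop("the origin has no polar representation")
  zs <- if (zero_toward == "+z") z else -z
  data.frame(
    r = sqrt(y^2 + z^2),
    theta = atan2(abs(y), zs) * 180 / pi
  )
}

#' Convert polar source coordinates to away/along Cartesian coordinates
#'
#' Inverse of [cartesian_to_polar()]; reconstructs (|y|, z) exactly (the
#' polar pair does not retain the sign of the away coordinate).
#'
#' @param r radius, cm.
#' @param theta polar angle, degrees in \[0, 180\].
#' @inheritParams cartesian_to_polar
#' @return data.frame with columns `y` (>= 0) and `z`, cm.
#' @export
polar_to_cartesian <- function(r, theta, zero_toward = c("+z", "-z")) {
  zero_toward <- match.arg(zero_toward)
  n <- max(length(r), length(theta))
  r <- rep_len(as.numeric(r), n)
  theta <- rep_len(as.numeric(theta), n)
  if (any(r <= 0)) stop("r must be positive")
  if (any(theta < 0 | theta > 180)) stop("theta outside [0, 180] degrees")
  th <- theta * pi / 180
  z <- r * cos(th)
  if (zero_toward == "-z") z <- -z
  data.frame(y = r * sin(th), z = z)
}
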