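#' Physical source model for the TG-43 formalism
#'
#' Bundles the physical quantities of a sealed HDR source needed by the
#' line-source dose engine: active length L, dose-rate constant Lambda,
#' air-kerma strength Sk, and the reference point (r0, theta0) at which the
#' formalism is normalised (conventionally 1 cm on the transverse axis).
#'
#' The polar angle is measured from the source long axis; the
#' `theta_zero_orientation` flag records which physical end of the source the
#' 0-degree direction points to. The AAPM convention puts 0 degrees toward the
#' source tip, while vendor anisotropy tables are frequently indexed with 0
#' degrees on the cable side; the flag makes the convention explicit so tables
#' from either camp can be compared without silent pole swaps.
#'
#' @param active_length_L active source length, cm.
#' @param dose_rate_constant_Lambda dose-rate constant, cGy h^-1 U^-1.
#' @param air_kerma_strength_Sk air-kerma strength, U (1 U = 1 uGy m^2 h^-1).
#' @param r0 reference distance, cm (default 1.0). Must exceed L/2.
#' @param theta0 reference angle, degrees (default 90).
#' @param theta_zero_orientation which physical end the angle 0 deg points to:
#'   `"tip"` (AAPM convention) or `"cable"` (common vendor-table convention).
#' @return An object of class `source_model`.
#' @export
source_model <- function(active_length_L = 0.5,
                         dose_rate_constant_Lambda = 1.101,
                         air_kerma_strength_Sk = 1,
                         r0 = 1.0,
                         theta0 = 90,
                         theta_zero_orientation = c("tip", "cable")) {
  theta_zero_orientation <- match.arg(theta_zero_orientation)
  stopifnot(
    is.numeric(active_length_L), length(active_length_L) == 1L, active_length_L > 0,
    is.numeric(dose_rate_constant_Lambda), dose_rate_constant_Lambda > 0,
    is.numeric(air_kerma_strength_Sk), air_kerma_strength_Sk > 0,
    is.numeric(r0), length(r0) == 1L,
    is.numeric(theta0), length(theta0) == 1L
  )
  if (r0 <= active_length_L / 2)
    stop("reference distance r0 must exceed L/2")
  if (theta0 <= 0 || theta0 > 90)
    stop("theta0 must lie in (0, 90] degrees")
  structure(
    list(
      active_length_L = active_length_L,
      dose_rate_constant_Lambda = dose_rate_constant_Lambda,
      air_kerma_strength_Sk = air_kerma_strength_Sk,
      r0 = r0,
      theta0 = theta0,
      theta_zero_orientation = theta_zero_orientation
    ),
    class = "source_model"
  )
}

#' @export
print.source_model <- function(x, ...) {
  cat("TG-43 source model\n")
  cat(sprintf("  active length L      : %g cm\n", x$active_length_L))
  cat(sprintf("  dose-rate constant   : %g cGy/h/U\n", x$dose_rate_constant_Lambda))
  cat(sprintf("  air-kerma strength Sk: %g U\n", x$air_kerma_strength_Sk))
  cat(sprintf("  reference point      : (%g cm, %g deg)\n", x$r0, x$theta0))
  cat(sprintf("  theta = 0 deg toward : %s\n", x$theta_zero_orientation))
  invisible(x)
}
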