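#' TG-43 line-source dose engine
#'
#' Binds a [source_model()], a [radial_dose_model()] and an
#' [anisotropy_table()] into a dose engine implementing the TG-43
#' line-source approximation
#' \deqn{\dot D(r,\theta) = S_k \Lambda
#'   \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)} g_L(r) F(r,\theta).}
#'
#' @param source a [source_model()].
#' @param g a [radial_dose_model()].
#' @param F an [anisotropy_table()].
#' @param label short label used in reports (e.g. `"reference"`, `"vendor"`).
#' @return An object of class `tg43_engine`.
#' @export
tg43_engine <- function(source, g, F, label = F$provenance) {
  stopifnot(inherits(source, "source_model"),
            inherits(g, "radial_dose_model"),
            inherits(F, "anisotropy_table"))
  G0 <- geometry_factor(source$r0, source$theta0, source$active_length_L)
  structure(
    list(source = source, g = g, F = F, G0 = G0,
         label = if (is.null(label) || !nzchar(label)) "engine" else label),
    class = "tg43_engine"
  )
}

#' Single-dwell dose rate per the TG-43 line-source approximation
#'
#' @param r distance(s) from the source center, cm.
#' @param theta polar angle(s) from the source long axis, degrees.
#' @param engine a [tg43_engine()].
#' @return dose rate in cGy/h (per the engine's Sk).
#' @examples
#' src <- source_model()
#' g <- make_radial_model("flat")
#' F <- make_reference_anisotropy(synthetic_anisotropy_spec())
#' eng <- tg43_engine(src, g, F)
#' dose_rate(1, 90, eng)  # = Sk * Lambda at the reference point
#' @export
dose_rate <- function(r, theta, engine) {
  stopifnot(inherits(engine, "tg43_engine"))
  src <- engine$source
  G <- geometry_factor(r, theta, src$active_length_L)
  src$air_kerma_strength_Sk * src$dose_rate_constant_Lambda *
    (G / engine$G0) *
    radial_dose(r, engine$g) *
    anisotropy_lookup(r, theta, engine$F)
}

#' Transverse-axis dose rate per unit air-kerma strength
#'
#' Closed form for the dose rate on the transverse axis (theta = theta0)
#' divided by Sk:
#' \deqn{\dot D(r,\theta_0)/S_k = \Lambda\,
#'   \frac{G_L(r,\theta_0)}{G_L(r_0,\theta_0)}\, g_L(r).}
#' Used as the denominator when extracting an anisotropy function from an
#' along-away dose-rate table, avoiding any interpolation in the transverse
#' profile.
#'
#' @param r radius, cm (vectorised); must exceed L/2.
#' @param source a [source_model()].
#' @param g a [radial_dose_model()].
#' @return dose rate per unit Sk, cGy h^-1 U^-1.
#' @export
transverse_axis_dose <- function(r, source, g) {
  stopifnot(inherits(source, "source_model"),
            inherits(g, "radial_dose_model"))
  G0 <- geometry_factor(source$r0, source$theta0, source$active_length_L)
  source$dose_rate_constant_Lambda *
    geometry_factor(r, source$theta0, source$active_length_L) / G0 *
    radial_dose(r, g)
}

#' @export
print.tg43_engine <- function(x, ...) {
  cat(sprintf("TG-43 line-source dose engine [%s]\n", x$label))
  print(x$source)
  print(x$g)
  print(x$F)
  invisible(x)
}
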