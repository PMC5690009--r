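#' Along-away dose-rate table
#'
#' Dose rate per unit air-kerma strength tabulated on a Cartesian grid about
#' the source: `y` is the away (transverse) coordinate, `z` the along
#' coordinate (signed, zero at the center of the active core). The matrix is
#' indexed `values[z, y]`. Grid points falling on or too close to the source
#' segment carry `NA`.
#'
#' @param y_values ascending away coordinates, cm.
#' @param z_values ascending along coordinates, cm.
#' @param values matrix `length(z_values)` x `length(y_values)` of dose rate
#'   per unit Sk, cGy h^-1 U^-1; positive or `NA`.
#' @param provenance free-text label.
#' @return An object of class `alongaway_table` with attribute `n_points`
#'   (count of finite entries).
#' @export
alongaway_table <- function(y_values, z_values, values, provenance = "") {
  y_values <- as.numeric(y_values)
  z_values <- as.numeric(z_values)
  values <- as.matrix(values)
  if (any(diff(y_values) <= 0) || any(diff(z_values) <= 0))
    stop("y and z axes must be strictly increasing")
  if (!all(dim(values) == c(length(z_values), length(y_values))))
    stop(sprintf("values must be a %d x %d matrix (z x y)",
                 length(z_values), length(y_values)))
  if (any(values[is.finite(values)] <= 0))
    stop("all tabulated dose rates must be positive")
  structure(
    list(y_values = y_values, z_values = z_values, values = values,
         n_points = sum(is.finite(values)), provenance = provenance),
    class = "alongaway_table"
  )
}

#' @export
print.alongaway_table <- function(x, ...) {
  cat(sprintf("along-away dose-rate table%s: %d x %d grid, %d valid points\n",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else "",
              length(x$z_values), length(x$y_values), x$n_points))
  cat(sprintf("  y (away) : %g .. %g cm\n", min(x$y_values), max(x$y_values)))
  cat(sprintf("  z (along): %g .. %g cm\n", min(x$z_values), max(x$z_values)))
  invisible(x)
}

# default along-away grid: 13 away values x 28 along values (z symmetric
# about the active-core center, no z = 0 row); the two on-axis points inside
# the singular zone (y = 0, z = +/-0.25) are excluded, leaving 362 valid
# reference points.
default_alongaway_y <- function()
  c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 5, 7)
default_alongaway_z <- function() {
  half <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 8)
  c(-rev(half), half)
}

#' Generate an along-away dose-rate table from a dose engine
#'
#' Evaluates `dose_rate / Sk` from a TG-43 engine at every (y, z) grid
#' point. Points within `exclusion_radius` of the source center (the
#' singular zone containing the active core) are excluded and carry `NA`.
#' With the default grid this produces exactly 362 valid reference points.
#'
#' @param engine a [tg43_engine()].
#' @param y_values,z_values grid coordinates, cm (defaults give 362 points).
#' @param exclusion_radius points with r below this radius are excluded;
#'   default `L/2 + 0.05` cm.
#' @param zero_toward direction of the 0-degree pole of the engine's F
#'   table: `"+z"` or `"-z"`.
#' @return an [alongaway_table()].
#' @export
make_alongaway <- function(engine,
                           y_values = default_alongaway_y(),
                           z_values = default_alongaway_z(),
                           exclusion_radius = NULL,
                           zero_toward = c("-z", "+z")) {
  stopifnot(inherits(engine, "tg43_engine"))
  zero_toward <- match.arg(zero_toward)
  src <- engine$source
  if (is.null(exclusion_radius))
    exclusion_radius <- src$active_length_L / 2 + 0.05
  yy <- matrix(y_values, length(z_values), length(y_values), byrow = TRUE)
  zz <- matrix(z_values, length(z_values), length(y_values))
  r <- sqrt(yy^2 + zz^2)
  th <- atan2(abs(yy), if (zero_toward == "+z") zz else -zz) * 180 / pi
  vals <- matrix(NA_real_, length(z_values), length(y_values))
  ok <- r > exclusion_radius
  vals[ok] <- dose_rate(r[ok], th[ok], engine) / src$air_kerma_strength_Sk
  alongaway_table(y_values, z_values, vals,
                  provenance = paste0("synthetic-", engine$label))
}

#' Extract the 2D anisotropy function from an along-away table
#'
#' Applies the formal TG-43 definition of F(r, theta) to a tabulated
#' along-away dose-rate table:
#' \deqn{F(r,\theta) = \frac{(\dot D(r,\theta)/S_k)\; G_L(r,\theta_0)}
#'   {(\dot D(r,\theta_0)/S_k)\; G_L(r,\theta)}}
#' with the transverse-axis denominator taken from the closed form of
#' [transverse_axis_dose()] so that no interpolation of the table itself is
#' needed on the transverse axis. Each Cartesian grid point keeps its (y, z)
#' index with the polar equivalent attached — note the change of
#' coordinates: the result lives on the (y, z)-derived polar points, not on
#' a regular (r, theta) grid.
#'
#' @param table an [alongaway_table()].
#' @param source a [source_model()].
#' @param g a [radial_dose_model()].
#' @param exclusion_radius points with r below this radius are skipped
#'   (default `L/2 + 0.05` cm).
#' @param zero_toward direction of the 0-degree pole: `"+z"` or `"-z"`.
#' @return data.frame of class `anisotropy_points` with columns
#'   `y, z, r, theta, F`. The number of skipped points is attached as
#'   attribute `n_skipped`.
#' @export
extract_anisotropy <- function(table, source, g,
                               exclusion_radius = NULL,
                               zero_toward = c("-z", "+z")) {
  stopifnot(inherits(table, "alongaway_table"),
            inherits(source, "source_model"),
            inherits(g, "radial_dose_model"))
  zero_toward <- match.arg(zero_toward)
  if (is.null(exclusion_radius))
    exclusion_radius <- source$active_length_L / 2 + 0.05
  yy <- matrix(table$y_values, length(table$z_values), length(table$y_values),
               byrow = TRUE)
  zz <- matrix(table$z_values, length(table$z_values), length(table$y_values))
  r <- sqrt(yy^2 + zz^2)
  th <- atan2(abs(yy), if (zero_toward == "+z") zz else -zz) * 180 / pi
  use <- is.finite(table$values) & r > exclusion_radius
  n_skipped <- sum(is.finite(table$values)) - sum(use)
  if (n_skipped > 0)
    message(sprintf("extract_anisotropy: skipped %d point(s) inside r = %g cm",
                    n_skipped, exclusion_radius))
  rv <- r[use]; tv <- th[use]
  d_transverse <- transverse_axis_dose(rv, source, g)       # closed form
  Fv <- (table$values[use] * geometry_factor(rv, source$theta0, source$active_length_L)) /
        (d_transverse * geometry_factor(rv, tv, source$active_length_L))
  out <- data.frame(y = yy[use], z = zz[use], r = rv, theta = tv, F = Fv)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "zero_toward") <- zero_toward
  class(out) <- c("anisotropy_points", "data.frame")
  out
}
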