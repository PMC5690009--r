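#' Dose plane on a uniform Cartesian grid
#'
#' Dose rate (per unit Sk, or absolute if the engine's Sk is not 1) on a
#' uniform (y, z) grid. The matrix is indexed `values[z, y]`; masked points
#' (inside applicator material or the singular zone around a dwell) are
#' `NA`.
#'
#' @param y,z ascending, uniformly spaced axes, cm.
#' @param values matrix `length(z)` x `length(y)`.
#' @param spacing grid spacing, cm.
#' @param label engine/plan label.
#' @param origin free-text description of the plane origin.
#' @return an object of class `dose_plane`.
#' @export
dose_plane <- function(y, z, values, spacing, label = "",
                       origin = "active-core centroid") {
  y <- as.numeric(y); z <- as.numeric(z)
  values <- as.matrix(values)
  if (spacing <= 0) stop("grid spacing must be positive")
  if (!all(dim(values) == c(length(z), length(y))))
    stop("values must be a length(z) x length(y) matrix")
  if (any(values[is.finite(values)] < 0))
    stop("dose values must be non-negative")
  structure(
    list(y = y, z = z, values = values, spacing = spacing,
         label = label, origin = origin),
    class = "dose_plane"
  )
}

#' @export
print.dose_plane <- function(x, ...) {
  cat(sprintf("dose plane%s: %d x %d grid, spacing %g cm, %d masked point(s)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$z), length(x$y), x$spacing, sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
plot.dose_plane <- function(x, log = TRUE, ...) {
  v <- x$values
  if (log) v <- log10(v)
  graphics::image(x$z, x$y, v, xlab = "z along [cm]", ylab = "y away [cm]",
                  main = paste0("dose plane ", x$label,
                                if (log) " (log10)" else ""), ...)
  invisible(x)
}

#' Uniform square evaluation grid
#'
#' @param half_width half-width of the square plane, cm.
#' @param spacing grid spacing, cm (default 0.05, i.e. 0.5 mm).
#' @param center plane center (y, z), cm.
#' @return list with ascending `y` and `z` axes and the spacing.
#' @export
plane_grid <- function(half_width = 6, spacing = 0.05, center = c(0, 0)) {
  if (half_width <= 0 || spacing <= 0)
    stop("half_width and spacing must be positive")
  n <- as.integer(round(half_width / spacing))
  ax <- seq(-n, n) * spacing
  list(y = ax + center[1], z = ax + center[2], spacing = spacing)
}

# TRUE for points inside an applicator mask
in_applicator <- function(app, yy, zz) {
  dy <- yy - app$center[1]
  dz <- zz - app$center[2]
  if (app$type == "cylinder") {
    ax <- app$axis / sqrt(sum(app$axis^2))
    along <- dy * ax[1] + dz * ax[2]
    perp <- abs(dy * ax[2] - dz * ax[1])
    abs(along) < app$half_length & perp < app$radius
  } else {
    sqrt(dy^2 + dz^2) < app$radius
  }
}

#' Compute a dose plane by superposition over a dwell set
#'
#' Sums, at every grid point, `weight * dose_rate` over all dwells, with
#' each point transformed into the local polar frame of the dwell (theta
#' measured from the dwell's axis direction, which points toward the
#' 0-degree pole of the engine's anisotropy table). Points inside any
#' applicator mask, or within `singular_radius` of any dwell center, are
#' masked (`NA`).
#'
#' @param dwells a [dwell_set()].
#' @param engine a [tg43_engine()].
#' @param grid a [plane_grid()] (or list with `y`, `z`, `spacing`).
#' @param singular_radius exclusion radius around each dwell, cm; default
#'   `L/2 + 0.05`.
#' @return a [dose_plane()].
#' @export
compute_dose_plane <- function(dwells, engine, grid = plane_grid(),
                               singular_radius = NULL) {
  stopifnot(inherits(dwells, "dwell_set"), inherits(engine, "tg43_engine"))
  if (is.null(singular_radius))
    singular_radius <- engine$source$active_length_L / 2 + 0.05
  ny <- length(grid$y); nz <- length(grid$z)
  yy <- matrix(grid$y, nz, ny, byrow = TRUE)
  zz <- matrix(grid$z, nz, ny)
  total <- matrix(0, nz, ny)
  masked <- matrix(FALSE, nz, ny)
  for (k in seq_len(nrow(dwells$positions))) {
    dy <- yy - dwells$positions[k, 1]
    dz <- zz - dwells$positions[k, 2]
    ax <- dwells$directions[k, ]
    along <- dy * ax[1] + dz * ax[2]
    perp <- abs(dy * ax[2] - dz * ax[1])
    r <- sqrt(dy^2 + dz^2)
    masked <- masked | r < singular_radius
    ok <- !masked & r >= singular_radius
    th <- atan2(perp[ok], along[ok]) * 180 / pi
    total[ok] <- total[ok] + dwells$weights[k] * dose_rate(r[ok], th, engine)
  }
  for (app in dwells$applicators)
    masked <- masked | in_applicator(app, yy, zz)
  total[masked] <- NA_real_
  dose_plane(grid$y, grid$z, total, grid$spacing,
             label = paste(dwells$name, engine$label, sep = "/"))
}

#' Signed percent-difference map between two dose planes
#'
#' Per unmasked point, `100 * (a - b) / b` — plane `b` is the reference
#' (denominator). Points masked in either plane are excluded.
#'
#' @param a,b [dose_plane()] objects on identical grids.
#' @return a Cartesian [diff_map()].
#' @export
percent_diff_plane <- function(a, b) {
  stopifnot(inherits(a, "dose_plane"), inherits(b, "dose_plane"))
  if (!isTRUE(all.equal(a$y, b$y)) || !isTRUE(all.equal(a$z, b$z)))
    stop("dose planes must share an identical grid")
  vals <- 100 * (a$values - b$values) / b$values
  vals[!is.finite(a$values) | !is.finite(b$values)] <- NA_real_
  diff_map(vals, coord = "cartesian", axis1 = b$z, axis2 = b$y,
           reference_label = b$label, comparison_label = a$label,
           denominator = "b")
}

#' Summary statistics of a percent-difference map
#'
#' Amplitude (min, max), mean, SD (n-1 denominator), median and quartiles
#' over all unmasked cells — the statistics shown per clinical setup in
#' commissioning box plots.
#'
#' @param diff a [diff_map()].
#' @return a one-row data.frame.
#' @export
setup_summary <- function(diff) {
  s <- summary(diff)
  data.frame(n = s$n, min = s$min, max = s$max, mean = s$mean, sd = s$sd,
             p25 = s$p25, median = s$median, p75 = s$p75)
}

#' Percent difference at named reporting points
#'
#' Bilinear interpolation of a Cartesian difference map at each named point
#' (e.g. the ABS reporting points of a Fletcher plan). Points tagged with a
#' different plane than `plane` are skipped.
#'
#' @param points data.frame with columns `name`, `y`, `z` and optionally
#'   `plane`.
#' @param diff a Cartesian [diff_map()].
#' @param plane plane tag to evaluate (default `"coronal"`).
#' @return data.frame `name, y, z, pct_diff`.
#' @export
evaluate_abs_points <- function(points, diff, plane = "coronal") {
  stopifnot(inherits(diff, "diff_map"))
  if (diff$coord != "cartesian")
    stop("reporting points are evaluated on Cartesian difference maps")
  if (!is.null(points$plane)) points <- points[points$plane == plane, ]
  if (!nrow(points)) stop("no points to evaluate on this plane")
  if (any(points$y < min(diff$axis2) | points$y > max(diff$axis2) |
          points$z < min(diff$axis1) | points$z > max(diff$axis1)))
    stop("reporting point outside the plane bounds")
  data.frame(
    name = points$name, y = points$y, z = points$z,
    pct_diff = bilinear_at(diff$axis1, diff$axis2, diff$values,
                           points$z, points$y),
    stringsAsFactors = FALSE
  )
}
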