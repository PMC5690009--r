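#' Resample an anisotropy table onto new axes
#'
#' Bilinear resampling via [anisotropy_lookup()], including radial clamping
#' and linear pole extrapolation where the target axes extend beyond the
#' source table. The provenance of the result records the direction of the
#' interpolation as `"int-<src>2<dst>"`.
#'
#' @param source_table an [anisotropy_table()].
#' @param target_radii radii of the output grid, cm.
#' @param target_angles angles of the output grid, degrees in \[0, 180\].
#' @param dst_label label of the target axes used in the provenance string.
#' @return an [anisotropy_table()] on the target axes.
#' @export
resample_table <- function(source_table, target_radii, target_angles,
                           dst_label = "target") {
  stopifnot(inherits(source_table, "anisotropy_table"))
  target_radii <- sort(as.numeric(target_radii))
  target_angles <- sort(as.numeric(target_angles))
  vals <- matrix(NA_real_, length(target_radii), length(target_angles))
  for (j in seq_along(target_angles))
    vals[, j] <- anisotropy_lookup(target_radii, target_angles[j], source_table)
  src <- if (nzchar(source_table$provenance)) source_table$provenance else "src"
  anisotropy_table(target_radii, target_angles, vals,
                   provenance = sprintf("int-%s2%s", src, dst_label))
}

#' Percent-difference map between two anisotropy tables on shared axes
#'
#' Computes the signed per-cell percent difference `100 * (b - a) / den`
#' where the denominator is table `a` or `b` as configured. Absolute values
#' are a display choice; the map itself stays signed.
#'
#' @param a,b [anisotropy_table()] objects on identical axes.
#' @param denominator `"a"` or `"b"`: which table normalises the difference.
#' @return a `diff_map` object (polar coordinates).
#' @export
compare_tables <- function(a, b, denominator = c("a", "b")) {
  stopifnot(inherits(a, "anisotropy_table"), inherits(b, "anisotropy_table"))
  denominator <- match.arg(denominator)
  if (!isTRUE(all.equal(a$radii, b$radii)) ||
      !isTRUE(all.equal(a$angles, b$angles)))
    stop("tables must share identical radial and angular axes")
  den <- if (denominator == "a") a$values else b$values
  diff_map(
    values = 100 * (b$values - a$values) / den,
    coord = "polar",
    axis1 = a$radii, axis2 = a$angles,
    reference_label = a$provenance, comparison_label = b$provenance,
    denominator = denominator
  )
}

#' Signed percent-difference map
#'
#' Container for a grid of signed percent differences, either on a polar
#' (radii x angles) or Cartesian (z x y) grid. Created by
#' [compare_tables()] and [percent_diff_plane()].
#'
#' @param values matrix of signed percent differences; `axis1` indexes rows,
#'   `axis2` columns.
#' @param coord `"polar"` (axis1 = radii cm, axis2 = angles deg) or
#'   `"cartesian"` (axis1 = z cm, axis2 = y cm).
#' @param axis1,axis2 grid coordinates.
#' @param reference_label,comparison_label,denominator provenance of the
#'   compared objects and of the normalisation.
#' @param zero_toward for Cartesian maps, direction of the 0-degree pole
#'   used when cells are mapped to polar angles (see [cartesian_to_polar()]).
#' @return an object of class `diff_map`.
#' @export
diff_map <- function(values, coord = c("polar", "cartesian"), axis1, axis2,
                     reference_label = "a", comparison_label = "b",
                     denominator = "a", zero_toward = "-z") {
  coord <- match.arg(coord)
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(axis1), length(axis2))))
    stop("values dimension does not match the coordinate axes")
  if (any(is.infinite(values)))
    stop("percent differences must be finite")
  structure(
    list(values = values, coord = coord,
         axis1 = as.numeric(axis1), axis2 = as.numeric(axis2),
         reference_label = reference_label,
         comparison_label = comparison_label,
         denominator = denominator, zero_toward = zero_toward),
    class = "diff_map"
  )
}

#' @export
summary.diff_map <- function(object, ...) {
  v <- object$values[is.finite(object$values)]
  if (!length(v)) stop("empty difference map")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  out <- list(
    n = length(v), min = min(v), max = max(v),
    mean = mean(v), sd = stats::sd(v),
    p25 = q[1], median = q[2], p75 = q[3]
  )
  class(out) <- "summary.diff_map"
  out
}

#' @export
print.summary.diff_map <- function(x, ...) {
  cat(sprintf(
    "percent differences over %d cells:\n  amplitude [%.3f, %.3f] %%\n  mean %.3f %%  SD %.3f %%\n  quartiles %.3f / %.3f / %.3f %%\n",
    x$n, x$min, x$max, x$mean, x$sd, x$p25, x$median, x$p75))
  invisible(x)
}

#' @export
print.diff_map <- function(x, ...) {
  cat(sprintf("diff map [%s vs %s, denominator '%s'] on a %s grid (%d x %d)\n",
              x$comparison_label, x$reference_label, x$denominator,
              x$coord, length(x$axis1), length(x$axis2)))
  print(summary(x))
  invisible(x)
}

#' @export
plot.diff_map <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("%% difference: %s vs %s", x$comparison_label,
                    x$reference_label)
  lab <- if (x$coord == "polar") c("radius [cm]", "angle [deg]") else
    c("z along [cm]", "y away [cm]")
  graphics::image(x$axis1, x$axis2, x$values, xlab = lab[1], ylab = lab[2],
                  main = main, ...)
  invisible(x)
}

# polar angle of every cell of a diff map, as a matrix matching $values
diff_map_theta <- function(diff) {
  if (diff$coord == "polar") {
    matrix(diff$axis2, length(diff$axis1), length(diff$axis2), byrow = TRUE)
  } else {
    zz <- matrix(diff$axis1, length(diff$axis1), length(diff$axis2))
    yy <- matrix(diff$axis2, length(diff$axis1), length(diff$axis2), byrow = TRUE)
    th <- atan2(abs(yy), if (diff$zero_toward == "+z") zz else -zz) * 180 / pi
    th[yy == 0 & zz == 0] <- NA_real_
    th
  }
}

#' Fraction of the polar-angle domain covered by angular bands
#'
#' Helper for ODIN reporting: the fraction of the polar-angle domain
#' \[0, 180\] degrees covered by a set of angular bands. For the action-level
#' bands within 15 degrees of both poles, `[0,15] U [165,180]`, this is
#' 30/180, approximately 17%.
#'
#' @param bands list of numeric length-2 vectors `c(lo, hi)` in degrees.
#' @return fraction in \[0, 1\].
#' @export
angular_coverage <- function(bands) {
  if (!length(bands)) return(0)
  w <- vapply(bands, function(b) {
    if (length(b) != 2L || b[2] < b[1] || b[1] < 0 || b[2] > 180)
      stop("each band must be c(lo, hi) within [0, 180] degrees")
    b[2] - b[1]
  }, numeric(1))
  sum(w) / 180
}

# secondary, solid-angle weighted coverage of the same bands
solid_angle_coverage <- function(bands) {
  if (!length(bands)) return(0)
  w <- vapply(bands, function(b)
    (cos(b[1] * pi / 180) - cos(b[2] * pi / 180)) / 2, numeric(1))
  sum(w)
}

#' Detect outcome discrepancies due to interpolation (ODIN)
#'
#' Flags every cell of a percent-difference map whose magnitude exceeds the
#' investigation level and classifies flagged cells into investigation
#' (|diff| in (investigation, intervention\]) and intervention
#' (|diff| > intervention) levels — the 2% / 5% action levels commonly used
#' in TPS commissioning. Flagged cells are grouped into contiguous angular
#' bands (splitting where the angular gap between successive flagged cells
#' exceeds `gap_deg`), and the fraction of the polar-angle domain
#' \[0, 180\] covered by those bands is reported; a solid-angle weighted
#' coverage is included as a secondary figure.
#'
#' @param diff a [diff_map()].
#' @param investigation investigation level, percent (default 2).
#' @param intervention intervention level, percent (default 5).
#' @param gap_deg angular gap (degrees) above which flagged cells are split
#'   into separate bands.
#' @return an object of class `odin_report`.
#' @export
odin_detect <- function(diff, investigation = 2, intervention = 5,
                        gap_deg = 10) {
  stopifnot(inherits(diff, "diff_map"))
  if (!(investigation > 0 && investigation <= intervention))
    stop("need 0 < investigation <= intervention")
  v <- diff$values
  th <- diff_map_theta(diff)
  fin <- is.finite(v)
  flag <- fin & abs(v) > investigation
  idx <- which(flag, arr.ind = TRUE)
  flagged <- data.frame(
    axis1 = diff$axis1[idx[, 1]],
    axis2 = diff$axis2[idx[, 2]],
    theta = th[idx],
    diff_pct = v[idx],
    level = ifelse(abs(v[idx]) > intervention, "intervention", "investigation"),
    stringsAsFactors = FALSE
  )
  names(flagged)[1:2] <- if (diff$coord == "polar") c("r", "theta_cell") else c("z", "y")

  bands <- list()
  if (nrow(flagged)) {
    ths <- sort(unique(flagged$theta))
    brk <- c(0, which(diff(ths) > gap_deg), length(ths))
    for (k in seq_len(length(brk) - 1L)) {
      grp <- ths[(brk[k] + 1L):brk[k + 1L]]
      bands[[k]] <- c(min(grp), max(grp))
    }
  }
  structure(
    list(flagged = flagged,
         n_flagged = nrow(flagged),
         n_intervention = sum(flagged$level == "intervention"),
         investigation = investigation, intervention = intervention,
         bands = bands,
         coverage_fraction = angular_coverage(bands),
         coverage_solid_angle = solid_angle_coverage(bands),
         stats = summary(diff)),
    class = "odin_report"
  )
}

#' @export
print.odin_report <- function(x, ...) {
  cat(sprintf("ODIN report (investigation > %g%%, intervention > %g%%)\n",
              x$investigation, x$intervention))
  cat(sprintf("  flagged cells      : %d (%d at intervention level)\n",
              x$n_flagged, x$n_intervention))
  if (length(x$bands)) {
    for (b in x$bands)
      cat(sprintf("  angular band       : [%.1f, %.1f] deg\n", b[1], b[2]))
    cat(sprintf("  angular coverage   : %.1f%% of [0, 180] deg (%.1f%% solid angle)\n",
                100 * x$coverage_fraction, 100 * x$coverage_solid_angle))
  } else {
    cat("  no cells above the investigation level\n")
  }
  print(x$stats)
  invisible(x)
}
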