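#' QA point pattern on polar rays
#'
#' A set of control points arranged on polar rays around the source, used to
#' spot-check a planning system's dose-rate output during commissioning.
#'
#' @param name pattern label.
#' @param ray_angles ray angles, degrees in \[0, 180\].
#' @param radii radii sampled on every ray, cm.
#' @param symmetry `"transverse-mirror"` if the pattern assumes the source
#'   is symmetric about its transverse axis (the assumption the legacy
#'   array patterns make), or `"none"`.
#' @return an object of class `qa_pattern`; `$points` holds the resolved
#'   (r, theta) list.
#' @export
qa_pattern <- function(name, ray_angles, radii,
                       symmetry = c("none", "transverse-mirror")) {
  symmetry <- match.arg(symmetry)
  ray_angles <- as.numeric(ray_angles)
  radii <- as.numeric(radii)
  if (!length(ray_angles) || !length(radii))
    stop("a pattern needs at least one ray and one radius")
  if (any(ray_angles < 0 | ray_angles > 180))
    stop("ray angles must lie in [0, 180] degrees")
  if (any(radii <= 0)) stop("radii must be positive")
  points <- expand.grid(theta = ray_angles, r = radii,
                        KEEP.OUT.ATTRS = FALSE)[, c("r", "theta")]
  structure(
    list(name = name, ray_angles = ray_angles, radii = radii,
         points = points, symmetry = symmetry),
    class = "qa_pattern"
  )
}

#' @export
print.qa_pattern <- function(x, ...) {
  cat(sprintf("QA pattern '%s': %d rays x %d radii = %d points (symmetry: %s)\n",
              x$name, length(x$ray_angles), length(x$radii),
              nrow(x$points), x$symmetry))
  cat("  rays at:", paste0(format(x$ray_angles), " deg", collapse = ", "), "\n")
  invisible(x)
}

#' Half-star QA point pattern
#'
#' Six rays at 0, a configurable angle strictly inside (0, 15), 45, 90, 135,
#' and a configurable angle strictly inside (165, 180) degrees. Unlike the
#' legacy array patterns, the two free rays deliberately sit inside the
#' steep pole-gradient zones of a cable-driven source, forcing the planning
#' system to display results exactly where sparse anisotropy tables
#' interpolate worst. Assumes cylindrical (not transverse-mirror) symmetry.
#'
#' @param radii radii per ray, cm (default 1, 2, 5; must exceed L/2).
#' @param low_ray angle of the cable-side free ray, degrees in (0, 15);
#'   default 7.
#' @param high_ray angle of the tip-side free ray, degrees in (165, 180);
#'   default 172.
#' @return a [qa_pattern()].
#' @export
half_star_pattern <- function(radii = c(1, 2, 5), low_ray = 7,
                              high_ray = 172) {
  if (!(low_ray > 0 && low_ray < 15))
    stop("the cable-side free ray must lie strictly inside (0, 15) degrees")
  if (!(high_ray > 165 && high_ray < 180))
    stop("the tip-side free ray must lie strictly inside (165, 180) degrees")
  qa_pattern("half-star", c(0, low_ray, 45, 90, 135, high_ray), radii,
             symmetry = "none")
}

#' Legacy commissioning point arrays
#'
#' Array-style QA patterns of the kind recommended by national commissioning
#' protocols. The shipped default ray sets assume transverse-mirror symmetry
#' and place no ray strictly inside (0, 15) degrees — the pole blind spot
#' that lets interpolation discrepancies in vendor anisotropy tables go
#' unnoticed. Ray angles and radii are configurable since the protocols
#' specify layouts diagrammatically rather than numerically.
#'
#' @param kind `"ncs"` or `"estro"`.
#' @param ray_angles override the default ray set.
#' @param radii radii per ray, cm.
#' @return a [qa_pattern()] with the symmetry flag set.
#' @export
legacy_pattern <- function(kind = c("ncs", "estro"), ray_angles = NULL,
                           radii = c(1, 2, 5)) {
  kind <- match.arg(kind)
  if (is.null(ray_angles))
    ray_angles <- switch(kind,
      ncs = c(0, 30, 60, 90, 120, 150, 180),
      estro = c(0, 45, 90, 135, 180))
  qa_pattern(kind, ray_angles, radii, symmetry = "transverse-mirror")
}

#' Evaluate a QA pattern against two dose engines
#'
#' Computes, at every pattern point, the dose rate from both engines and
#' the signed percent difference `100 * (b - a) / a` (engine `a` is the
#' reference). Points are flagged at the investigation and intervention
#' levels; a domain error at a single point (e.g. a radius inside the
#' source) yields `NA` for that row rather than aborting the report.
#'
#' @param pattern a [qa_pattern()].
#' @param engine_a reference [tg43_engine()].
#' @param engine_b comparison [tg43_engine()].
#' @param investigation,intervention action levels, percent.
#' @return data.frame of class `pattern_report` with one row per point and
#'   attribute `exit_status`: 0 (clean), 3 (investigation-level findings),
#'   4 (intervention-level findings).
#' @export
evaluate_pattern <- function(pattern, engine_a, engine_b,
                             investigation = 2, intervention = 5) {
  stopifnot(inherits(pattern, "qa_pattern"),
            inherits(engine_a, "tg43_engine"),
            inherits(engine_b, "tg43_engine"))
  pts <- pattern$points
  da <- db <- rep(NA_real_, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    da[k] <- tryCatch(dose_rate(pts$r[k], pts$theta[k], engine_a),
                      error = function(e) NA_real_)
    db[k] <- tryCatch(dose_rate(pts$r[k], pts$theta[k], engine_b),
                      error = function(e) NA_real_)
  }
  diff <- 100 * (db - da) / da
  level <- rep("ok", nrow(pts))
  level[abs(diff) > investigation] <- "investigation"
  level[abs(diff) > intervention] <- "intervention"
  level[!is.finite(diff)] <- NA_character_
  out <- data.frame(r = pts$r, theta = pts$theta,
                    dose_a = da, dose_b = db, diff_pct = diff,
                    level = level, stringsAsFactors = FALSE)
  status <- if (any(level == "intervention", na.rm = TRUE)) 4L
            else if (any(level == "investigation", na.rm = TRUE)) 3L else 0L
  attr(out, "exit_status") <- status
  attr(out, "pattern") <- pattern$name
  class(out) <- c("pattern_report", "data.frame")
  out
}
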