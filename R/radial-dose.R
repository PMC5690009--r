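#' Radial dose function model g_L(r)
#'
#' The radial dose function describes the transverse-axis dose falloff beyond
#' what the geometry function accounts for (attenuation and scatter in the
#' medium), normalised to 1 at the reference distance r0. Two representations
#' are supported: a polynomial in r (the form vendors ship as a
#' "Meisberger-style" fit) and a tabulated (r, g) list interpolated linearly
#' or log-linearly. Log-linear interpolation is the better choice close to
#' the source where g varies quickly.
#'
#' @param form `"polynomial"` or `"table"`.
#' @param coefficients polynomial coefficients c0, c1, ... (ascending powers
#'   of r), length >= 2 (degree >= 1). Polynomial form only.
#' @param table two-column matrix or data.frame of (r_cm, g) with strictly
#'   increasing radii and positive g. Table form only.
#' @param interpolation `"linear"` (in r) or `"log-linear"` (linear in
#'   log g versus log r, so a query at the geometric mean of two node radii
#'   returns the geometric mean of the node values). Table form only.
#' @param valid_range numeric length-2 (r_min, r_max) in cm over which the
#'   model may be evaluated. Defaults to the table's radial span for table
#'   form and c(0.3, 16) for polynomial form.
#' @param r0 reference distance, cm, at which g must equal 1.
#' @param normalize if `TRUE`, divide out g(r0) instead of rejecting a model
#'   with g(r0) != 1.
#' @param oor_policy out-of-range query policy: `"reject"` (error, default) or
#'   `"clamp"` (clamp r to the valid range with a warning).
#' @return An object of class `radial_dose_model`.
#' @export
radial_dose_model <- function(form = c("polynomial", "table"),
                              coefficients = NULL,
                              table = NULL,
                              interpolation = c("linear", "log-linear"),
                              valid_range = NULL,
                              r0 = 1.0,
                              normalize = FALSE,
                              oor_policy = c("reject", "clamp")) {
  form <- match.arg(form)
  interpolation <- match.arg(interpolation)
  oor_policy <- match.arg(oor_policy)

  if (form == "polynomial") {
    if (is.null(coefficients) || length(coefficients) < 2L)
      stop("polynomial form needs coefficients of degree >= 1")
    coefficients <- as.numeric(coefficients)
    if (is.null(valid_range)) valid_range <- c(0.3, 16)
  } else {
    if (is.null(table)) stop("table form needs a (r, g) table")
    table <- as.matrix(table)
    if (ncol(table) != 2L) stop("radial dose table must have two columns (r_cm, g)")
    if (any(diff(table[, 1]) <= 0)) stop("table radii must be strictly increasing")
    if (any(table[, 2] <= 0)) stop("all g values must be positive")
    if (is.null(valid_range)) valid_range <- range(table[, 1])
  }
  valid_range <- as.numeric(valid_range)
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2])
    stop("valid_range must be (r_min, r_max) with r_min < r_max")

  m <- structure(
    list(form = form, coefficients = coefficients, table = table,
         interpolation = interpolation, valid_range = valid_range,
         r0 = r0, oor_policy = oor_policy),
    class = "radial_dose_model"
  )
  g0 <- radial_dose_unchecked(r0, m)
  if (normalize) {
    if (m$form == "polynomial") m$coefficients <- m$coefficients / g0
    else m$table[, 2] <- m$table[, 2] / g0
  } else if (abs(g0 - 1) > 1e-6) {
    stop(sprintf("g(r0 = %g) = %.8f differs from 1 by more than 1e-6; %s",
                 r0, g0, "pass normalize = TRUE to renormalise at load"))
  }
  m
}

# evaluation without range policy (internal; used during construction)
radial_dose_unchecked <- function(r, model) {
  if (model$form == "polynomial") {
    co <- model$coefficients
    out <- rep(co[length(co)], length(r))
    for (k in seq(length(co) - 1L, 1L)) out <- out * r + co[k]
    out
  } else {
    rt <- model$table[, 1]
    gt <- model$table[, 2]
    if (model$interpolation == "log-linear")
      exp(stats::approx(log(rt), log(gt), xout = log(r), rule = 2)$y)
    else
      stats::approx(rt, gt, xout = r, rule = 2)$y
  }
}

#' Evaluate the radial dose function
#'
#' @param r query radius or radii, cm.
#' @param model a [radial_dose_model()].
#' @return g_L(r), dimensionless. Out-of-range queries follow the model's
#'   `oor_policy` ("reject" or "clamp" with a warning).
#' @export
radial_dose <- function(r, model) {
  stopifnot(inherits(model, "radial_dose_model"))
  r <- as.numeric(r)
  lo <- model$valid_range[1]
  hi <- model$valid_range[2]
  oor <- r < lo | r > hi
  if (any(oor)) {
    if (model$oor_policy == "reject")
      stop(sprintf("radius outside the model's valid range [%g, %g] cm", lo, hi))
    warning(sprintf("%d radius value(s) clamped to the valid range [%g, %g] cm",
                    sum(oor), lo, hi))
    r <- pmin(hi, pmax(lo, r))
  }
  radial_dose_unchecked(r, model)
}

#' @export
print.radial_dose_model <- function(x, ...) {
  cat(sprintf("radial dose model g_L(r): %s", x$form))
  if (x$form == "polynomial")
    cat(sprintf(" (degree %d)", length(x$coefficients) - 1L))
  else
    cat(sprintf(" (%d nodes, %s interpolation)", nrow(x$table), x$interpolation))
  cat(sprintf("\n  valid range [%g, %g] cm, out-of-range policy '%s'\n",
              x$valid_range[1], x$valid_range[2], x$oor_policy))
  invisible(x)
}
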