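#' Specification for a synthetic 2D anisotropy function
#'
#' Defines a smooth anisotropy function with exponential dose depressions
#' toward both source poles,
#' \deqn{F_{raw}(r,\theta) = 1 - A_{cable}(r)\, e^{-\theta_c / w_{cable}}
#'                            - A_{tip}(r)\,   e^{-\theta_t / w_{tip}}}
#' where \eqn{\theta_c} and \eqn{\theta_t} are the angular distances (deg)
#' to the cable-side and tip-side poles, renormalised so that
#' F(r, 90 deg) = 1 exactly. The depression amplitudes vary linearly with
#' radius, `A(r) = A * (1 + slope * (r - 1))`.
#'
#' The defaults emulate the structure of published Monte Carlo anisotropy
#' tables for cable-driven HDR Ir-192 sources: steep gradients within about
#' 15 degrees of both poles, steeper and deeper on the cable side (the drive
#' cable perturbs the medium more than the tip), and a mild radial
#' dependence. By convention the synthetic tables put the cable pole at
#' theta = 0 — the indexing used by the vendor tables this generator stands
#' in for.
#'
#' @param A_cable,A_tip pole depression amplitudes at r = 1 cm, in (0, 1).
#' @param w_cable,w_tip gradient widths, degrees (> 0); smaller is steeper.
#' @param slope_cable,slope_tip relative change of the amplitudes per cm.
#' @param radii radii of the generated tables, cm.
#' @param angle_step dense angular step, degrees (default 3).
#' @param seed integer seed recorded in provenance and used for the optional
#'   noise.
#' @param noise_sd relative SD of multiplicative log-normal noise
#'   (default 0: tables are exact and deterministic).
#' @return an object of class `synthetic_anisotropy_spec`.
#' @export
synthetic_anisotropy_spec <- function(A_cable = 0.55, A_tip = 0.45,
                                      w_cable = 6, w_tip = 8,
                                      slope_cable = -0.004, slope_tip = -0.003,
                                      radii = c(0.5, 1, 1.5, 2, 3, 5, 7, 10, 15),
                                      angle_step = 3,
                                      seed = 1L,
                                      noise_sd = 0) {
  stopifnot(A_cable >= 0, A_cable < 1, A_tip >= 0, A_tip < 1,
            w_cable > 0, w_tip > 0, angle_step > 0, noise_sd >= 0,
            all(radii > 0), !is.unsorted(radii, strictly = TRUE))
  Ac <- A_cable * (1 + slope_cable * (radii - 1))
  At <- A_tip * (1 + slope_tip * (radii - 1))
  if (any(Ac < 0 | Ac >= 1 | At < 0 | At >= 1))
    stop("amplitudes must stay within [0, 1) over the requested radii")
  structure(
    list(A_cable = A_cable, A_tip = A_tip,
         w_cable = w_cable, w_tip = w_tip,
         slope_cable = slope_cable, slope_tip = slope_tip,
         radii = radii, angle_step = angle_step,
         seed = as.integer(seed), noise_sd = noise_sd),
    class = "synthetic_anisotropy_spec"
  )
}

#' Evaluate the noiseless synthetic anisotropy function
#'
#' The closed-form generating function behind
#' [make_reference_anisotropy()], renormalised so F(r, 90) = 1 exactly.
#' Useful for checking interpolation errors against ground truth.
#'
#' @param spec a [synthetic_anisotropy_spec()].
#' @param r radius, cm (vectorised).
#' @param theta polar angle, degrees (cable pole at 0).
#' @return F(r, theta), dimensionless.
#' @export
synthetic_anisotropy_value <- function(spec, r, theta) {
  Ac <- spec$A_cable * (1 + spec$slope_cable * (r - 1))
  At <- spec$A_tip * (1 + spec$slope_tip * (r - 1))
  raw <- function(th) 1 - Ac * exp(-th / spec$w_cable) -
                          At * exp(-(180 - th) / spec$w_tip)
  raw(theta) / raw(90)
}

#' Generate a dense reference anisotropy table
#'
#' Evaluates the synthetic anisotropy function of a
#' [synthetic_anisotropy_spec()] on a dense angular grid. Like most published
#' reference tables, the grid does not include the 0 and 180 degree poles
#' (the default dense angles run `angle_step .. 180 - angle_step`, which for
#' the 3-degree default includes 90 exactly). Optional multiplicative
#' log-normal noise uses the stored seed; the default is noiseless so all
#' downstream oracles are exact.
#'
#' @param spec a [synthetic_anisotropy_spec()].
#' @param angles optional explicit angle grid, degrees.
#' @return an [anisotropy_table()] with provenance `"reference"`.
#' @export
make_reference_anisotropy <- function(spec, angles = NULL) {
  stopifnot(inherits(spec, "synthetic_anisotropy_spec"))
  if (is.null(angles))
    angles <- seq(spec$angle_step, 180 - spec$angle_step, by = spec$angle_step)
  vals <- outer(spec$radii, angles,
                function(r, a) synthetic_anisotropy_value(spec, r, a))
  if (spec$noise_sd > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(spec$seed)
    vals <- vals * exp(stats::rnorm(length(vals), 0, spec$noise_sd))
    i90 <- which(abs(angles - 90) < 1e-9)
    if (length(i90)) vals[, i90] <- 1  # keep the normalisation exact
  }
  tb <- anisotropy_table(spec$radii, angles, vals, provenance = "reference")
  attr(tb, "spec") <- spec
  attr(tb, "zero_pole") <- "cable"
  tb
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# the 17-angle vendor-style angular grid: both poles present (planning
# systems require 0 and 180 entries), a near-pole angle at 1.5 deg on the
# cable side, and no samples inside the high-gradient gaps (1.5, 25.5) and
# (155.5, 178.5) degrees.
default_vendor_angles <- function()
  c(0, 1.5, 25.5, 35.5, 45.5, 55.5, 60.5, 75.5, 90,
    105.5, 120.5, 135.5, 145.5, 150.5, 155.5, 178.5, 180)

default_vendor_radii <- function()
  c(0.5, 0.7, 1, 2, 3.5, 5, 7, 10, 13, 15)

#' Subsample a dense anisotropy table into a vendor-style sparse table
#'
#' Builds a sparse "vendor input data" style table from a dense reference
#' table: interior nodes are taken from the dense table (bilinear lookup,
#' exact where axes coincide), while the mandatory 0 and 180 degree pole
#' entries are filled by [pole_extrapolate()] — the first-order linear
#' extrapolation that vendor pole entries have been observed to match. The
#' default 17-angle set leaves no samples inside the high-gradient bands
#' near either pole, which is precisely the sampling defect that produces
#' ODIN regions when the planning system interpolates linearly across them.
#'
#' @param dense a dense [anisotropy_table()].
#' @param angles target angles (default: the 17-angle vendor set).
#' @param radii target radii (default: a 10-radius vendor set).
#' @return an [anisotropy_table()] with provenance `"vendor"`.
#' @export
subsample_vendor <- function(dense,
                             angles = default_vendor_angles(),
                             radii = default_vendor_radii()) {
  stopifnot(inherits(dense, "anisotropy_table"))
  if (!length(angles) || !length(radii)) stop("empty target axes")
  angles <- sort(as.numeric(angles))
  radii <- sort(as.numeric(radii))
  vals <- matrix(NA_real_, length(radii), length(angles))
  for (j in seq_along(angles)) {
    a <- angles[j]
    vals[, j] <- if (a %in% c(0, 180) && !(a %in% dense$angles))
      pole_extrapolate(dense, radii, a)
    else
      anisotropy_lookup(radii, a, dense)
  }
  tb <- anisotropy_table(radii, angles, vals, provenance = "vendor")
  attr(tb, "zero_pole") <- attr(dense, "zero_pole")
  tb
}

#' Angular sampling gaps of a sparse anisotropy table
#'
#' Returns the angular intervals between consecutive tabulated angles wider
#' than `min_gap` degrees — the bands where linear interpolation of the
#' sparse table is unsupported by data. For the default vendor table these
#' are the two pole-side gaps (1.5, 25.5) and (155.5, 178.5) degrees, the
#' ground-truth ODIN bands of the synthetic pipeline.
#'
#' @param table an [anisotropy_table()].
#' @param min_gap minimum gap width, degrees (default 20).
#' @return list of numeric length-2 vectors `c(lo, hi)`.
#' @export
vendor_gap_bands <- function(table, min_gap = 20) {
  stopifnot(inherits(table, "anisotropy_table"))
  aa <- table$angles
  d <- diff(aa)
  lapply(which(d > min_gap), function(k) c(aa[k], aa[k + 1L]))
}

#' Construct a radial dose model for synthetic pipelines
#'
#' @param kind `"flat"` (g identically 1), `"polynomial"` (a frozen
#'   quartic with the gentle rise-then-fall shape typical of HDR Ir-192
#'   radial dose functions, normalised to g(1 cm) = 1), or `"table"` (the
#'   same quartic sampled at `radii`).
#' @param radii sampling radii for the table form.
#' @param interpolation interpolation for the table form.
#' @return a [radial_dose_model()].
#' @export
make_radial_model <- function(kind = c("polynomial", "flat", "table"),
                              radii = c(0.3, 0.5, 1, 1.5, 2, 3, 4, 5, 7, 10, 12, 15, 16),
                              interpolation = c("linear", "log-linear")) {
  kind <- match.arg(kind)
  interpolation <- match.arg(interpolation)
  co <- c(0.97589790838, 0.0327248406259, -0.0094748079169,
          0.000881913674561, -2.98547632219e-05)
  co[1] <- co[1] + (1 - sum(co))   # pin g(1 cm) = 1 exactly
  switch(kind,
    flat = radial_dose_model("polynomial", coefficients = c(1, 0),
                             valid_range = c(0.05, 25)),
    polynomial = radial_dose_model("polynomial", coefficients = co,
                                   valid_range = c(0.3, 16)),
    table = {
      g <- radial_dose_model("polynomial", coefficients = co,
                             valid_range = c(0.3, 16))
      radial_dose_model("table",
                        table = cbind(radii, radial_dose(radii, g)),
                        interpolation = interpolation,
                        normalize = TRUE)
    })
}
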