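#' Dwell-position set for a clinical configuration
#'
#' An ordered set of HDR dwell positions in the evaluation plane. Each dwell
#' has a position (away y, along z) of its active-core center, a unit axis
#' direction pointing toward the 0-degree pole of the anisotropy table
#' (by convention the cable side points to -z, so the default axis is
#' `(0, -1)`), and a relative weight (dwell time). Applicator geometry is
#' carried along as masks that blank out dose-plane points inside the
#' applicator material.
#'
#' @param name setup label.
#' @param positions n x 2 matrix of dwell (y, z), cm.
#' @param directions n x 2 matrix of unit axis vectors; recycled from a
#'   single row.
#' @param weights positive relative dwell times; default uniform.
#' @param applicators list of applicator masks, each either
#'   `list(type = "cylinder", center = c(y, z), axis = c(uy, uz), half_length, radius)`
#'   or `list(type = "circle", center = c(y, z), radius)`.
#' @return an object of class `dwell_set`.
#' @export
dwell_set <- function(name, positions, directions = c(0, -1),
                      weights = NULL, applicators = list()) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  n <- nrow(positions)
  if (n < 1L) stop("a dwell set needs at least one dwell")
  directions <- matrix(as.numeric(directions), ncol = 2)
  if (nrow(directions) == 1L) directions <- directions[rep(1L, n), , drop = FALSE]
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) stop("dwell axis directions must be nonzero")
  directions <- directions / nrm
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("need one positive weight per dwell")
  structure(
    list(name = name, positions = positions, directions = directions,
         weights = as.numeric(weights), applicators = applicators),
    class = "dwell_set"
  )
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("dwell set '%s': %d dwell(s), %d applicator mask(s)\n",
              x$name, nrow(x$positions), length(x$applicators)))
  invisible(x)
}

# equally spaced dwells (endpoints included) along z at away-coordinate y
line_dwells <- function(span, n, y = 0, z_center = 0) {
  z <- if (n == 1L) z_center else seq(-span / 2, span / 2, length.out = n) + z_center
  cbind(rep(y, n), z)
}

#' Build a standard clinical dwell configuration
#'
#' Five configurations spanning the commissioning study designs:
#' \describe{
#'   \item{one_dwell}{a single dwell at the origin — the simplest test, and
#'     the worst case for pole-gradient interpolation errors (contact or
#'     single-dwell balloon treatments).}
#'   \item{short_applicator}{one applicator, 6 dwells spanning 3.5 cm
#'     (step 0.7 cm) — vaginal cylinder style.}
#'   \item{long_applicator}{one applicator spanning 9 cm at a configurable
#'     dwell step (default 0.5 cm, 19 dwells).}
#'   \item{fletcher}{a 6 cm tandem plus two lateral ovoids of 2 cm diameter,
#'     with the ABS-style reporting points attached as attribute
#'     `abs_points`.}
#'   \item{multi_applicator}{N parallel applicators at a configurable pitch
#'     — interstitial implant style.}
#' }
#'
#' @param kind configuration name (see Details).
#' @param ... overrides: `span`, `n_dwells`, `step` for the applicator
#'   setups; `tandem_length`, `tandem_step`, `ovoid_diameter`,
#'   `ovoid_offset`, `ovoid_z` for fletcher; `n_applicators`, `pitch`,
#'   `span`, `n_dwells` for multi_applicator.
#' @return a [dwell_set()]; for `fletcher` the ABS points are attached as
#'   attribute `abs_points` (data.frame name, y, z, plane).
#' @export
make_setup <- function(kind = c("one_dwell", "short_applicator",
                                "long_applicator", "fletcher",
                                "multi_applicator"), ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  pick <- function(nm, default) if (!is.null(opts[[nm]])) opts[[nm]] else default
  switch(kind,
    one_dwell = dwell_set("one_dwell", matrix(c(0, 0), 1)),
    short_applicator = {
      span <- pick("span", 3.5)
      n <- pick("n_dwells", 6L)
      if (span <= 0 || n < 1) stop("span and dwell count must be positive")
      dwell_set("short_applicator", line_dwells(span, n),
                applicators = list(list(type = "cylinder", center = c(0, 0),
                                        axis = c(0, 1),
                                        half_length = span / 2 + 0.25,
                                        radius = 0.3)))
    },
    long_applicator = {
      span <- pick("span", 9)
      step <- pick("step", 0.5)
      if (span <= 0 || step <= 0) stop("span and step must be positive")
      n <- as.integer(round(span / step)) + 1L
      dwell_set("long_applicator", line_dwells(span, n),
                applicators = list(list(type = "cylinder", center = c(0, 0),
                                        axis = c(0, 1),
                                        half_length = span / 2 + 0.25,
                                        radius = 0.3)))
    },
    fletcher = make_fletcher(pick("tandem_length", 6),
                             pick("tandem_step", 0.5),
                             pick("ovoid_diameter", 2),
                             pick("ovoid_offset", 1.5),
                             pick("ovoid_z", NULL)),
    multi_applicator = {
      n_app <- pick("n_applicators", 5L)
      pitch <- pick("pitch", 1)
      span <- pick("span", 3)
      n <- pick("n_dwells", 7L)
      if (n_app < 1 || pitch <= 0 || span <= 0 || n < 1)
        stop("applicator count, pitch, span and dwell count must be positive")
      ys <- (seq_len(n_app) - (n_app + 1) / 2) * pitch
      pos <- do.call(rbind, lapply(ys, function(y) line_dwells(span, n, y = y)))
      apps <- lapply(ys, function(y)
        list(type = "cylinder", center = c(y, 0), axis = c(0, 1),
             half_length = span / 2 + 0.25, radius = 0.2))
      dwell_set("multi_applicator", pos, applicators = apps)
    })
}

make_fletcher <- function(tandem_length, tandem_step, ovoid_diameter,
                          ovoid_offset, ovoid_z) {
  if (tandem_length <= 0 || tandem_step <= 0 || ovoid_diameter <= 0)
    stop("fletcher dimensions must be positive")
  half <- tandem_length / 2
  if (is.null(ovoid_z)) ovoid_z <- -half          # ovoids at the cable end
  n <- as.integer(round(tandem_length / tandem_step)) + 1L
  pos <- rbind(line_dwells(tandem_length, n),
               c(-ovoid_offset, ovoid_z),
               c(ovoid_offset, ovoid_z))
  orad <- ovoid_diameter / 2
  apps <- list(
    list(type = "cylinder", center = c(0, 0), axis = c(0, 1),
         half_length = half + 0.25, radius = 0.3),
    list(type = "circle", center = c(-ovoid_offset, ovoid_z), radius = orad),
    list(type = "circle", center = c(ovoid_offset, ovoid_z), radius = orad)
  )
  ds <- dwell_set("fletcher", pos, applicators = apps)
  # schematic ABS-style reporting points (coronal plane unless tagged);
  # coordinates are configuration defaults, not patient anatomy
  tip_z <- half
  abs_points <- data.frame(
    name = c("point_A_left", "point_A_right", "tandem_tip",
             "ovoid_surface_left", "ovoid_surface_right",
             "ovoid_plus_0.5_left", "ovoid_plus_0.5_right",
             "rectal", "bladder"),
    y = c(-2, 2, 0,
          -(ovoid_offset + orad + 0.1), ovoid_offset + orad + 0.1,
          -(ovoid_offset + orad + 0.5), ovoid_offset + orad + 0.5,
          -2, 2),
    z = c(-half + 2, -half + 2, tip_z + 1.8,
          ovoid_z, ovoid_z, ovoid_z, ovoid_z,
          ovoid_z, ovoid_z),
    plane = c("coronal", "coronal", "coronal", "coronal", "coronal",
              "coronal", "coronal", "sagittal", "sagittal"),
    stringsAsFactors = FALSE
  )
  attr(ds, "abs_points") <- abs_points
  ds
}
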