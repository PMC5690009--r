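#' Gamma-index acceptance criteria
#'
#' A (DTA, d%L) criterion pair for 2D gamma analysis with local dose
#' normalisation: DTA is the distance-to-agreement in mm, `dd_local` the
#' local percent dose-difference criterion. The search for the minimising
#' position is an exhaustive fine search over the continuously interpolated
#' evaluated plane, within `search_radius_factor * DTA` of each reference
#' point at a step of `sub_sampling * DTA`.
#'
#' @param dta_mm distance to agreement, mm (> 0).
#' @param dd_local_pct local percent dose difference, % (> 0).
#' @param search_radius_factor search radius as a multiple of DTA
#'   (default 3).
#' @param sub_sampling search step as a fraction of DTA (default 0.1).
#' @param low_dose_cutoff exclude reference points below this percentage of
#'   the reference-plane maximum (default 0: no cutoff).
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dta_mm, dd_local_pct, search_radius_factor = 3,
                           sub_sampling = 0.1, low_dose_cutoff = 0) {
  stopifnot(dta_mm > 0, dd_local_pct > 0, search_radius_factor > 0,
            sub_sampling > 0, low_dose_cutoff >= 0, low_dose_cutoff < 100)
  structure(
    list(dta_mm = dta_mm, dd_local_pct = dd_local_pct,
         search_radius_factor = search_radius_factor,
         sub_sampling = sub_sampling, low_dose_cutoff = low_dose_cutoff),
    class = "gamma_criteria"
  )
}

#' 2D gamma-index analysis of two dose planes
#'
#' For every unmasked reference point, the gamma index is the minimum over
#' candidate positions x within the search radius of
#' \deqn{\gamma = \sqrt{ \frac{|x - x_{ref}|^2}{DTA^2} +
#'   \frac{(D_{eval}(x) - D_{ref})^2}{(dd\% \cdot D_{ref})^2} }}
#' with the evaluated dose obtained by bilinear interpolation and the dose
#' difference normalised locally by the reference point's dose. A point
#' passes when gamma <= 1. Candidate positions whose search disc extends
#' beyond the evaluated plane are simply restricted to the in-bounds
#' portion; no reference points are excluded unless a low-dose cutoff is
#' requested.
#'
#' @param reference reference [dose_plane()] (normalising plane).
#' @param evaluated evaluated [dose_plane()] on a congruent grid.
#' @param criteria a [gamma_criteria()].
#' @return an object of class `gamma_result`: per-point gamma matrix plus
#'   pass statistics.
#' @export
gamma_2d <- function(reference, evaluated, criteria) {
  stopifnot(inherits(reference, "dose_plane"),
            inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  if (!isTRUE(all.equal(reference$y, evaluated$y)) ||
      !isTRUE(all.equal(reference$z, evaluated$z)))
    stop("reference and evaluated planes must share a congruent grid")
  Dref <- reference$values
  if (!any(is.finite(Dref) & Dref > 0))
    stop("reference plane has no positive dose: local normalisation undefined")

  dta <- criteria$dta_mm / 10                     # cm
  step <- criteria$sub_sampling * dta
  radius <- criteria$search_radius_factor * dta
  nsteps <- as.integer(round(radius / step))
  offs <- seq(-nsteps, nsteps) * step             # includes 0 exactly
  dd <- criteria$dd_local_pct / 100

  eval_ref <- is.finite(Dref)
  if (criteria$low_dose_cutoff > 0) {
    cut <- criteria$low_dose_cutoff / 100 * max(Dref, na.rm = TRUE)
    eval_ref <- eval_ref & Dref >= cut
  }
  denom <- dd * Dref
  gamma2 <- matrix(Inf, nrow(Dref), ncol(Dref))

  Vev <- evaluated$values
  axw <- function(ax, q) {
    nmax <- length(ax)
    ok <- q >= ax[1] & q <= ax[nmax]
    i <- pmin(pmax(findInterval(q, ax, rightmost.closed = TRUE), 1L), nmax - 1L)
    w <- (q - ax[i]) / (ax[i + 1L] - ax[i])
    w[!ok] <- NA_real_
    list(i = i, w = w)
  }
  zw <- lapply(offs, function(o) axw(evaluated$z, reference$z + o))
  yw <- lapply(offs, function(o) axw(evaluated$y, reference$y + o))
  for (iz in seq_along(offs)) {
    dzo <- offs[iz]
    a <- zw[[iz]]
    for (iy in which(offs^2 <= radius^2 - dzo^2 + 1e-12)) {
      dyo <- offs[iy]
      b <- yw[[iy]]
      Dq <- outer(1 - a$w, 1 - b$w) * Vev[a$i, b$i, drop = FALSE] +
            outer(1 - a$w, b$w)     * Vev[a$i, b$i + 1L, drop = FALSE] +
            outer(a$w, 1 - b$w)     * Vev[a$i + 1L, b$i, drop = FALSE] +
            outer(a$w, b$w)         * Vev[a$i + 1L, b$i + 1L, drop = FALSE]
      g2 <- (dzo^2 + dyo^2) / dta^2 + ((Dq - Dref) / denom)^2
      g2[!is.finite(g2)] <- Inf
      upd <- g2 < gamma2
      gamma2[upd] <- g2[upd]
    }
  }
  gm <- sqrt(gamma2)
  gm[!eval_ref] <- NA_real_
  gv <- gm[eval_ref & is.finite(gm)]
  n_eval <- length(gv)
  n_pass <- sum(gv <= 1 + 1e-9)
  structure(
    list(gamma = gm, criteria = criteria,
         evaluated_points = n_eval, passed_points = n_pass,
         pass_pct = 100 * n_pass / n_eval,
         gamma_mean = mean(gv), gamma_min = min(gv), gamma_max = max(gv),
         gamma_median = stats::median(gv)),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  cat(sprintf("gamma analysis %g%%L/%gmm (local normalisation)\n",
              cr$dd_local_pct, cr$dta_mm))
  cat(sprintf("  evaluated points: %d\n", x$evaluated_points))
  cat(sprintf("  passed (gamma<=1): %d (%.1f%%)\n", x$passed_points, x$pass_pct))
  cat(sprintf("  gamma mean %.3f  min %.3f  max %.3f  median %.3f\n",
              x$gamma_mean, x$gamma_min, x$gamma_max, x$gamma_median))
  invisible(x)
}

#' Default 3 x 3 criteria grid for a gamma sweep
#'
#' The nine (d%L, DTA) combinations of \{1, 2, 3\}% x \{1, 2, 3\} mm,
#' ordered dose-criterion first — the standard commissioning sweep layout.
#'
#' @param dd_pct,dta_mm criterion levels to cross.
#' @return list of [gamma_criteria()].
#' @export
default_criteria_grid <- function(dd_pct = c(1, 2, 3), dta_mm = c(1, 2, 3)) {
  out <- list()
  for (dd in dd_pct) for (dta in dta_mm)
    out[[length(out) + 1L]] <- gamma_criteria(dta, dd)
  out
}

#' Gamma sweep over a list of criteria
#'
#' Runs [gamma_2d()] for each criterion pair and tabulates the pass
#' statistics, one row per (d%L, DTA) combination in the given order.
#'
#' @param reference,evaluated [dose_plane()] objects.
#' @param criteria_list list of [gamma_criteria()]
#'   (default [default_criteria_grid()]).
#' @return data.frame with columns `dd_pct, dta_mm, evaluated_points,
#'   passed_points, pass_pct, gamma_mean, gamma_min, gamma_max,
#'   gamma_median`.
#' @export
gamma_sweep <- function(reference, evaluated,
                        criteria_list = default_criteria_grid()) {
  if (!length(criteria_list)) stop("need at least one criterion")
  rows <- lapply(criteria_list, function(cr) {
    g <- gamma_2d(reference, evaluated, cr)
    data.frame(dd_pct = cr$dd_local_pct, dta_mm = cr$dta_mm,
               evaluated_points = g$evaluated_points,
               passed_points = g$passed_points, pass_pct = g$pass_pct,
               gamma_mean = g$gamma_mean, gamma_min = g$gamma_min,
               gamma_max = g$gamma_max, gamma_median = g$gamma_median)
  })
  do.call(rbind, rows)
}
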