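#' Nucleator ray measurement
#'
#' A 2D nucleator design: a central point inside the profile and intercept
#' lengths from that point to the profile boundary along isotropic ray
#' directions. The estimator assumes the profile is star-shaped about the
#' central point (each ray crosses the boundary once).
#'
#' @param lengths intercept lengths, mm (>= 0, at least two rays).
#' @param directions ray directions in radians, `[0, 2*pi)`; optional
#'   metadata, one per length.
#' @return Object of class `nucleator_measurement`.
#' @export
nucleator_measurement <- function(lengths, directions = NULL) {
  if (length(lengths) < 2L) {
    stopf("nucleator needs at least 2 rays, got %d", length(lengths))
  }
  if (any(!is.finite(lengths)) || any(lengths < 0)) {
    stopf("intercept lengths must be finite and nonnegative")
  }
  if (!is.null(directions)) {
    if (length(directions) != length(lengths)) {
      stopf("one direction per intercept length required")
    }
    directions <- directions %% (2 * pi)
  }
  structure(list(lengths = as.numeric(lengths), directions = directions),
            class = "nucleator_measurement")
}

#' 2D nucleator area estimate
#'
#' Classical isotropic 2D nucleator: with intercept lengths `l_i` from an
#' interior point to the boundary along isotropic directions, the profile
#' area is estimated as `pi * mean(l_i^2)`. Exact for a circle measured from
#' its center; unbiased over isotropic directions for star-shaped profiles.
#'
#' @param m a [nucleator_measurement()] or a bare numeric vector of
#'   intercept lengths.
#' @return Estimated area, mm^2.
#' @export
nucleator_area <- function(m) {
  if (!inherits(m, "nucleator_measurement")) m <- nucleator_measurement(m)
  pi * mean(m$lengths^2)
}

#' Ray directions for a nucleator design
#'
#' Either `n` isotropic uniform random directions, or the systematic design:
#' `n` equally spaced directions with a single uniform random rotation
#' (lower variance at equal `n`).
#'
#' @param n number of rays (>= 2).
#' @param design `"systematic"` or `"random"`.
#' @param seed optional RNG seed.
#' @return Numeric vector of angles in radians, `[0, 2*pi)`.
#' @export
nucleator_directions <- function(n, design = c("systematic", "random"),
                                 seed = NULL) {
  design <- match.arg(design)
  if (n < 2L) stopf("nucleator needs at least 2 rays, got %d", n)
  with_seed(seed, {
    switch(design,
           systematic = (stats::runif(1, 0, 2 * pi / n) +
                           2 * pi * (seq_len(n) - 1) / n) %% (2 * pi),
           random = stats::runif(n, 0, 2 * pi))
  })
}

#' Ray-boundary intercept lengths for a polygonal profile
#'
#' Casts rays from a central point and returns the distance to the polygon
#' boundary along each direction. For a profile that is star-shaped about
#' the point each ray crosses the boundary exactly once; for robustness the
#' farthest crossing is returned, and a profile violating the star-shape
#' assumption can be rejected via `require_star_shaped`.
#'
#' @param vertices two-column matrix of polygon vertices (closed implicitly).
#' @param center `(x, y)` of the central point, inside the polygon.
#' @param angles ray directions, radians.
#' @param require_star_shaped if `TRUE`, error when any ray crosses the
#'   boundary more than once (the single-intercept nucleator would be
#'   biased there).
#' @return Numeric vector of intercept lengths, one per angle.
#' @export
intercept_lengths_polygon <- function(vertices, center, angles,
                                      require_star_shaped = FALSE) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  x0 <- center[1]; y0 <- center[2]
  nv <- nrow(vertices)
  ax <- vertices[, 1]; ay <- vertices[, 2]
  bx <- ax[c(2:nv, 1)]; by <- ay[c(2:nv, 1)]
  ex <- bx - ax; ey <- by - ay
  vapply(angles, function(th) {
    dx <- cos(th); dy <- sin(th)
    # solve p0 + t*d = a + s*e for each edge; keep t > 0, s in [0, 1]
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    t <- ((ax - x0) * ey - (ay - y0) * ex) / den
    s <- ((ax - x0) * dy - (ay - y0) * dx) / den
    hit <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    if (!any(hit)) {
      stopf("ray at angle %.3f rad does not hit the boundary; is the center inside the profile?", th)
    }
    tt <- sort(unique(round(t[hit], 9)))
    if (require_star_shaped && length(tt) > 1L) {
      stopf("profile is not star-shaped about the center: ray at %.3f rad crosses the boundary %d times",
            th, length(tt))
    }
    max(tt)
  }, numeric(1))
}

#' Serial section areas with spacing
#'
#' An ordered series of cross-sectional areas measured on equidistant
#' sections, the input to the Cavalieri volume estimator.
#'
#' @param areas section areas, mm^2 (>= 0).
#' @param d distance between consecutive sections, mm (> 0).
#' @return Object of class `section_series`.
#' @export
section_series <- function(areas, d) {
  if (length(areas) == 0L) stopf("section series must contain at least one area")
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stopf("invariant violated: section areas must be finite and >= 0")
  }
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  structure(list(areas = as.numeric(areas), d = d), class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat(sprintf("<section_series> %d sections every %g mm, total area %.4g mm^2\n",
              length(x$areas), x$d, sum(x$areas)))
  invisible(x)
}

#' Cavalieri volume estimate
#'
#' Unbiased volume estimate from equidistant section areas:
#' `V = d * sum(a_i)` with `d` the distance between sections and `a_i` the
#' cross-sectional areas.
#'
#' @param s a [section_series()], or a numeric vector of areas (then `d`
#'   must be given).
#' @param d section spacing, mm; ignored when `s` is a [section_series()].
#' @return Estimated volume, mm^3.
#' @export
cavalieri_volume <- function(s, d = NULL) {
  if (!inherits(s, "section_series")) {
    if (is.null(d)) stopf("supply d when passing bare areas")
    s <- section_series(s, d)
  }
  s$d * sum(s$areas)
}
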