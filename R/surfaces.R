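#' Surface specification
#'
#' Describes the idealized substrate on which tessera growth centers are
#' scattered. Real skeletal elements present a mix of flat and curved
#' regions; the package emulates these as curvature regimes rather than
#' anatomical shapes.
#'
#' @param kind one of `"plane"`, `"sphere"`, `"cylinder"`, `"slab_shell"`.
#'   `"slab_shell"` is a plane that will be voxelized as a slab shell.
#' @param extent for planar kinds, `c(length_x, length_y)` in micrometers;
#'   for a cylinder, its axial length; ignored for a sphere.
#' @param radius radius in micrometers (curved kinds only).
#' @return A `surface_spec` object.
#' @export
surface_spec <- function(kind = c("plane", "sphere", "cylinder", "slab_shell"),
                         extent = NULL, radius = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("plane", "slab_shell")) {
    if (is.null(extent) || length(extent) != 2 || any(extent <= 0))
      stop("planar surfaces need a positive `extent = c(lx, ly)`",
           call. = FALSE)
  }
  if (kind %in% c("sphere", "cylinder")) {
    if (is.null(radius) || length(radius) != 1 || radius <= 0)
      stop("curved surfaces need a positive `radius`", call. = FALSE)
  }
  if (kind == "cylinder") {
    if (is.null(extent) || length(extent) < 1 || extent[1] <= 0)
      stop("a cylinder needs a positive axial `extent`", call. = FALSE)
    extent <- extent[1]
  }
  structure(list(kind = kind, extent = extent, radius = radius),
            class = "surface_spec")
}

#' @export
print.surface_spec <- function(x, ...) {
  cat("<surface_spec>", x$kind)
  if (!is.null(x$extent)) cat(" extent:", paste(x$extent, collapse = " x "), "um")
  if (!is.null(x$radius)) cat(" radius:", x$radius, "um")
  cat("\n")
  invisible(x)
}

surface_area.surface_spec <- function(x) {
  switch(x$kind,
         plane = ,
         slab_shell = prod(x$extent),
         sphere = 4 * pi * x$radius^2,
         cylinder = 2 * pi * x$radius * x$extent)
}

#' Geodesic distances between points on a surface
#'
#' Euclidean in the plane, great-circle arcs on the sphere, unrolled
#' periodic metric on the cylinder.
#'
#' @param surface a [surface_spec()].
#' @param a,b matrices of points (rows) in the surface's natural
#'   coordinates: `(x, y)` for planes, `(x, y, z)` on the sphere,
#'   `(arc, z)` for the cylinder (arc = radius * angle).
#' @return Matrix of pairwise distances between rows of `a` and rows of `b`.
#' @export
surface_distances <- function(surface, a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  switch(surface$kind,
    plane = ,
    slab_shell = {
      dx <- outer(a[, 1], b[, 1], "-")
      dy <- outer(a[, 2], b[, 2], "-")
      sqrt(dx^2 + dy^2)
    },
    sphere = {
      R <- surface$radius
      cosang <- tcrossprod(a / R, b / R)
      cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
      R * acos(cosang)
    },
    cylinder = {
      circ <- 2 * pi * surface$radius
      dx <- abs(outer(a[, 1], b[, 1], "-"))
      dx <- pmin(dx, circ - dx)
      dz <- outer(a[, 2], b[, 2], "-")
      sqrt(dx^2 + dz^2)
    })
}

#' Hard-core point sampling on a surface
#'
#' Dart throwing with a minimum pairwise (geodesic) spacing, emulating a
#' random scatter of tessera growth centers subject to a minimum
#' cell-cluster size. Candidates are drawn uniformly on the surface and
#' rejected when closer than `min_spacing` to an accepted point; sampling
#' fails loudly when the requested count cannot be placed within the
#' attempt budget.
#'
#' @param surface a [surface_spec()].
#' @param n number of points (>= 1).
#' @param min_spacing minimum pairwise geodesic distance in micrometers.
#' @param seed integer seed; identical seeds give identical point sets.
#' @param max_attempts total candidate budget (default `max(1000, 500 * n)`).
#' @return A tibble of points: columns `x, y` (plane), `x, y, z` (sphere;
#'   also kept for other kinds as embedded 3D coordinates), or `arc, z`
#'   (cylinder).
#' @export
sample_hardcore_points <- function(surface, n, min_spacing = 0, seed = 1,
                                   max_attempts = NULL) {
  stopifnot(inherits(surface, "surface_spec"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (min_spacing < 0) stop("`min_spacing` must be >= 0", call. = FALSE)
  if (is.null(max_attempts)) max_attempts <- max(1000, 500 * n)
  draw <- switch(surface$kind,
    plane = ,
    slab_shell = function(m)
      cbind(stats::runif(m, 0, surface$extent[1]),
            stats::runif(m, 0, surface$extent[2])),
    sphere = function(m) {
      v <- matrix(stats::rnorm(3 * m), ncol = 3)
      surface$radius * v / sqrt(rowSums(v^2))
    },
    cylinder = function(m)
      cbind(stats::runif(m, 0, 2 * pi * surface$radius),
            stats::runif(m, 0, surface$extent[1])))
  withr::with_seed(seed, {
    pts <- draw(1)
    attempts <- 1
    while (nrow(pts) < n && attempts < max_attempts) {
      cand <- draw(1)
      attempts <- attempts + 1
      if (min_spacing == 0 ||
          min(surface_distances(surface, cand, pts)) >= min_spacing)
        pts <- rbind(pts, cand)
    }
    if (nrow(pts) < n)
      stop(sprintf(paste0("hard-core sampling infeasible: placed %d of %d ",
                          "points at min_spacing %.3g um within %d attempts"),
                   nrow(pts), n, min_spacing, max_attempts), call. = FALSE)
  })
  out <- switch(surface$kind,
    plane = ,
    slab_shell = tibble::tibble(x = pts[, 1], y = pts[, 2]),
    sphere = tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
    cylinder = tibble::tibble(arc = pts[, 1], z = pts[, 2]))
  attr(out, "surface") <- surface
  out
}
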