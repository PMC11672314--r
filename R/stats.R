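#' Polygon-class frequencies
#'
#' Tallies tiles by polygon class (neighbor count / side number). Boundary
#' tiles undercount their sides on open surfaces and are excluded by
#' default.
#'
#' @param classes a tibble with columns `n` and optionally `boundary`
#'   (e.g. from [neighbor_counts()]), or a named/plain integer vector of
#'   classes.
#' @param interior_only drop boundary-flagged tiles first.
#' @return Tibble `n, count, fraction` (fractions sum to 1).
#' @export
polygon_frequency <- function(classes, interior_only = TRUE) {
  if (is.data.frame(classes)) {
    n <- classes$n
    if (interior_only && "boundary" %in% names(classes))
      n <- n[!classes$boundary]
  } else n <- as.integer(classes)
  if (length(n) == 0) stop("no tiles to tally", call. = FALSE)
  tab <- table(n)
  tibble::tibble(n = as.integer(names(tab)),
                 count = as.integer(tab),
                 fraction = as.numeric(tab) / sum(tab))
}

#' Euler characteristic of a closed tessellation
#'
#' V - E + F over deduplicated vertices and edges: 2 for sphere-like
#' tessellations, 0 for toroidal ones. Open tessellations are refused —
#' boundary faces make the raw count meaningless; restrict to the interior
#' or close the surface instead.
#'
#' @param tess a closed `tessellation`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  if (!tess$closed)
    stop(paste0("tessellation is open (has boundary); the Euler ",
                "characteristic is only reported for closed tessellations"),
         call. = FALSE)
  used <- sort(unique(unlist(tess$faces)))
  V <- length(used)
  E <- nrow(tess_edges(tess))
  F <- length(tess$faces)
  as.integer(V - E + F)
}

#' Hexagonal deficiency of a closed trivalent tessellation
#'
#' The sum over faces of (6 - n). For a trivalent tessellation this equals
#' 6 times the Euler characteristic: 12 on the sphere, 0 on the torus.
#' When only 5/6/7-gons occur it reduces to (#pentagons - #heptagons),
#' which is why a sphere-like tiling needs a 12-pentagon excess.
#'
#' @param tess a closed trivalent `tessellation`.
#' @return Integer deficiency sum.
#' @export
hexagonal_deficiency <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  if (!tess$closed)
    stop("hexagonal deficiency requires a closed tessellation",
         call. = FALSE)
  vdeg <- vertex_face_count(tess)
  used <- which(vdeg > 0)
  bad <- used[vdeg[used] != 3L]
  if (length(bad) > 0)
    stop(sprintf("tessellation is not trivalent: vertex %d touches %d faces",
                 bad[1], vdeg[bad[1]]), call. = FALSE)
  as.integer(sum(6L - tess$sides))
}

#' Peak (mode) of a size distribution
#'
#' Histogram mode with parabolic refinement over the modal bin and its two
#' neighbors. The default bin rule is Freedman-Diaconis; a fixed
#' `bin_width` can be supplied for reproducible comparisons.
#'
#' @param values numeric vector (>= 10 values).
#' @param bin_rule `"fd"` or `"width"`.
#' @param bin_width bin width when `bin_rule = "width"`.
#' @return The mode, in the units of `values`.
#' @export
peak_of_distribution <- function(values, bin_rule = c("fd", "width"),
                                 bin_width = NULL) {
  bin_rule <- match.arg(bin_rule)
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("need at least 10 values to estimate a peak", call. = FALSE)
  if (diff(range(values)) == 0) return(values[1])
  w <- if (bin_rule == "fd") {
    iqr <- stats::IQR(values)
    if (iqr == 0) diff(range(values)) / 30
    else 2 * iqr * length(values)^(-1 / 3)
  } else {
    if (is.null(bin_width) || bin_width <= 0)
      stop("`bin_width` must be a positive width", call. = FALSE)
    bin_width
  }
  lo <- min(values)
  breaks <- seq(lo, max(values) + w, by = w)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  m <- which.max(h$counts)
  ctr <- h$mids[m]
  if (m == 1 || m == length(h$counts)) return(ctr)
  y0 <- h$counts[m - 1]; y1 <- h$counts[m]; y2 <- h$counts[m + 1]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0) return(ctr)
  ctr + 0.5 * w * (y0 - y2) / denom
}

#' Peak-rescaled distribution summary
#'
#' Divides values by the peak (mode) so distributions of the same shape at
#' different scales collapse onto each other; the density is histogrammed
#' on a fixed common grid so summaries are directly comparable, normalized
#' both to maximum 1 (for display: the peak sits at 1) and to unit area
#' (for distances).
#'
#' @param values positive numeric vector.
#' @param mode the peak value (from [peak_of_distribution()]); computed
#'   when `NULL`.
#' @param grid_max,grid_n common rescaled-axis grid: `grid_n` bins on
#'   `[0, grid_max]`.
#' @return A `dist_summary`.
#' @export
rescale_distribution <- function(values, mode = NULL, grid_max = 4,
                                 grid_n = 160) {
  if (is.null(mode)) mode <- peak_of_distribution(values)
  if (!is.finite(mode) || mode <= 0)
    stop("`mode` must be positive", call. = FALSE)
  x <- values / mode
  breaks <- seq(0, grid_max, length.out = grid_n + 1)
  xin <- x[x >= 0 & x <= grid_max]
  h <- graphics::hist(xin, breaks = breaks, plot = FALSE)
  dens <- h$density * length(xin) / length(x)  # mass beyond grid_max drops
  structure(list(values = values, mode = mode, breaks = breaks,
                 mids = h$mids, counts = h$counts,
                 density_unit = dens,
                 density_max1 = if (max(dens) > 0) dens / max(dens) else dens),
            class = "dist_summary")
}

#' @export
print.dist_summary <- function(x, ...) {
  cat(sprintf("<dist_summary> n = %d, mode = %.4g, rescaled peak bin at %.3g\n",
              length(x$values), x$mode, x$mids[which.max(x$density_unit)]))
  invisible(x)
}

#' Self-similarity distance between rescaled distributions
#'
#' L1 distance between the unit-area rescaled densities of two
#' [rescale_distribution()] summaries on their common grid; 0 for
#' identical shapes, 2 for disjoint supports.
#'
#' @param a,b `dist_summary` objects on the same grid.
#' @return Scalar in `[0, 2]`.
#' @export
self_similarity_distance <- function(a, b) {
  stopifnot(inherits(a, "dist_summary"), inherits(b, "dist_summary"))
  if (length(a$breaks) != length(b$breaks) ||
      any(abs(a$breaks - b$breaks) > 1e-12))
    stop("distributions were rescaled on different grids", call. = FALSE)
  w <- diff(a$breaks)
  sum(abs(a$density_unit - b$density_unit) * w)
}

#' Log-log peak regression against surface area
#'
#' Ordinary least squares of log10(peak) on log10(surface area) across
#' specimens, with the isometric reference exponent attached: under
#' shape-preserving growth a length scales as area^0.5, an area as
#' area^1 and a volume as area^1.5.
#'
#' @param data tibble with the specimen-level variables.
#' @param surface_area,peak column names (tidy-eval) of the predictor and
#'   response.
#' @param isometric_exponent reference slope m.
#' @return A `peak_regression`; see [tidy.peak_regression()].
#' @export
loglog_peak_regression <- function(data, surface_area, peak,
                                   isometric_exponent) {
  sa <- dplyr::pull(data, {{ surface_area }})
  pk <- dplyr::pull(data, {{ peak }})
  if (length(sa) < 3)
    stop("need >= 3 specimens for a peak regression", call. = FALSE)
  if (any(sa <= 0) || any(pk <= 0))
    stop("surface areas and peaks must be positive", call. = FALSE)
  fit <- stats::lm(log10(pk) ~ log10(sa))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  ci[is.na(ci)] <- stats::coef(fit)[2]  # zero-residual fits: degenerate CI
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 ci = ci[2, ],
                 isometric_exponent = isometric_exponent,
                 n = length(sa)),
            class = "peak_regression")
}

#' @export
print.peak_regression <- function(x, ...) {
  cat(sprintf(
    "<peak_regression> slope m' = %.4g [%.4g, %.4g], isometric m = %.3g, n = %d\n",
    x$slope, x$ci[1], x$ci[2], x$isometric_exponent, x$n))
  invisible(x)
}

#' Tidy a peak regression
#'
#' @param x a `peak_regression`.
#' @param ... unused.
#' @return `tidy()`: one row per coefficient with estimate, std.error and
#'   confidence bounds. `glance()`: one-row model summary with the fitted
#'   slope, its CI, the isometric reference and r.squared.
#' @export
tidy.peak_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  ci <- suppressWarnings(stats::confint(x$fit))
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, 1]), std.error = unname(s[, 2]),
                 conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]))
}

#' @rdname tidy.peak_regression
#' @export
glance.peak_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, conf.low = unname(x$ci[1]),
                 conf.high = unname(x$ci[2]),
                 isometric_exponent = x$isometric_exponent,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared,
                 n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Neighbor-count versus size relation
#'
#' Mean plane-based area by polygon class plus the Spearman rank
#' correlation between neighbor count and area across tiles — tiles with
#' more neighbors tend to be larger (a Lewis-law-like relation).
#'
#' @param records tessera table with columns `n_neighbors` and
#'   `plane_area_um2` (boundary rows dropped if flagged).
#' @return List with `by_class` (tibble `n, mean_area, n_tiles`) and
#'   `spearman_rho`.
#' @export
neighbor_size_relation <- function(records) {
  df <- records
  if (!is.null(df$boundary)) df <- df[!df$boundary, ]
  df <- df[is.finite(df$plane_area_um2), ]
  if (length(unique(df$n_neighbors)) < 2)
    stop("need >= 2 distinct neighbor-count classes", call. = FALSE)
  by_class <- df |>
    dplyr::group_by(n = .data$n_neighbors) |>
    dplyr::summarise(mean_area = mean(.data$plane_area_um2),
                     n_tiles = dplyr::n(), .groups = "drop")
  rho <- if (stats::sd(df$plane_area_um2) == 0) 0 else
    stats::cor(df$n_neighbors, df$plane_area_um2, method = "spearman")
  list(by_class = by_class, spearman_rho = rho)
}
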