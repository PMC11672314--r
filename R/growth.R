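#' Growth-simulator state
#'
#' Tiles are rigid convex polygons realized as intersections of half-planes:
#' tile i is bounded toward each neighbor j by a mineral front at distance
#' `f_ij` from its center along the center-to-center direction. The fiber
#' (intertesseral joint) between i and j carries the gap
#' `g_ij = d_ij - f_ij - f_ji >= 0`; apposition advances fronts, substrate
#' expansion scales centers while fronts (rigid mineral) stay fixed.
#'
#' [init_state()] starts from a planar Voronoi tessellation with every tile
#' shrunk toward its center by `sqrt(fill_fraction)`, so initial coverage
#' approximates `fill_fraction` and all gap invariants hold.
#'
#' @param tess a planar `tessellation` with adjacency.
#' @param fill_fraction initial covered fraction, in (0, 1].
#' @return A `growth_state`.
#' @export
init_state <- function(tess, fill_fraction = 1) {
  stopifnot(inherits(tess, "tessellation"))
  if (!is.null(tess$surface) &&
      !tess$surface$kind %in% c("plane", "slab_shell"))
    stop("growth simulation runs on planar tessellations", call. = FALSE)
  if (fill_fraction <= 0 || fill_fraction > 1)
    stop("`fill_fraction` must be in (0, 1]", call. = FALSE)
  centers <- tess$centers[, 1:2, drop = FALSE]
  ed <- tess$adjacency
  d <- sqrt(rowSums((centers[ed[, 1], , drop = FALSE] -
                     centers[ed[, 2], , drop = FALSE])^2))
  shrink <- sqrt(fill_fraction)
  ext <- tess$surface$extent
  state <- structure(list(
    centers = centers,
    edges = tibble::tibble(a = ed[, 1], b = ed[, 2],
                           fa = shrink * d / 2, fb = shrink * d / 2),
    box = c(0, ext[1], 0, ext[2]),
    boundary = tess$boundary,
    shrink = shrink,
    lambda_cum = 1,
    step = 0L,
    chain = FALSE), class = "growth_state")
  check_gaps(state)
  state
}

#' One-dimensional chain state
#'
#' An analytically checkable reduction: tiles are segments on a line,
#' fibers join consecutive tiles. Fronts start at
#' `sqrt(fill_fraction) * d / 2` like the planar case, or can be given
#' explicitly.
#'
#' @param centers increasing tile center positions (micrometers).
#' @param fill_fraction initial covered fraction in (0, 1].
#' @param fronts optional 2-column matrix (left, right fronts per fiber is
#'   derived from this per-edge pair `fa`, `fb`).
#' @param domain `c(lo, hi)` substrate interval; defaults to the center
#'   span padded by half the end spacings.
#' @return A `growth_state` with `chain = TRUE`.
#' @export
chain_state <- function(centers, fill_fraction = 1, fronts = NULL,
                        domain = NULL) {
  centers <- sort(as.numeric(centers))
  m <- length(centers)
  if (m < 2) stop("a chain needs >= 2 tiles", call. = FALSE)
  d <- diff(centers)
  if (is.null(fronts)) {
    shrink <- sqrt(fill_fraction)
    fronts <- cbind(shrink * d / 2, shrink * d / 2)
  }
  if (is.null(domain))
    domain <- c(centers[1] - d[1] / 2, centers[m] + d[m - 1] / 2)
  state <- structure(list(
    centers = cbind(centers, 0),
    edges = tibble::tibble(a = seq_len(m - 1), b = 2:m,
                           fa = fronts[, 1], fb = fronts[, 2]),
    box = c(domain[1], domain[2], 0, 1),
    boundary = c(TRUE, rep(FALSE, m - 2), TRUE),
    shrink = NA_real_,
    lambda_cum = 1,
    step = 0L,
    chain = TRUE), class = "growth_state")
  check_gaps(state)
  state
}

#' @export
print.growth_state <- function(x, ...) {
  g <- edge_gaps(x)
  cat(sprintf(
    "<growth_state> %d tiles, %d fibers, cumulative scale %.3f, step %d\n",
    nrow(x$centers), nrow(x$edges), x$lambda_cum, x$step))
  cat(sprintf("  gaps: mean %.3g, max %.3g um\n", mean(g), max(g)))
  invisible(x)
}

edge_lengths <- function(state) {
  e <- state$edges
  sqrt(rowSums((state$centers[e$a, , drop = FALSE] -
                state$centers[e$b, , drop = FALSE])^2))
}

edge_gaps <- function(state) {
  edge_lengths(state) - state$edges$fa - state$edges$fb
}

check_gaps <- function(state) {
  g <- edge_gaps(state)
  if (any(g < -1e-9 * max(edge_lengths(state))))
    stop("front overlap: some gap g_ij is negative", call. = FALSE)
  if (any(state$edges$fa <= 0) || any(state$edges$fb <= 0))
    stop("fronts must be positive", call. = FALSE)
  invisible(state)
}

#' Expand the substrate
#'
#' Homogeneous (isometric) expansion: centers and the domain scale by
#' `lambda` about the origin while the rigid mineral fronts stay fixed, so
#' every gap opens by exactly `(lambda - 1) * d_ij` — larger neighboring
#' tiles (larger center spacing) open larger absolute gaps, loading their
#' fibers more.
#'
#' @param state a `growth_state`.
#' @param lambda linear scale factor, > 1.
#' @return The expanded `growth_state`.
#' @export
expand_substrate <- function(state, lambda) {
  stopifnot(inherits(state, "growth_state"))
  if (lambda <= 1) stop("`lambda` must be > 1", call. = FALSE)
  state$centers <- state$centers * lambda
  state$box <- state$box * lambda
  state$lambda_cum <- state$lambda_cum * lambda
  state
}

#' Apposition rules
#'
#' `appose_constant()`: every front advances by the same increment
#' `min(delta, g_ij / 2)` (clipped at contact, so overlaps are never
#' created); uniform tilings close all gaps, but heterogeneous tilings
#' leave residual gaps next to larger tiles. `appose_proportional()`:
#' each front advances by `k * g_ij / 2` — the same amount on both ends of
#' every fiber (equal fiber force), the gap-proportional rule under which
#' larger tiles accrete more total area and the tiling stays complete with
#' the same number and pattern of tiles.
#'
#' @param state a `growth_state`.
#' @param delta constant front increment (micrometers, >= 0).
#' @return The updated `growth_state`.
#' @export
appose_constant <- function(state, delta) {
  stopifnot(inherits(state, "growth_state"))
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  g <- edge_gaps(state)
  adv <- pmin(delta, g / 2)
  state$edges$fa <- state$edges$fa + adv
  state$edges$fb <- state$edges$fb + adv
  state$step <- state$step + 1L
  state
}

#' @rdname appose_constant
#' @param k gap-closure rate fraction in (0, 1].
#' @export
appose_proportional <- function(state, k) {
  stopifnot(inherits(state, "growth_state"))
  if (k <= 0 || k > 1) stop("`k` must be in (0, 1]", call. = FALSE)
  g <- edge_gaps(state)
  adv <- k * g / 2
  state$edges$fa <- state$edges$fa + adv
  state$edges$fb <- state$edges$fb + adv
  state$step <- state$step + 1L
  state
}

#' Asymmetric front perturbation
#'
#' Shifts each fiber's boundary position off-center (`fa + eps`,
#' `fb - eps`) without changing any gap, producing a non-Voronoi
#' configuration for convergence experiments.
#'
#' @param state a `growth_state`.
#' @param amount maximum |shift| as a fraction of `d_ij / 2`.
#' @param seed integer seed.
#' @return The perturbed `growth_state`.
#' @export
perturb_fronts <- function(state, amount = 0.2, seed = 1) {
  stopifnot(inherits(state, "growth_state"))
  d <- edge_lengths(state)
  withr::with_seed(seed, {
    eps <- stats::runif(nrow(state$edges), -amount, amount) * d / 2
  })
  eps <- pmax(pmin(eps, state$edges$fb - 1e-9 * d),
              -(state$edges$fa - 1e-9 * d))
  state$edges$fa <- state$edges$fa + eps
  state$edges$fb <- state$edges$fb - eps
  check_gaps(state)
  state
}

# Tile polygons as half-plane intersections clipped to the domain box.
tile_polygons <- function(state) {
  m <- nrow(state$centers)
  e <- state$edges
  if (state$chain) {
    segs <- vector("list", m)
    # tile i spans [c_i - f_(i-1,i from b side), c_i + f_(i,i+1 from a side)]
    lo <- c(state$box[1], state$centers[e$b, 1] - e$fb)
    hi <- c(state$centers[e$a, 1] + e$fa, state$box[2])
    for (i in seq_len(m)) segs[[i]] <- c(max(state$box[1], lo[i]),
                                         min(state$box[2], hi[i]))
    return(segs)
  }
  by_tile <- vector("list", m)
  for (r in seq_len(nrow(e))) {
    by_tile[[e$a[r]]] <- rbind(by_tile[[e$a[r]]], c(e$b[r], e$fa[r]))
    by_tile[[e$b[r]]] <- rbind(by_tile[[e$b[r]]], c(e$a[r], e$fb[r]))
  }
  polys <- vector("list", m)
  bx <- state$box
  for (i in seq_len(m)) {
    P <- rbind(c(bx[1], bx[3]), c(bx[2], bx[3]),
               c(bx[2], bx[4]), c(bx[1], bx[4]))
    hp <- by_tile[[i]]
    ci <- state$centers[i, ]
    if (!is.null(hp)) {
      for (r in seq_len(nrow(hp))) {
        j <- hp[r, 1]; f <- hp[r, 2]
        u <- state$centers[j, ] - ci
        u <- u / sqrt(sum(u^2))
        # keep x . u <= ci . u + f  <=>  -u1 x - u2 y + (ci.u + f) >= 0
        cl <- clip_halfplane(P, integer(nrow(P)), -u[1], -u[2],
                             sum(ci * u) + f, 0L)
        P <- cl$P
        if (nrow(P) == 0) break
      }
    }
    polys[[i]] <- P
  }
  polys
}

#' Tile areas of a growth state
#' @param state a `growth_state`.
#' @return Numeric vector of tile areas (um^2; chain mode: lengths).
#' @export
tile_areas <- function(state) {
  polys <- tile_polygons(state)
  if (state$chain)
    return(vapply(polys, function(s) max(0, s[2] - s[1]), 1.0))
  vapply(polys, function(P) {
    if (is.null(P) || nrow(P) < 3) return(0)
    shoelace_area(P[, 1], P[, 2])
  }, 1.0)
}

#' Covered fraction of a region
#'
#' Tiled area divided by region area, by polygon clipping. Tiles are
#' pairwise disjoint by construction, so their clipped areas add.
#'
#' @param state a `growth_state`.
#' @param region optional polygon (2-column matrix of vertices); default
#'   is the whole substrate box (chain mode: the interval).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(state, region = NULL) {
  stopifnot(inherits(state, "growth_state"))
  if (state$chain) {
    segs <- tile_polygons(state)
    lo <- if (is.null(region)) state$box[1] else region[1]
    hi <- if (is.null(region)) state$box[2] else region[2]
    if (hi <= lo) stop("empty region", call. = FALSE)
    covered <- sum(vapply(segs, function(s)
      max(0, min(s[2], hi) - max(s[1], lo)), 1.0))
    return(covered / (hi - lo))
  }
  bx <- state$box
  if (is.null(region)) {
    area_region <- (bx[2] - bx[1]) * (bx[4] - bx[3])
    if (area_region <= 0) stop("empty region", call. = FALSE)
    return(sum(tile_areas(state)) / area_region)
  }
  region <- as.matrix(region)
  area_region <- shoelace_area(region[, 1], region[, 2])
  if (area_region <= 0) stop("empty region", call. = FALSE)
  rp <- list(list(x = region[, 1], y = region[, 2]))
  covered <- 0
  for (P in tile_polygons(state)) {
    if (is.null(P) || nrow(P) < 3) next
    cl <- polyclip::polyclip(list(list(x = P[, 1], y = P[, 2])), rp,
                             op = "intersection")
    covered <- covered + sum(vapply(cl, function(q)
      shoelace_area(q$x, q$y), 1.0))
  }
  covered / area_region
}

#' Candidate sites for new tiles
#'
#' Connected uncovered regions of the substrate larger than
#' `gap_area_threshold`, each reported with its centroid and area — where
#' a constant-rate tiling would have to insert new tiles.
#'
#' @param state a `growth_state`.
#' @param gap_area_threshold minimum region area (um^2; chain: length).
#' @return Tibble `x, y, area`, one row per candidate site.
#' @export
propose_new_tiles <- function(state, gap_area_threshold) {
  stopifnot(inherits(state, "growth_state"))
  if (gap_area_threshold <= 0)
    stop("`gap_area_threshold` must be > 0", call. = FALSE)
  if (state$chain) {
    segs <- tile_polygons(state)
    m <- length(segs)
    gaps <- list()
    for (i in seq_len(m - 1)) {
      lo <- segs[[i]][2]; hi <- segs[[i + 1]][1]
      if (hi - lo > gap_area_threshold)
        gaps[[length(gaps) + 1]] <- c((lo + hi) / 2, hi - lo)
    }
    if (length(gaps) == 0)
      return(tibble::tibble(x = numeric(), y = numeric(), area = numeric()))
    g <- do.call(rbind, gaps)
    return(tibble::tibble(x = g[, 1], y = 0, area = g[, 2]))
  }
  bx <- state$box
  boxp <- list(list(x = bx[c(1, 2, 2, 1)], y = bx[c(3, 3, 4, 4)]))
  tiles <- lapply(tile_polygons(state), function(P) {
    if (is.null(P) || nrow(P) < 3) NULL else list(x = P[, 1], y = P[, 2])
  })
  tiles <- tiles[!vapply(tiles, is.null, TRUE)]
  gap <- polyclip::polyclip(boxp, tiles, op = "minus")
  if (length(gap) == 0)
    return(tibble::tibble(x = numeric(), y = numeric(), area = numeric()))
  signed <- vapply(gap, function(q) {
    x <- q$x; y <- q$y; j <- c(2:length(x), 1)
    sum(x * y[j] - x[j] * y) / 2
  }, 1.0)
  outer_idx <- which(signed > 0)
  rows <- lapply(outer_idx, function(oi) {
    a <- signed[oi]
    # subtract holes contained in this outer ring
    for (hi in which(signed < 0)) {
      if (point_in_poly(gap[[hi]]$x[1], gap[[hi]]$y[1], gap[[oi]]))
        a <- a + signed[hi]
    }
    cx <- poly_centroid(gap[[oi]])
    tibble::tibble(x = cx[1], y = cx[2], area = a)
  })
  out <- dplyr::bind_rows(rows)
  out[out$area > gap_area_threshold, ]
}

point_in_poly <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

poly_centroid <- function(poly) {
  x <- poly$x; y <- poly$y
  j <- c(2:length(x), 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Deviation from the Voronoi (equipartitioned) configuration
#'
#' Mean over fibers of the offset of the mid-gap point from the
#' center-to-center midpoint, normalized by the spacing:
#' `|f_ij - f_ji| / (2 d_ij)`. Zero when every fiber's boundary sits on
#' the perpendicular bisector (the Voronoi limit).
#'
#' @param state a `growth_state`.
#' @return Mean normalized boundary offset (dimensionless).
#' @export
voronoi_deviation <- function(state) {
  stopifnot(inherits(state, "growth_state"))
  d <- edge_lengths(state)
  mean(abs(state$edges$fa - state$edges$fb) / (2 * d))
}

#' Growth rule constructors
#' @param delta constant-rule front increment (micrometers).
#' @export
rule_constant <- function(delta) {
  structure(list(type = "constant", delta = delta), class = "growth_rule")
}

#' @rdname rule_constant
#' @param k proportional-rule gap-closure fraction in (0, 1].
#' @export
rule_proportional <- function(k) {
  structure(list(type = "proportional", k = k), class = "growth_rule")
}

#' Run expansion/apposition growth cycles
#'
#' Each cycle expands the substrate by `lambda_per_cycle` and applies the
#' apposition rule once, recording tile count, coverage, gap statistics,
#' Voronoi deviation and the tile-area sample per cycle.
#'
#' @param state a `growth_state`.
#' @param lambda_per_cycle per-cycle linear expansion (> 1).
#' @param rule a [rule_constant()] or [rule_proportional()].
#' @param n_cycles number of cycles.
#' @param seed kept for interface symmetry; the dynamics are
#'   deterministic.
#' @return A `growth_trajectory`: `summary` tibble (one row per cycle),
#'   `areas` (list of per-cycle tile-area vectors), `final_state`.
#' @export
run_cycles <- function(state, lambda_per_cycle, rule, n_cycles, seed = NULL) {
  stopifnot(inherits(state, "growth_state"), inherits(rule, "growth_rule"))
  rows <- vector("list", n_cycles)
  areas <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    state <- expand_substrate(state, lambda_per_cycle)
    state <- switch(rule$type,
                    constant = appose_constant(state, rule$delta),
                    proportional = appose_proportional(state, rule$k))
    g <- edge_gaps(state)
    polys <- tile_polygons(state)
    ar <- if (state$chain)
      vapply(polys, function(s) max(0, s[2] - s[1]), 1.0)
    else vapply(polys, function(P) {
      if (is.null(P) || nrow(P) < 3) 0 else shoelace_area(P[, 1], P[, 2])
    }, 1.0)
    areas[[cyc]] <- ar
    region_area <- if (state$chain) state$box[2] - state$box[1] else
      (state$box[2] - state$box[1]) * (state$box[4] - state$box[3])
    rows[[cyc]] <- tibble::tibble(
      cycle = cyc,
      n_tiles = nrow(state$centers),
      coverage = sum(ar) / region_area,
      gap_mean = mean(g), gap_median = stats::median(g), gap_max = max(g),
      voronoi_deviation = voronoi_deviation(state),
      lambda_cum = state$lambda_cum)
  }
  structure(list(summary = dplyr::bind_rows(rows), areas = areas,
                 final_state = state, rule = rule),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<growth_trajectory> %s rule, %d cycles; final coverage %.4f, %d tiles\n",
    x$rule$type, nrow(s), s$coverage[nrow(s)], s$n_tiles[nrow(s)]))
  invisible(x)
}

#' @export
tidy.growth_trajectory <- function(x, ...) x$summary
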