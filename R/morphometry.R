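#' Outward-facing axis of a tessera
#'
#' Determines which of the six bounding-cuboid face normals points out of
#' the skeletal element: signed distances are summed along the ray from
#' the tile's center voxel to the volume boundary in each axis direction,
#' and the direction with the maximum sum (most open space: positive
#' signed distances outside the skeleton) wins. Ties break deterministically
#' in the order +z, +y, +x, -z, -y, -x.
#'
#' @param labels a `label_volume`.
#' @param signed_dist the signed `distance_volume` of the binarized volume.
#' @param id tile id.
#' @return Named unit vector (`axis` attribute one of "+x".."-z").
#' @export
outward_axis <- function(labels, signed_dist, id) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(signed_dist, "distance_volume"),
            isTRUE(signed_dist$signed))
  d <- dim(labels$data)
  st <- cpp_label_stats(labels$data, d)
  outward_axis_impl(st, signed_dist$data, d, id)
}

outward_axis_impl <- function(st, sd, d, id) {
  if (id < 1 || id > nrow(st) || st[id, "count"] == 0)
    stop(sprintf("unknown label id %d", id), call. = FALSE)
  n <- st[id, "count"]
  c0 <- round(c(st[id, "sum_i"], st[id, "sum_j"], st[id, "sum_k"]) / n) + 1
  c0 <- pmin(pmax(c0, 1), d)
  # rays run to the volume boundary; sums are normalized by ray length
  # (mean signed distance) so directions with a longer run to the box
  # face of a synthetic volume are not favored by length alone
  sums <- c(
    "+z" = mean(sd[c0[1], c0[2], c0[3]:d[3]]),
    "+y" = mean(sd[c0[1], c0[2]:d[2], c0[3]]),
    "+x" = mean(sd[c0[1]:d[1], c0[2], c0[3]]),
    "-z" = mean(sd[c0[1], c0[2], c0[3]:1]),
    "-y" = mean(sd[c0[1], c0[2]:1, c0[3]]),
    "-x" = mean(sd[c0[1]:1, c0[2], c0[3]]))
  axis <- names(sums)[which.max(sums)]  # which.max takes the first = tie rule
  vec <- switch(axis,
                "+x" = c(1, 0, 0), "-x" = c(-1, 0, 0),
                "+y" = c(0, 1, 0), "-y" = c(0, -1, 0),
                "+z" = c(0, 0, 1), "-z" = c(0, 0, -1))
  attr(vec, "axis") <- axis
  vec
}

axis_index <- function(axis_vec) which(axis_vec != 0)

#' Bounding-box tessera dimensions
#'
#' `tessera_thickness()` is the axis-aligned bounding-box side along the
#' tile's outward (thickness) axis; `tessera_width()` is the longest of
#' the two remaining box sides — so columnar tiles taller than wide do not
#' conflate the two. `tessera_volume()` is the member voxel count times
#' the voxel volume.
#'
#' @param labels a `label_volume`.
#' @param id tile id.
#' @param axis outward axis from [outward_axis()] (or any of the six unit
#'   vectors).
#' @return Length in micrometers (volume: cubic micrometers).
#' @export
tessera_thickness <- function(labels, id, axis) {
  bb <- label_bbox_sides(labels, id)
  unname(bb[axis_index(axis)])
}

#' @rdname tessera_thickness
#' @export
tessera_width <- function(labels, id, axis) {
  bb <- label_bbox_sides(labels, id)
  unname(max(bb[-axis_index(axis)]))
}

#' @rdname tessera_thickness
#' @export
tessera_volume <- function(labels, id) {
  st <- cpp_label_stats(labels$data, dim(labels$data))
  if (id < 1 || id > nrow(st) || st[id, "count"] == 0)
    stop(sprintf("unknown label id %d", id), call. = FALSE)
  unname(st[id, "count"]) * labels$voxel^3
}

label_bbox_sides <- function(labels, id) {
  st <- cpp_label_stats(labels$data, dim(labels$data))
  if (id < 1 || id > nrow(st) || st[id, "count"] == 0)
    stop(sprintf("unknown label id %d", id), call. = FALSE)
  c((st[id, "max_i"] - st[id, "min_i"] + 1),
    (st[id, "max_j"] - st[id, "min_j"] + 1),
    (st[id, "max_k"] - st[id, "min_k"] + 1)) * labels$voxel
}

#' Plane-based tessera area
#'
#' The in-plane footprint of a tile from the RAG alone: neighbors are
#' ordered angularly about the tile center in the fitted tangent plane,
#' each consecutive neighbor pair forms a triangle with the center, the
#' triangle centroids are projected onto the plane through the center
#' perpendicular to the fitted normal (the mean of the triangle-fan
#' normals), and the projected centroids' polygon area is returned
#' (shoelace formula).
#'
#' @param graph a `rag`.
#' @param id node id with at least 3 neighbors.
#' @return Area in square micrometers, or `NA` (with a `"reason"`
#'   attribute) for boundary/under-connected nodes.
#' @export
plane_area <- function(graph, id) {
  stopifnot(inherits(graph, "rag"))
  nodes <- graph$nodes
  row <- which(nodes$id == id)
  if (length(row) != 1) stop(sprintf("unknown node id %d", id), call. = FALSE)
  nb <- sort(c(graph$edges$b[graph$edges$a == id],
               graph$edges$a[graph$edges$b == id]))
  if (length(nb) < 3) {
    out <- NA_real_; attr(out, "reason") <- "fewer than 3 neighbors"
    return(out)
  }
  ctr <- unlist(nodes[row, c("x", "y", "z")])
  P <- as.matrix(nodes[match(nb, nodes$id), c("x", "y", "z")])
  rel <- sweep(P, 2, ctr)
  # initial normal: smallest principal direction of the neighbor cloud
  normal <- prcomp(rel)$rotation[, 3]
  ord <- angular_order(rel, normal)
  # refined normal: mean of consecutive-triangle normals (oriented)
  tn <- vapply(seq_along(ord), function(t) {
    u <- rel[ord[t], ]; v <- rel[ord[if (t == length(ord)) 1 else t + 1], ]
    w <- cross3(u, v)
    if (sum(w * normal) < 0) w <- -w
    w / sqrt(sum(w^2))
  }, numeric(3))
  normal <- rowMeans(tn)
  normal <- normal / sqrt(sum(normal^2))
  ord <- angular_order(rel, normal)
  m <- length(ord)
  cents <- t(vapply(seq_len(m), function(t) {
    (rel[ord[t], ] + rel[ord[if (t == m) 1 else t + 1], ]) / 3
  }, numeric(3)))
  # project onto the plane through the center perpendicular to normal
  basis <- plane_basis(normal)
  uv <- cents %*% basis
  shoelace_area(uv[, 1], uv[, 2])
}

angular_order <- function(rel, normal) {
  basis <- plane_basis(normal)
  uv <- rel %*% basis
  ang <- atan2(uv[, 2], uv[, 1])
  order(ang, seq_len(nrow(rel)))  # id order breaks collinear ties
}

plane_basis <- function(normal) {
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, normal); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(normal, e1)
  cbind(e1, e2)
}

#' Mineralized volume fraction
#'
#' Labeled (mineralized) voxels divided by the element-mask voxels (shell
#' plus enclosed core).
#'
#' @param labels a `label_volume`.
#' @param element_mask a `binary_volume` covering the whole element.
#' @return Fraction in `[0, 1]`.
#' @export
mineralized_fraction <- function(labels, element_mask) {
  stopifnot(inherits(labels, "label_volume"),
            inherits(element_mask, "binary_volume"))
  nmask <- sum(element_mask$data)
  if (nmask == 0) stop("empty element mask", call. = FALSE)
  sum(labels$data > 0) / nmask
}

#' Assemble the per-tessera morphometric table
#'
#' One row per tile: center, outward axis, thickness, width, volume,
#' plane-based area, neighbor count and (when a smoothed surface mesh is
#' supplied) Gaussian and mean curvature at the nearest mesh vertex.
#'
#' @param labels a `label_volume`.
#' @param signed_dist signed `distance_volume` (for outward axes).
#' @param graph the `rag` built from `labels`.
#' @param mesh optional `surface_mesh` from [smooth_surface_from_rag()].
#' @param curvature_flag |K| threshold (1/um^2) above which a tile is
#'   flagged as curved-region.
#' @return A tibble, one `tessera` record per row.
#' @export
tessera_table <- function(labels, signed_dist, graph, mesh = NULL,
                          curvature_flag = Inf) {
  d <- dim(labels$data)
  st <- cpp_label_stats(labels$data, d)
  present <- which(st[, "count"] > 0)
  vox <- labels$voxel
  deg <- neighbor_counts(graph)
  rows <- lapply(present, function(id) {
    ax <- outward_axis_impl(st, signed_dist$data, d, id)
    bb <- c((st[id, "max_i"] - st[id, "min_i"] + 1),
            (st[id, "max_j"] - st[id, "min_j"] + 1),
            (st[id, "max_k"] - st[id, "min_k"] + 1)) * vox
    n <- st[id, "count"]
    tibble::tibble(
      id = as.integer(id),
      x = (st[id, "sum_i"] / n + 0.5) * vox,
      y = (st[id, "sum_j"] / n + 0.5) * vox,
      z = (st[id, "sum_k"] / n + 0.5) * vox,
      axis = attr(ax, "axis"),
      thickness_um = bb[axis_index(ax)],
      width_um = max(bb[-axis_index(ax)]),
      volume_um3 = n * vox^3,
      plane_area_um2 = suppressWarnings(as.numeric(plane_area(graph, id))),
      n_neighbors = deg$n[match(id, deg$id)],
      boundary = deg$boundary[match(id, deg$id)])
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(mesh)) {
    kh <- t(vapply(seq_len(nrow(out)), function(r) {
      tessera_curvature(mesh, c(out$x[r], out$y[r], out$z[r]))
    }, numeric(2)))
    out$gaussian_curvature <- kh[, 1]
    out$mean_curvature <- kh[, 2]
    out$curved_region <- abs(out$gaussian_curvature) > curvature_flag
  }
  out
}
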