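#' Tessera centroids
#'
#' Per-label centroid as the mean of member-voxel world coordinates
#' (voxel-center convention).
#'
#' @param labels a `label_volume`.
#' @return Tibble `id, x, y, z` (micrometers) plus `n_voxels`.
#' @export
centroids <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  st <- cpp_label_stats(labels$data, dim(labels$data))
  present <- which(st[, "count"] > 0)
  if (length(present) == 0) stop("no labels present", call. = FALSE)
  n <- st[present, "count"]
  v <- labels$voxel
  tibble::tibble(id = as.integer(present),
                 x = (st[present, "sum_i"] / n + 0.5) * v,
                 y = (st[present, "sum_j"] / n + 0.5) * v,
                 z = (st[present, "sum_k"] / n + 0.5) * v,
                 n_voxels = as.integer(n))
}

new_rag <- function(nodes, edges, log = NULL) {
  if (is.null(log))
    log <- tibble::tibble(op = character(), a = integer(), b = integer())
  structure(list(nodes = nodes, edges = edges, log = log), class = "rag")
}

#' @export
print.rag <- function(x, ...) {
  cat(sprintf("<rag> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the region adjacency graph of a label volume
#'
#' Nodes sit at tile centroids; an edge links two labels when they have at
#' least `min_contact` face-adjacent (6-neighborhood) voxel pairs, or —
#' to recover neighbors separated by unmineralized intertesseral gaps —
#' when their supports come within `bridge_gap` micrometers of each other
#' (checked by synchronous label dilation of `ceiling(bridge_gap / (2 *
#' voxel))` rounds on each side).
#'
#' @param labels a `label_volume`.
#' @param min_contact minimum face-contact voxel pairs for a direct edge.
#' @param bridge_gap gap-bridging distance in micrometers (0 disables).
#' @return A `rag`: nodes tibble (`id, x, y, z, boundary`), edges tibble
#'   (`a, b, contact, bridged`).
#' @export
build_rag <- function(labels, min_contact = 1, bridge_gap = 0) {
  stopifnot(inherits(labels, "label_volume"))
  nodes <- centroids(labels)
  nodes$boundary <- FALSE
  cc <- cpp_contact_counts(labels$data, dim(labels$data))
  direct <- tibble::tibble(a = cc[, 1], b = cc[, 2], contact = cc[, 3])
  direct <- direct[direct$contact >= min_contact, ]
  edges <- direct
  edges$bridged <- FALSE
  if (bridge_gap > 0) {
    rounds <- ceiling(bridge_gap / (2 * labels$voxel))
    dil <- cpp_dilate_labels(labels$data, dim(labels$data),
                             as.integer(rounds))
    cc2 <- cpp_contact_counts(dil, dim(labels$data))
    key <- paste(edges$a, edges$b)
    add <- !(paste(cc2[, 1], cc2[, 2]) %in% key)
    if (any(add)) {
      edges <- rbind(edges,
                     tibble::tibble(a = cc2[add, 1], b = cc2[add, 2],
                                    contact = 0L, bridged = TRUE))
    }
  }
  edges <- edges[order(edges$a, edges$b), ]
  new_rag(nodes, edges)
}

#' Build a RAG directly from a tessellation
#'
#' Uses the tessellation's cell centers and adjacency (no voxel volume
#' required); boundary cells keep their flag. Useful for mesh and
#' curvature work on generated tessellations.
#'
#' @param tess a `tessellation`.
#' @return A `rag`.
#' @export
rag_from_tessellation <- function(tess) {
  stopifnot(inherits(tess, "tessellation"))
  nodes <- tibble::tibble(id = seq_len(nrow(tess$centers)),
                          x = tess$centers[, 1], y = tess$centers[, 2],
                          z = tess$centers[, 3],
                          n_voxels = NA_integer_,
                          boundary = tess$boundary)
  edges <- tibble::tibble(a = tess$adjacency[, 1], b = tess$adjacency[, 2],
                          contact = NA_integer_, bridged = FALSE)
  new_rag(nodes, edges)
}

#' Edit a RAG
#'
#' Ordered manual corrections: `add(a, b)` inserts an edge between known
#' nodes (contact count 0, marked manual); `remove(a, b)` deletes an
#' existing edge. Every edit is logged.
#'
#' @param graph a `rag`.
#' @param edits list of `rag_add(a, b)` / `rag_remove(a, b)` items.
#' @return The edited `rag`.
#' @export
edit_rag <- function(graph, edits) {
  stopifnot(inherits(graph, "rag"))
  for (e in edits) {
    a <- min(e$a, e$b); b <- max(e$a, e$b)
    if (a == b) stop("self-edges are not allowed", call. = FALSE)
    if (!all(c(a, b) %in% graph$nodes$id))
      stop(sprintf("unknown node id in edit (%d, %d)", a, b), call. = FALSE)
    hit <- graph$edges$a == a & graph$edges$b == b
    if (identical(e$op, "add")) {
      if (!any(hit))
        graph$edges <- rbind(graph$edges,
                             tibble::tibble(a = a, b = b, contact = 0L,
                                            bridged = FALSE))
    } else if (identical(e$op, "remove")) {
      if (!any(hit))
        stop(sprintf("cannot remove nonexistent edge (%d, %d)", a, b),
             call. = FALSE)
      graph$edges <- graph$edges[!hit, ]
    } else stop("unknown edit op: ", e$op, call. = FALSE)
    graph$log <- rbind(graph$log,
                       tibble::tibble(op = e$op, a = a, b = b))
  }
  graph$edges <- graph$edges[order(graph$edges$a, graph$edges$b), ]
  graph
}

#' @rdname edit_rag
#' @param a,b node ids.
#' @export
rag_add <- function(a, b) list(op = "add", a = as.integer(a),
                               b = as.integer(b))

#' @rdname edit_rag
#' @export
rag_remove <- function(a, b) list(op = "remove", a = as.integer(a),
                                  b = as.integer(b))

#' Neighbor counts (polygon classes)
#'
#' A tile's number of RAG neighbors is its polygon class: a hexagonal tile
#' has six edges to six neighbors. Boundary-flagged nodes undercount their
#' sides and are excluded from polygon-class statistics downstream.
#'
#' @param graph a `rag`.
#' @return Tibble `id, n, boundary`.
#' @export
neighbor_counts <- function(graph) {
  stopifnot(inherits(graph, "rag"))
  deg <- table(factor(c(graph$edges$a, graph$edges$b),
                      levels = graph$nodes$id))
  tibble::tibble(id = graph$nodes$id, n = as.integer(deg),
                 boundary = graph$nodes$boundary)
}

#' Flag boundary nodes of a RAG
#'
#' @param graph a `rag`.
#' @param ids node ids to flag as boundary cells.
#' @export
mark_boundary <- function(graph, ids) {
  graph$nodes$boundary <- graph$nodes$boundary | graph$nodes$id %in% ids
  graph
}

#' Write / read a RAG edge list as CSV
#' @param graph a `rag`.
#' @param path CSV path.
#' @export
write_rag_csv <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$edges), path, row.names = FALSE)
  invisible(path)
}
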