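#' Smoothed surface mesh from a RAG
#'
#' Triangulates the coarse surface defined by the tile centers (every
#' 3-clique of the RAG — for Voronoi-derived adjacency these are exactly
#' the Delaunay triangles), subdivides each triangle once at the edge
#' midpoints for a finer mesh, then applies `iterations` rounds of
#' Taubin lambda/mu smoothing (a shrinkage-compensated Laplacian: a plane
#' stays a plane and closed surfaces keep their scale, unlike plain
#' Laplacian smoothing). Triangles are oriented consistently: outward for
#' closed surfaces, along the dominant normal for open patches.
#'
#' @param graph a `rag`.
#' @param iterations smoothing iterations (>= 0); the default is
#'   strong enough that curvature read off the mesh is unbiased by the
#'   subdivision-level faceting at the coarse nodes.
#' @param lambda,mu Taubin smoothing factors.
#' @return A `surface_mesh`: `vertices` (n x 3), `triangles` (m x 3).
#' @export
smooth_surface_from_rag <- function(graph, iterations = 20, lambda = 0.5,
                                    mu = -0.6) {
  stopifnot(inherits(graph, "rag"))
  V <- as.matrix(graph$nodes[, c("x", "y", "z")])
  ids <- graph$nodes$id
  ed <- cbind(match(graph$edges$a, ids), match(graph$edges$b, ids))
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  tris <- rag_triangles(nrow(V), ed)
  if (nrow(tris) == 0)
    stop("RAG has no 3-cliques; not embeddable as a surface triangulation",
         call. = FALSE)
  tris <- orient_triangles(V, tris)
  sub <- subdivide_mesh(V, tris)
  Vs <- taubin_smooth(sub$V, sub$tris, iterations, lambda, mu)
  structure(list(vertices = Vs, triangles = sub$tris,
                 n_nodes = nrow(V)), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

rag_triangles <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  tris <- list()
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    common <- intersect(adj[[a]], adj[[b]])
    common <- common[common > b]  # a < b < c: each clique once
    for (cc in common)
      if (a < b) tris[[length(tris) + 1]] <- c(a, b, cc)
  }
  if (length(tris) == 0) return(matrix(0L, 0, 3))
  unique(do.call(rbind, tris))
}

orient_triangles <- function(V, tris) {
  ctr <- colMeans(V)
  n1 <- t(apply(tris, 1, function(tr) {
    cross3(V[tr[2], ] - V[tr[1], ], V[tr[3], ] - V[tr[1], ])
  }))
  # closed-ish surface (normals align with the radial direction from the
  # centroid): orient outward; flat patch: orient along the dominant normal
  radial <- t(apply(tris, 1, function(tr) colMeans(V[tr, ]) - ctr))
  rad_dot <- rowSums(n1 * radial)
  align <- abs(rad_dot) /
    pmax(sqrt(rowSums(n1^2)) * sqrt(rowSums(radial^2)), 1e-300)
  if (stats::median(align) > 0.5) {
    flip <- rad_dot < 0
  } else {
    dom <- prcomp(V)$rotation[, 3]
    flip <- (n1 %*% dom) < 0
  }
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  tris
}

subdivide_mesh <- function(V, tris) {
  mkey <- new.env(parent = emptyenv())
  verts <- lapply(seq_len(nrow(V)), function(i) V[i, ])
  midpoint <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    id <- mkey[[key]]
    if (is.null(id)) {
      verts[[length(verts) + 1]] <<- (V[a, ] + V[b, ]) / 2
      id <- length(verts)
      assign(key, id, envir = mkey)
    }
    id
  }
  newtris <- vector("list", 4 * nrow(tris))
  for (t in seq_len(nrow(tris))) {
    a <- tris[t, 1]; b <- tris[t, 2]; cc <- tris[t, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
    newtris[[4 * t - 3]] <- c(a, ab, ca)
    newtris[[4 * t - 2]] <- c(ab, b, bc)
    newtris[[4 * t - 1]] <- c(ca, bc, cc)
    newtris[[4 * t]] <- c(ab, bc, ca)
  }
  list(V = do.call(rbind, verts), tris = do.call(rbind, newtris))
}

mesh_neighbor_list <- function(n, tris) {
  adj <- vector("list", n)
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  e <- unique(rbind(e, e[, 2:1]))
  sp <- split(e[, 2], e[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- sp[[nm]]
  adj
}

taubin_smooth <- function(V, tris, iterations, lambda, mu) {
  if (iterations <= 0) return(V)
  adj <- mesh_neighbor_list(nrow(V), tris)
  lap <- function(X) {
    L <- matrix(0, nrow(X), 3)
    for (i in seq_len(nrow(X))) {
      nb <- adj[[i]]
      if (length(nb) > 0) L[i, ] <- colMeans(X[nb, , drop = FALSE]) - X[i, ]
    }
    L
  }
  for (it in seq_len(iterations)) {
    V <- V + lambda * lap(V)
    V <- V + mu * lap(V)
  }
  V
}

#' Principal curvatures on a surface mesh
#'
#' Per-vertex quadric fit over the 2-ring neighborhood in the local normal
#' frame: h(u, v) = a u + b v + (A u^2 + 2 B u v + C v^2) / 2, with the
#' Gaussian and mean curvature of the graph surface evaluated at the
#' vertex. The sign convention makes convex surfaces with outward normals
#' (spheres) have positive mean curvature.
#'
#' Estimates are averaged over each vertex's neighborhood
#' (`smooth_passes` rounds of neighbor averaging) so that the sampled
#' value reflects the local surface rather than the subdivision-level
#' undulation of a single vertex.
#'
#' @param mesh a `surface_mesh`.
#' @param smooth_passes neighbor-averaging rounds applied to the K/H
#'   fields after fitting.
#' @return Matrix with columns `K` (1/um^2) and `H` (1/um) per vertex.
#' @export
mesh_curvature <- function(mesh, smooth_passes = 2) {
  V <- mesh$vertices; tris <- mesh$triangles
  n <- nrow(V)
  # area-weighted vertex normals from oriented faces
  fn <- t(apply(tris, 1, function(tr) {
    cross3(V[tr[2], ] - V[tr[1], ], V[tr[3], ] - V[tr[1], ])
  }))
  vn <- matrix(0, n, 3)
  for (t in seq_len(nrow(tris)))
    for (s in 1:3) vn[tris[t, s], ] <- vn[tris[t, s], ] + fn[t, ]
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
  adj <- mesh_neighbor_list(n, tris)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("K", "H")))
  for (i in seq_len(n)) {
    ring1 <- adj[[i]]
    ring2 <- unique(c(ring1, unlist(adj[ring1])))
    ring2 <- setdiff(ring2, i)
    if (length(ring2) < 5) next
    nrm <- vn[i, ]
    basis <- plane_basis(nrm)
    rel <- sweep(V[ring2, , drop = FALSE], 2, V[i, ])
    u <- rel %*% basis[, 1]; v <- rel %*% basis[, 2]
    h <- rel %*% nrm
    X <- cbind(u, v, u^2 / 2, u * v, v^2 / 2)
    fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, h)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    a <- fit[1]; b <- fit[2]; A <- fit[3]; B <- fit[4]; C <- fit[5]
    g <- 1 + a^2 + b^2
    K <- (A * C - B^2) / g^2
    H <- (A * (1 + b^2) - 2 * B * a * b + C * (1 + a^2)) / (2 * g^1.5)
    # outward-normal convention: a sphere bends away from the tangent
    # plane along -normal, so flip H to make convexity positive
    out[i, ] <- c(K, -H)
  }
  for (p in seq_len(smooth_passes)) {
    sm <- out
    for (i in seq_len(n)) {
      nb <- c(i, adj[[i]])
      vals <- out[nb, , drop = FALSE]
      ok <- stats::complete.cases(vals)
      if (any(ok)) sm[i, ] <- colMeans(vals[ok, , drop = FALSE])
    }
    out <- sm
  }
  out
}

#' Curvature at the mesh point nearest a tessera center
#'
#' @param mesh a `surface_mesh` (curvatures are computed and cached on
#'   first use).
#' @param center tessera center, length-3 (micrometers).
#' @return `c(K, H)`.
#' @export
tessera_curvature <- function(mesh, center) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0) stop("empty mesh", call. = FALSE)
  kh <- attr(mesh, "curvature")
  if (is.null(kh)) kh <- mesh_curvature(mesh)
  nn <- RANN::nn2(mesh$vertices, matrix(center, 1), k = 1)
  kh[nn$nn.idx[1, 1], ]
}

#' Cache curvatures on a mesh
#' @param mesh a `surface_mesh`.
#' @return The mesh with a `"curvature"` attribute attached.
#' @export
with_curvature <- function(mesh) {
  attr(mesh, "curvature") <- mesh_curvature(mesh)
  mesh
}
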