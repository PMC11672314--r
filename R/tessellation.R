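#' Tessellation objects
#'
#' The combinatorial-geometric container used for topology and geometry
#' operations: deduplicated vertex positions (micrometers, embedded in 3D),
#' faces as ordered vertex-index rings, per-face side counts, cell
#' seed/center positions, cell adjacency pairs and a `closed` flag (TRUE
#' when the tessellation has no boundary).
#'
#' @param vertices numeric matrix (V x 3) of vertex positions.
#' @param faces list of integer vertex-index rings (each >= 3 distinct).
#' @param centers numeric matrix (F x 3) of cell seed/center positions.
#' @param adjacency 2-column integer matrix of neighboring cell pairs.
#' @param closed logical; TRUE when every edge borders exactly two faces.
#' @param boundary logical vector flagging boundary cells (open surfaces).
#' @param surface optional [surface_spec()] the tessellation lives on.
#' @return A `tessellation` object.
#' @export
new_tessellation <- function(vertices, faces, centers, adjacency,
                             closed = FALSE, boundary = NULL,
                             surface = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) == 2) vertices <- cbind(vertices, 0)
  centers <- as.matrix(centers)
  if (ncol(centers) == 2) centers <- cbind(centers, 0)
  sides <- lengths(faces)
  if (any(sides < 3) || any(vapply(faces, anyDuplicated, 1L) > 0))
    stop("each face ring needs >= 3 distinct vertices", call. = FALSE)
  adjacency <- matrix(as.integer(adjacency), ncol = 2)
  adjacency <- unique(t(apply(adjacency, 1, sort)))
  if (is.null(boundary)) boundary <- rep(FALSE, length(faces))
  tess <- structure(list(vertices = vertices, faces = faces,
                         sides = as.integer(sides), centers = centers,
                         adjacency = adjacency, closed = isTRUE(closed),
                         boundary = boundary, surface = surface),
                    class = "tessellation")
  if (tess$closed) {
    ec <- edge_face_count(tess)
    if (any(ec != 2L))
      stop("closed tessellation has edges not bordering exactly 2 faces",
           call. = FALSE)
  }
  tess
}

#' @export
print.tessellation <- function(x, ...) {
  cat(sprintf("<tessellation> %d cells, %d vertices, %s%s\n",
              length(x$faces), nrow(x$vertices),
              if (x$closed) "closed" else "open",
              if (!is.null(x$surface)) paste0(" (", x$surface$kind, ")") else ""))
  invisible(x)
}

# Unique undirected edges from face rings, as a 2-column matrix.
tess_edges <- function(tess) {
  e <- do.call(rbind, lapply(tess$faces, function(f) {
    cbind(f, c(f[-1], f[1]))
  }))
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

edge_face_count <- function(tess) {
  e <- do.call(rbind, lapply(tess$faces, function(f) {
    cbind(f, c(f[-1], f[1]))
  }))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

# Number of faces incident to each vertex index.
vertex_face_count <- function(tess) {
  idx <- unlist(tess$faces)
  tabulate(idx, nbins = nrow(tess$vertices))
}

#' Cell areas of a tessellation
#'
#' Planar cells use the shoelace formula; spherical cells use the
#' spherical-excess formula (cells are convex).
#'
#' @param tess a tessellation.
#' @return Numeric vector of per-cell areas (square micrometers).
#' @export
tess_cell_areas <- function(tess) {
  kind <- if (!is.null(tess$surface)) tess$surface$kind else "plane"
  if (kind == "sphere") {
    R <- tess$surface$radius
    vapply(tess$faces, function(f) {
      sph_polygon_area(tess$vertices[f, , drop = FALSE] / R) * R^2
    }, 1.0)
  } else {
    vapply(tess$faces, function(f) {
      shoelace_area(tess$vertices[f, 1], tess$vertices[f, 2])
    }, 1.0)
  }
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Area of a convex spherical polygon with unit-vector vertices (CCW from
# outside), on the unit sphere: spherical excess.
sph_polygon_area <- function(v) {
  m <- nrow(v)
  ang <- numeric(m)
  for (t in seq_len(m)) {
    p <- v[if (t == 1) m else t - 1, ]
    c0 <- v[t, ]
    nx <- v[if (t == m) 1 else t + 1, ]
    t1 <- p - sum(p * c0) * c0
    t2 <- nx - sum(nx * c0) * c0
    cosang <- sum(t1 * t2) / sqrt(sum(t1^2) * sum(t2^2))
    ang[t] <- acos(pmin(1, pmax(-1, cosang)))
  }
  sum(ang) - (m - 2) * pi
}

#' Voronoi tessellation of points on a surface
#'
#' Equipartitions the surface among seed points: each location belongs to
#' its nearest seed. Planar diagrams are computed with \pkg{deldir}
#' (clipped to the extent rectangle, boundary cells flagged); spherical
#' diagrams are built per cell by half-plane clipping in the gnomonic
#' projection (great-circle bisectors project to straight lines), then
#' cross-verified against nearest-seed queries; cylindrical diagrams unroll
#' the surface with periodic ghost copies.
#'
#' @param points point tibble/matrix as produced by
#'   [sample_hardcore_points()] (plane: `x, y`; sphere: `x, y, z`;
#'   cylinder: `arc, z`).
#' @param surface a [surface_spec()].
#' @return A `tessellation`; `closed` is TRUE for the sphere. Cells whose
#'   polygon is clipped by the domain boundary are flagged in `boundary`.
#' @export
voronoi_tessellation <- function(points, surface) {
  stopifnot(inherits(surface, "surface_spec"))
  pts <- as.matrix(points)
  switch(surface$kind,
         plane = ,
         slab_shell = planar_voronoi(pts, surface),
         sphere = spherical_voronoi(pts, surface),
         cylinder = cylinder_voronoi(pts, surface))
}

planar_voronoi <- function(pts, surface) {
  if (nrow(pts) < 2)
    stop("planar Voronoi needs >= 2 points", call. = FALSE)
  lx <- surface$extent[1]; ly <- surface$extent[2]
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = c(0, lx, 0, ly),
                       suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  eps <- 1e-9 * max(lx, ly)
  vkey <- new.env(parent = emptyenv())
  verts <- list(); nv <- 0
  faces <- vector("list", length(tl))
  boundary <- logical(length(tl))
  for (i in seq_along(tl)) {
    px <- tl[[i]]$x; py <- tl[[i]]$y
    ring <- integer(length(px))
    for (t in seq_along(px)) {
      key <- paste(round(px[t] / eps), round(py[t] / eps))
      id <- vkey[[key]]
      if (is.null(id)) {
        nv <- nv + 1; id <- nv
        verts[[nv]] <- c(px[t], py[t], 0)
        assign(key, id, envir = vkey)
      }
      ring[t] <- id
    }
    ring <- ring[!duplicated(ring)]
    faces[[i]] <- ring
    boundary[i] <- any(px < eps | px > lx - eps | py < eps | py > ly - eps)
  }
  ds <- dd$dirsgs
  nonzero <- (ds$x1 - ds$x2)^2 + (ds$y1 - ds$y2)^2 > eps^2
  adj <- cbind(ds$ind1[nonzero], ds$ind2[nonzero])
  new_tessellation(do.call(rbind, verts), faces, cbind(pts[, 1:2], 0), adj,
                   closed = FALSE, boundary = boundary, surface = surface)
}

# Clip a convex polygon (rows of P, CCW) with edge labels elab (elab[t] is
# the label of the edge from vertex t to t+1) by half-plane
# c0 + a*u + b*v >= 0; inserted edges get label j.
clip_halfplane <- function(P, elab, a, b, c0, j) {
  m <- nrow(P)
  if (m == 0) return(list(P = P, elab = elab))
  vals <- c0 + a * P[, 1] + b * P[, 2]
  keep <- vals >= 0
  if (all(keep)) return(list(P = P, elab = elab))
  if (!any(keep)) return(list(P = P[0, , drop = FALSE], elab = integer(0)))
  Q <- list(); ql <- integer(0)
  for (t in seq_len(m)) {
    t2 <- if (t == m) 1 else t + 1
    if (keep[t]) {
      Q[[length(Q) + 1]] <- P[t, ]; ql <- c(ql, elab[t])
      if (!keep[t2]) {  # leaving: cut point, then travel along clip line
        s <- vals[t] / (vals[t] - vals[t2])
        Q[[length(Q) + 1]] <- P[t, ] + s * (P[t2, ] - P[t, ])
        ql <- c(ql, j)
      }
    } else if (keep[t2]) {  # entering: cut point resumes original edge
      s <- vals[t] / (vals[t] - vals[t2])
      Q[[length(Q) + 1]] <- P[t, ] + s * (P[t2, ] - P[t, ])
      ql <- c(ql, elab[t])
    }
  }
  list(P = do.call(rbind, Q), elab = ql)
}

spherical_voronoi <- function(pts, surface) {
  R <- surface$radius
  n <- nrow(pts)
  if (n < 4)
    stop("spherical Voronoi needs >= 4 points", call. = FALSE)
  q <- pts / sqrt(rowSums(pts^2))  # unit directions
  rings <- vector("list", n)       # per cell: neighbor ids in CCW order
  W <- 10                          # gnomonic half-width (~84 deg)
  for (i in seq_len(n)) {
    qi <- q[i, ]
    # orthonormal tangent basis, right-handed with qi
    ref <- if (abs(qi[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * qi) * qi; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(qi[2] * e1[3] - qi[3] * e1[2],
            qi[3] * e1[1] - qi[1] * e1[3],
            qi[1] * e1[2] - qi[2] * e1[1])
    cosang <- q %*% qi
    ord <- order(-cosang)
    ord <- ord[ord != i]
    k <- min(n - 1, 18)
    repeat {
      P <- rbind(c(-W, -W), c(W, -W), c(W, W), c(-W, W))
      elab <- c(0L, 0L, 0L, 0L)
      for (j in ord[seq_len(k)]) {
        qj <- q[j, ]
        cl <- clip_halfplane(P, elab,
                             a = -sum(e1 * qj), b = -sum(e2 * qj),
                             c0 = 1 - sum(qi * qj), j = j)
        P <- cl$P; elab <- cl$elab
        if (nrow(P) == 0)
          stop(sprintf("degenerate spherical Voronoi cell %d (empty cell)",
                       i), call. = FALSE)
      }
      if (any(elab == 0L)) {
        if (k == n - 1)
          stop(sprintf(paste0("spherical Voronoi cell %d unbounded within ",
                              "the gnomonic window; configuration too ",
                              "sparse or degenerate"), i), call. = FALSE)
        k <- min(n - 1, 2 * k); next
      }
      # guarantee: all bisectors that can cut the cell are within the
      # candidate set when the k-th candidate angle >= 2 * max vertex angle
      vmax <- sqrt(max(P[, 1]^2 + P[, 2]^2))
      theta_max <- atan(vmax)
      ang_k <- acos(pmin(1, pmax(-1, cosang[ord[k]])))
      if (k == n - 1 || ang_k >= 2 * theta_max) break
      k <- min(n - 1, 2 * k)
    }
    rings[[i]] <- as.integer(elab)
  }
  # symmetric adjacency check
  adj <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(pmin(i, rings[[i]]), pmax(i, rings[[i]]))
  })))
  for (r in seq_len(nrow(adj))) {
    a <- adj[r, 1]; b <- adj[r, 2]
    if (!(a %in% rings[[b]]) || !(b %in% rings[[a]]))
      stop(sprintf(paste0("degenerate configuration: adjacency %d-%d not ",
                          "symmetric (near-cospherical seeds)"), a, b),
           call. = FALSE)
  }
  # vertices from sorted cell triples (trivalent for generic seeds)
  vkey <- new.env(parent = emptyenv())
  verts <- list(); nv <- 0
  faces <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- rings[[i]]
    m <- length(nb)
    ring <- integer(m)
    for (t in seq_len(m)) {
      jprev <- nb[if (t == 1) m else t - 1]
      jcur <- nb[t]
      tri <- sort(c(i, jprev, jcur))
      key <- paste(tri, collapse = "-")
      id <- vkey[[key]]
      if (is.null(id)) {
        v <- cross3(q[tri[2], ] - q[tri[1], ], q[tri[3], ] - q[tri[1], ])
        v <- v / sqrt(sum(v^2))
        if (sum(v * q[tri[1], ]) < 0) v <- -v
        nv <- nv + 1; id <- nv
        verts[[nv]] <- v * R
        assign(key, id, envir = vkey)
      }
      ring[t] <- id
    }
    faces[[i]] <- ring
  }
  V <- do.call(rbind, verts)
  # cross-verify ownership: the 3 nearest seeds of each vertex must all be
  # incident (equidistant); use chord distance (monotone with the angle)
  nn <- RANN::nn2(q * R, V, k = min(n, 4))
  d3 <- nn$nn.dists[, 3]; d1 <- nn$nn.dists[, 1]
  if (any(d3 - d1 > 1e-6 * R))
    stop("spherical Voronoi verification failed: vertex not equidistant ",
         "to its three defining seeds", call. = FALSE)
  new_tessellation(V, faces, q * R, adj, closed = TRUE,
                   boundary = rep(FALSE, n), surface = surface)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

cylinder_voronoi <- function(pts, surface) {
  R <- surface$radius; L <- surface$extent[1]
  circ <- 2 * pi * R
  n <- nrow(pts)
  if (n < 2) stop("cylindrical Voronoi needs >= 2 points", call. = FALSE)
  x <- pts[, 1] %% circ; z <- pts[, 2]
  gx <- c(x - circ, x, x + circ)
  gz <- rep(z, 3)
  dd <- deldir::deldir(gx, gz, rw = c(-circ, 2 * circ, 0, L),
                       suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  mid <- (n + 1):(2 * n)
  eps <- 1e-9 * max(circ, L)
  vkey <- new.env(parent = emptyenv())
  verts <- list(); nv <- 0
  faces <- vector("list", n)
  boundary <- logical(n)
  for (ii in seq_along(mid)) {
    tile <- tl[[mid[ii]]]
    px <- tile$x %% circ; pz <- tile$y
    ring <- integer(length(px))
    for (t in seq_along(px)) {
      th <- px[t] / R
      p3 <- c(R * cos(th), R * sin(th), pz[t])
      key <- paste(round(p3 / eps), collapse = " ")
      id <- vkey[[key]]
      if (is.null(id)) {
        nv <- nv + 1; id <- nv
        verts[[nv]] <- p3
        assign(key, id, envir = vkey)
      }
      ring[t] <- id
    }
    ring <- ring[!duplicated(ring)]
    faces[[ii]] <- ring
    boundary[ii] <- any(tile$y < eps | tile$y > L - eps)
  }
  ds <- dd$dirsgs
  nonzero <- (ds$x1 - ds$x2)^2 + (ds$y1 - ds$y2)^2 > eps^2
  a <- (ds$ind1[nonzero] - 1) %% n + 1
  b <- (ds$ind2[nonzero] - 1) %% n + 1
  keepmid <- ds$ind1[nonzero] %in% mid | ds$ind2[nonzero] %in% mid
  adj <- cbind(a, b)[keepmid & a != b, , drop = FALSE]
  th <- x / R
  centers <- cbind(R * cos(th), R * sin(th), z)
  new_tessellation(do.call(rbind, verts), faces, centers, adj,
                   closed = FALSE, boundary = boundary, surface = surface)
}

#' Goldberg tessellation of the sphere
#'
#' A closed trivalent tiling with exactly 12 pentagonal faces and otherwise
#' hexagons, built as the dual of a class-I subdivided icosahedron (the
#' fullerene construction). `frequency = 0` gives the dodecahedron.
#'
#' @param frequency integer >= 0; each icosahedron edge is divided into
#'   `frequency + 1` segments before dualizing.
#' @param radius sphere radius (micrometers).
#' @return A closed `tessellation` with `10 * (frequency + 1)^2 + 2` faces.
#' @export
goldberg_tessellation <- function(frequency = 0, radius = 1) {
  if (frequency < 0 || frequency != round(frequency))
    stop("`frequency` must be a non-negative integer", call. = FALSE)
  nu <- frequency + 1
  ico <- icosahedron()
  vkey <- new.env(parent = emptyenv())
  verts <- list(); nv <- 0
  getid <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(round(p * 1e8), collapse = " ")
    id <- vkey[[key]]
    if (is.null(id)) {
      nv <<- nv + 1; id <- nv
      verts[[nv]] <<- p
      assign(key, id, envir = vkey)
    }
    id
  }
  tris <- list()
  for (f in seq_len(nrow(ico$faces))) {
    A <- ico$verts[ico$faces[f, 1], ]
    B <- ico$verts[ico$faces[f, 2], ]
    C <- ico$verts[ico$faces[f, 3], ]
    # lattice ids for points P(i, j) = A + i/nu (B-A) + j/nu (C-A)
    ids <- matrix(NA_integer_, nu + 1, nu + 1)
    for (i in 0:nu) for (j in 0:(nu - i))
      ids[i + 1, j + 1] <- getid(A + (i / nu) * (B - A) + (j / nu) * (C - A))
    for (i in 0:(nu - 1)) for (j in 0:(nu - 1 - i)) {
      tris[[length(tris) + 1]] <-
        c(ids[i + 1, j + 1], ids[i + 2, j + 1], ids[i + 1, j + 2])
      if (j <= nu - 2 - i)
        tris[[length(tris) + 1]] <-
          c(ids[i + 2, j + 1], ids[i + 2, j + 2], ids[i + 1, j + 2])
    }
  }
  V <- do.call(rbind, verts)
  dual_of_triangulation(V * radius, do.call(rbind, tris),
                        project_radius = radius,
                        surface = surface_spec("sphere", radius = radius))
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(verts = v, faces = f)
}

#' Dual tessellation of a closed, consistently oriented triangulation
#'
#' One dual face per triangulation vertex; the dual face ring walks the
#' incident triangles in orientation order (a purely combinatorial walk, so
#' it also works for non-spherical embeddings such as tori). Dual vertices
#' sit at triangle centroids, optionally projected back to a sphere.
#'
#' @param verts triangulation vertex positions (n x 3).
#' @param tris integer matrix (m x 3) of consistently oriented triangles.
#' @param project_radius if non-NULL, dual vertices are radially projected
#'   to a sphere of this radius.
#' @param surface optional [surface_spec()] tag.
#' @return A closed trivalent `tessellation`.
#' @export
dual_of_triangulation <- function(verts, tris, project_radius = NULL,
                                  surface = NULL) {
  verts <- as.matrix(verts)
  tris <- as.matrix(tris)
  nV <- nrow(verts); nT <- nrow(tris)
  cent <- (verts[tris[, 1], , drop = FALSE] +
           verts[tris[, 2], , drop = FALSE] +
           verts[tris[, 3], , drop = FALSE]) / 3
  if (!is.null(project_radius))
    cent <- project_radius * cent / sqrt(rowSums(cent^2))
  # directed-edge map: in oriented triangle (a, b, c), edge a->b belongs to
  # this triangle; the adjacent triangle holds b->a.
  ekey <- paste(tris[, 1], tris[, 2], sep = "-")
  ekey <- c(ekey, paste(tris[, 2], tris[, 3], sep = "-"),
            paste(tris[, 3], tris[, 1], sep = "-"))
  etri <- rep(seq_len(nT), 3)
  emap <- new.env(parent = emptyenv())
  for (t in seq_along(ekey)) assign(ekey[t], etri[t], envir = emap)
  # incident triangles per vertex (any one to start the walk)
  start <- integer(nV)
  for (t in seq_len(nT)) for (s in 1:3) start[tris[t, s]] <- t
  deg <- tabulate(as.vector(tris), nbins = nV)
  faces <- vector("list", nV)
  for (v in seq_len(nV)) {
    ring <- integer(deg[v])
    t <- start[v]
    for (s in seq_len(deg[v])) {
      ring[s] <- t
      tv <- tris[t, ]
      pos <- which(tv == v)
      b <- tv[if (pos == 3) 1 else pos + 1]  # edge v -> b in this triangle
      t2 <- emap[[paste(b, v, sep = "-")]]   # triangle holding b -> v
      if (is.null(t2))
        stop("triangulation is not closed at vertex ", v, call. = FALSE)
      t <- t2
    }
    faces[[v]] <- ring
  }
  e <- unique(rbind(
    cbind(pmin(tris[, 1], tris[, 2]), pmax(tris[, 1], tris[, 2])),
    cbind(pmin(tris[, 2], tris[, 3]), pmax(tris[, 2], tris[, 3])),
    cbind(pmin(tris[, 3], tris[, 1]), pmax(tris[, 3], tris[, 1]))))
  new_tessellation(cent, faces, verts, e, closed = TRUE,
                   boundary = rep(FALSE, nV), surface = surface)
}

#' Toroidal hexagonal tessellation
#'
#' A closed trivalent all-hexagon tiling of the torus (the dual of a p x q
#' triangular lattice with periodic wrap), useful as a genus-1 reference:
#' its Euler characteristic is 0 and its hexagonal deficiency is 0.
#'
#' @param p,q lattice periods (>= 3 each, so faces stay simple rings).
#' @param R0,r major/minor torus radii for the 3D embedding.
#' @return A closed `tessellation` with `p * q` hexagonal faces.
#' @export
toroidal_hex_tessellation <- function(p = 4, q = 4, R0 = 3, r = 1) {
  if (p < 3 || q < 3) stop("`p` and `q` must be >= 3", call. = FALSE)
  id <- function(i, j) (i %% p) + p * (j %% q) + 1
  verts <- matrix(0, p * q, 3)
  for (j in 0:(q - 1)) for (i in 0:(p - 1)) {
    th <- 2 * pi * (i + j / 2) / p
    ph <- 2 * pi * j / q
    verts[id(i, j), ] <- c((R0 + r * cos(ph)) * cos(th),
                           (R0 + r * cos(ph)) * sin(th),
                           r * sin(ph))
  }
  tris <- list()
  for (j in 0:(q - 1)) for (i in 0:(p - 1)) {
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
    tris[[length(tris) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  dual_of_triangulation(verts, do.call(rbind, tris))
}

#' Triangular-lattice seed points (hexagonal Voronoi cells)
#'
#' Interior Voronoi cells of this lattice are regular hexagons of area
#' `sqrt(3)/2 * spacing^2`.
#'
#' @param nx,ny lattice counts.
#' @param spacing nearest-neighbor distance (micrometers).
#' @return Tibble of `x, y` plus the enclosing plane [surface_spec()] in
#'   attribute `"surface"`.
#' @export
hex_lattice_points <- function(nx, ny, spacing = 1) {
  i <- rep(seq_len(nx) - 1, times = ny)
  j <- rep(seq_len(ny) - 1, each = nx)
  x <- (i + 0.5 * (j %% 2)) * spacing + spacing / 2
  y <- j * spacing * sqrt(3) / 2 + spacing / 2
  surf <- surface_spec("plane",
                       extent = c(max(x) + spacing / 2,
                                  max(y) + spacing / 2))
  out <- tibble::tibble(x = x, y = y)
  attr(out, "surface") <- surf
  out
}
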