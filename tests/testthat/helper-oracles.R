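# Independent oracles used across the suite. These deliberately avoid the
# package's own kernels: brute-force distance scans, pure-R flood fills and
# a merge-tree watershed computed by exhaustive level sweeping.

# Brute-force EDT: per foreground voxel, min Euclidean distance to any
# background voxel. O(n^2); only for tiny volumes.
bf_edt <- function(fg, voxel = 1) {
  d <- dim(fg)
  idx_fg <- which(fg)
  idx_bg <- which(!fg)
  co_fg <- arrayInd(idx_fg, d)
  co_bg <- arrayInd(idx_bg, d)
  out <- array(0, d)
  for (t in seq_along(idx_fg)) {
    dd <- sqrt(colSums((t(co_bg) - co_fg[t, ])^2))
    out[idx_fg[t]] <- min(dd) * voxel
  }
  out
}

# Pure-R 2D connected components, 8-connectivity.
bf_components2d <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      ij <- arrayInd(v, d)
      for (di in -1:1) for (dj in -1:1) {
        i <- ij[1] + di; j <- ij[2] + dj
        if (i < 1 || j < 1 || i > d[1] || j > d[2]) next
        w <- i + (j - 1) * d[1]
        if (mask[w] && lab[w] == 0L) { lab[w] <- nxt; stack <- c(stack, w) }
      }
    }
  }
  lab
}

# Merge-tree watershed oracle on a 2D height map: sweeps unique heights in
# decreasing order, tracks basins (born at new superlevel components) and
# merges pairs meeting at a saddle when min(peaks) - saddle < persistence.
# Returns the number of surviving basins.
bf_watershed_count <- function(img, persistence) {
  hs <- sort(unique(img[img > 0]), decreasing = TRUE)
  basins <- list()  # each: list(rep = linear index of its max, peak)
  alive <- logical(0)
  for (h in hs) {
    lab <- bf_components2d(img >= h)
    comp_of_basin <- vapply(basins, function(b) lab[b$rep], 1L)
    alive0 <- alive
    for (cid in unique(lab[lab > 0])) {
      members <- which(alive0 & comp_of_basin == cid)
      if (length(members) == 0) {
        rep_idx <- which(img == max(img[lab == cid]) & lab == cid)[1]
        basins[[length(basins) + 1]] <- list(rep = rep_idx,
                                             peak = max(img[lab == cid]))
        alive <- c(alive, TRUE)
      } else if (length(members) > 1) {
        peaks <- vapply(basins[members], function(b) b$peak, 1.0)
        keep <- members[which.max(peaks)]
        for (m in setdiff(members, keep)) {
          if (min(basins[[m]]$peak, basins[[keep]]$peak) - h < persistence)
            alive[m] <- FALSE
        }
      }
    }
  }
  sum(alive)
}

# Shoelace polygon area for closed-form geometry checks.
bf_shoelace <- function(x, y) {
  n <- length(x); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Build a two-blob dumbbell mask (balls of radius r at c1, c2, optional
# connecting cylinder of radius rb along x).
dumbbell_mask <- function(dims, c1, c2, r, bridge_r = 0) {
  d <- dims
  co <- arrayInd(seq_len(prod(d)), d)
  m1 <- colSums((t(co) - c1)^2) <= r^2
  m2 <- colSums((t(co) - c2)^2) <= r^2
  m <- m1 | m2
  if (bridge_r > 0) {
    onx <- co[, 1] >= min(c1[1], c2[1]) & co[, 1] <= max(c1[1], c2[1])
    rad <- (co[, 2] - c1[2])^2 + (co[, 3] - c1[3])^2
    m <- m | (onx & rad <= bridge_r^2)
  }
  array(m, d)
}

# Small default-style phantom used by several suites (fast to build).
small_phantom <- function(n = 25, extent = 300, gap = 10, seed = 7,
                          lacunae = c(2, 7.5), noise_sd = 0.1,
                          shell = 60) {
  surf <- surface_spec("slab_shell", extent = c(extent, extent))
  pts <- sample_hardcore_points(surf, n, min_spacing = 40, seed = seed)
  tess <- voronoi_tessellation(pts, surf)
  voxelize_shell(tess, shell_thickness = shell, gap_width = gap, voxel = 5,
                 lacunae = lacunae, noise_sd = noise_sd, blur_sigma = 2,
                 seed = seed)
}

# Match segmentation labels to phantom truth ids via nearest centroids.
match_to_truth <- function(labels, phantom) {
  cen <- centroids(labels)
  tr <- phantom$truth
  nn <- RANN::nn2(as.matrix(tr[, c("x", "y", "z")]),
                  as.matrix(cen[, c("x", "y", "z")]), k = 1)
  tibble::tibble(seg_id = cen$id, truth_id = tr$id[nn$nn.idx[, 1]])
}
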