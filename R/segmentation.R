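#' Grayscale thresholding
#'
#' Foreground is every voxel with intensity at or above `level`, mirroring
#' plain grayscale segmentation of mineralized tissue against background.
#'
#' @param gray a `gray_volume`.
#' @param level threshold intensity.
#' @return A `binary_volume`.
#' @export
threshold_volume <- function(gray, level) {
  stopifnot(inherits(gray, "gray_volume"))
  binary_volume(gray$data >= level, gray$voxel)
}

#' Otsu threshold suggestion
#'
#' Histogram-based between-class variance maximization over 256 bins.
#' Returned, never applied automatically: thresholds remain the caller's
#' explicit choice.
#'
#' @param gray a `gray_volume`.
#' @return Suggested threshold level (intensity units).
#' @export
otsu_level <- function(gray) {
  x <- as.vector(gray$data)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(256L, 1L + floor((x - rng[1]) / diff(rng) * 256)), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  rng[1] + (k / 256) * diff(rng)
}

#' Clean a binary volume
#'
#' Removes connected foreground components smaller than `min_component`
#' voxels (26-connectivity) and fills background voids that are fully
#' enclosed by foreground (6-connectivity components not reaching the
#' volume border) of at most `max_void_extent` voxels — the lacunar gaps
#' inside tiles. Idempotent.
#'
#' @param bin a `binary_volume`.
#' @param min_component minimum foreground component size in voxels.
#' @param fill_enclosed_voids fill enclosed background pockets?
#' @param max_void_extent largest void size (voxels) to fill.
#' @return A cleaned `binary_volume`.
#' @export
clean_binary <- function(bin, min_component = 0, fill_enclosed_voids = TRUE,
                         max_void_extent = Inf) {
  stopifnot(inherits(bin, "binary_volume"))
  if (min_component < 0 || max_void_extent < 0)
    stop("cleaning parameters must be >= 0", call. = FALSE)
  fg <- bin$data
  d <- dim(fg)
  if (min_component > 0 && any(fg)) {
    cc <- cpp_label_components(fg, d, 26L)
    sizes <- tabulate(cc, nbins = max(cc))
    fg[cc > 0 & sizes[pmax(cc, 1L)] < min_component] <- FALSE
  }
  if (fill_enclosed_voids && any(!fg)) {
    bg <- cpp_label_components(!fg, d, 6L)
    border_ids <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                           bg[, , 1], bg[, , d[3]]))
    border_ids <- border_ids[border_ids > 0]
    sizes <- tabulate(bg, nbins = max(bg))
    enclosed <- setdiff(which(sizes <= max_void_extent), border_ids)
    if (length(enclosed) > 0)
      fg[bg %in% enclosed] <- TRUE
  }
  binary_volume(fg, bin$voxel)
}

#' Euclidean distance transforms
#'
#' `distance_map()` gives each foreground voxel its exact Euclidean
#' distance (micrometers) to the nearest background voxel (0 on
#' background). `signed_distance_map()` gives the signed variant: negative
#' inside the foreground, positive outside, magnitude the distance to the
#' foreground/background interface.
#'
#' @param bin a `binary_volume` with non-empty foreground (and, for the
#'   unsigned map, non-empty background).
#' @return A `distance_volume`.
#' @export
distance_map <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$data)) stop("empty foreground", call. = FALSE)
  if (all(bin$data))
    stop("all-foreground volume: no background reference for distances",
         call. = FALSE)
  distance_volume(cpp_edt(bin$data, dim(bin$data), bin$voxel), bin$voxel,
                  signed = FALSE)
}

#' @rdname distance_map
#' @export
signed_distance_map <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$data) || all(bin$data))
    stop("signed distance needs non-empty foreground and background",
         call. = FALSE)
  d <- dim(bin$data)
  inside <- cpp_edt(bin$data, d, bin$voxel)
  outside <- cpp_edt(!bin$data, d, bin$voxel)
  distance_volume(outside - inside, bin$voxel, signed = TRUE)
}

#' Hierarchical watershed instance segmentation
#'
#' Partitions the foreground of an unsigned distance map into labels grown
#' from distance maxima. Pairs of maxima whose separating saddle is
#' shallower than `persistence` (micrometers of distance depth) are merged
#' before basins are kept apart; voxels reachable by several surviving
#' basins join the one with the smaller label id (deterministic tie rule).
#'
#' @param dist an unsigned `distance_volume` (from [distance_map()]).
#' @param persistence saddle-depth merging threshold (micrometers, >= 0).
#' @param connectivity voxel neighborhood: 6, 18 or 26.
#' @return A `label_volume`; background stays 0.
#' @export
watershed_instances <- function(dist, persistence = 0, connectivity = 26) {
  stopifnot(inherits(dist, "distance_volume"))
  if (isTRUE(dist$signed))
    stop("watershed expects the unsigned distance map", call. = FALSE)
  if (persistence < 0) stop("`persistence` must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  lab <- cpp_watershed(dist$data, dim(dist$data), persistence,
                       as.integer(connectivity))
  label_volume(lab, dist$voxel)
}

#' Label proofreading edits
#'
#' Scriptable replacements for interactive proofreading: `merge_edit(a, b)`
#' relabels `b` into `a`; `split_edit(id, seeds)` re-runs a marker-based
#' watershed inside the support of `id` from the given seed points (world
#' micrometers, one row per marker); the first seed keeps the original id,
#' the rest get fresh ids. Edits are applied in order and appended to the
#' volume's edit log.
#'
#' @param labels a `label_volume`.
#' @param edits list of [merge_edit()] / [split_edit()] items.
#' @return The edited `label_volume`.
#' @export
edit_labels <- function(labels, edits) {
  stopifnot(inherits(labels, "label_volume"))
  out <- labels
  for (e in edits) {
    if (identical(e$op, "merge")) {
      out <- apply_merge(out, e$a, e$b)
    } else if (identical(e$op, "split")) {
      out <- apply_split(out, e$id, e$seeds)
    } else stop("unknown edit op: ", e$op, call. = FALSE)
  }
  out
}

#' @rdname edit_labels
#' @param a,b label ids to merge (`b` is relabeled to `a`).
#' @export
merge_edit <- function(a, b) list(op = "merge", a = as.integer(a),
                                  b = as.integer(b))

#' @rdname edit_labels
#' @param id label id to split.
#' @param seeds numeric matrix of marker points (rows; world micrometers).
#' @export
split_edit <- function(id, seeds) list(op = "split", id = as.integer(id),
                                       seeds = as.matrix(seeds))

apply_merge <- function(labels, a, b) {
  present <- unique(as.vector(labels$data))
  if (!a %in% present || !b %in% present)
    stop(sprintf("merge(%d, %d): unknown label id", a, b), call. = FALSE)
  labels$data[labels$data == b] <- as.integer(a)
  labels$log <- rbind(labels$log,
                      tibble::tibble(op = "merge", a = as.integer(a),
                                     b = as.integer(b), detail = ""))
  labels
}

apply_split <- function(labels, id, seeds) {
  d <- dim(labels$data)
  support <- labels$data == id
  if (!any(support)) stop(sprintf("split(%d): unknown label id", id),
                          call. = FALSE)
  vox <- labels$voxel
  idx <- round(seeds / vox + 0.5)  # world -> 1-based voxel index
  markers <- array(0L, d)
  for (s in seq_len(nrow(idx))) {
    i <- idx[s, 1]; j <- idx[s, 2]; k <- idx[s, 3]
    if (any(c(i, j, k) < 1) || i > d[1] || j > d[2] || k > d[3] ||
        !support[i, j, k])
      stop(sprintf("split(%d): seed %d outside the label's support", id, s),
           call. = FALSE)
    markers[i, j, k] <- s
  }
  edt <- cpp_edt(support, d, vox)
  part <- cpp_marker_watershed(edt, d, markers, support, 26L)
  newids <- c(id, max(labels$data) + seq_len(nrow(idx) - 1))
  labels$data[support] <- as.integer(newids[part[support]])
  labels$log <- rbind(labels$log,
                      tibble::tibble(op = "split", a = as.integer(id),
                                     b = NA_integer_,
                                     detail = paste(newids, collapse = ",")))
  labels
}

#' Remove partially formed tiles
#'
#' Drops labels failing a minimum volume or minimum thickness (thin,
#' partially mineralized tiles at element margins are unreliable and are
#' excluded from analysis). Thickness here is the smallest axis-aligned
#' bounding-box side, the thin dimension of a partial tile.
#'
#' @param labels a `label_volume`.
#' @param min_volume minimum tile volume in cubic micrometers.
#' @param min_thickness minimum bounding-box thin side in micrometers.
#' @return The filtered `label_volume`; removals are appended to the edit
#'   log (op `"remove"`).
#' @export
remove_partial_tesserae <- function(labels, min_volume = 0,
                                    min_thickness = 0) {
  stopifnot(inherits(labels, "label_volume"))
  if (min_volume < 0 || min_thickness < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  d <- dim(labels$data)
  st <- cpp_label_stats(labels$data, d)
  present <- which(st[, "count"] > 0)
  vox <- labels$voxel
  vol <- st[present, "count"] * vox^3
  thin <- pmin(st[present, "max_i"] - st[present, "min_i"] + 1,
               st[present, "max_j"] - st[present, "min_j"] + 1,
               st[present, "max_k"] - st[present, "min_k"] + 1) * vox
  drop <- present[vol < min_volume | thin < min_thickness]
  if (length(drop) > 0) {
    labels$data[labels$data %in% drop] <- 0L
    labels$log <- rbind(labels$log,
                        tibble::tibble(op = "remove", a = as.integer(drop),
                                       b = NA_integer_, detail = ""))
  }
  labels
}

#' Segment a grayscale shell volume end to end
#'
#' Convenience pipeline: threshold, clean, unsigned distance transform,
#' hierarchical watershed. Returns the label volume plus the intermediate
#' distance map (the signed map is computed on request by
#' [signed_distance_map()]).
#'
#' @param gray a `gray_volume`.
#' @param level threshold intensity.
#' @param min_component,max_void_extent cleaning parameters
#'   (see [clean_binary()]).
#' @param persistence watershed saddle-depth threshold in micrometers;
#'   a reasonable default is half the expected tile half-width.
#' @param connectivity voxel neighborhood for the watershed.
#' @return List with `labels` (`label_volume`), `binary`, `distance`.
#' @export
segment_shell <- function(gray, level, min_component = 20,
                          max_void_extent = 1000, persistence,
                          connectivity = 26) {
  bin <- threshold_volume(gray, level)
  bin <- clean_binary(bin, min_component = min_component,
                      fill_enclosed_voids = TRUE,
                      max_void_extent = max_void_extent)
  dm <- distance_map(bin)
  labels <- watershed_instances(dm, persistence = persistence,
                                connectivity = connectivity)
  list(labels = labels, binary = bin, distance = dm)
}
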