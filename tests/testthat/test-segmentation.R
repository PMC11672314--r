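test_that("thresholding a noise-free phantom recovers the exact support", {
  ph <- small_phantom(n = 12, extent = 200, noise_sd = 0, lacunae = c(0, 0),
                      gap = 10)
  bin <- threshold_volume(ph$gray, 0.5)
  # symmetric blur keeps the 0.5 level set on the true boundary
  expect_equal(bin$data, ph$labels$data > 0)
})

test_that("thresholding is monotone and safe above the intensity range", {
  ph <- small_phantom(n = 8, extent = 150)
  b1 <- threshold_volume(ph$gray, 0.3)
  b2 <- threshold_volume(ph$gray, 0.6)
  expect_true(all(b1$data | !b2$data))  # raising level never adds voxels
  b3 <- threshold_volume(ph$gray, max(ph$gray$data) + 1)
  expect_equal(sum(b3$data), 0)
})

test_that("void filling restores exactly the carved lacuna voxels", {
  ph <- small_phantom(n = 12, extent = 200, noise_sd = 0,
                      lacunae = c(2, 7.5))
  bin <- threshold_volume(ph$gray, 0.5)
  filled <- clean_binary(bin, min_component = 0, fill_enclosed_voids = TRUE,
                         max_void_extent = 100)
  carved_total <- sum(ph$truth$carved_voxels)
  expect_gt(carved_total, 0)
  expect_equal(sum(filled$data) - sum(bin$data), carved_total)
})

test_that("voids open to the outside are not filled; cleaning is idempotent", {
  fg <- array(TRUE, c(12, 12, 12))
  fg[5:8, 5:8, 5:12] <- FALSE  # tunnel open to the z+ border
  bin <- binary_volume(fg, 1)
  cleaned <- clean_binary(bin, min_component = 0, max_void_extent = 1e5)
  expect_equal(cleaned$data, fg)
  # an enclosed pocket is filled, and twice = once
  fg2 <- fg
  fg2[5:8, 5:8, 5:12] <- TRUE
  fg2[3, 3, 3] <- FALSE
  bin2 <- binary_volume(fg2, 1)
  c1 <- clean_binary(bin2, min_component = 0, max_void_extent = 10)
  expect_true(all(c1$data))
  expect_equal(clean_binary(c1, min_component = 0, max_void_extent = 10)$data,
               c1$data)
})

test_that("small-component removal respects the size threshold", {
  fg <- array(FALSE, c(20, 20, 5))
  fg[2:6, 2:6, 2:4] <- TRUE    # 75 voxels
  fg[15, 15, 2:3] <- TRUE      # 2 voxels
  bin <- binary_volume(fg, 1)
  cleaned <- clean_binary(bin, min_component = 10,
                          fill_enclosed_voids = FALSE)
  expect_equal(sum(cleaned$data), 75)
})

test_that("the exact EDT matches a brute-force scan and EBImage in 2D", {
  withr::with_seed(5, {
    fg <- array(stats::runif(10 * 9 * 8) < 0.6, c(10, 9, 8))
  })
  fg[1, 1, 1] <- FALSE  # keep background non-empty
  bin <- binary_volume(fg, 2.5)
  dm <- distance_map(bin)
  expect_equal(dm$data, bf_edt(fg, 2.5), tolerance = 1e-12)
  # 2D cross-check against an independent implementation
  mask2d <- matrix(FALSE, 24, 24)
  mask2d[6:19, 4:21] <- TRUE
  mask2d[10, 10] <- FALSE
  vol <- binary_volume(array(mask2d, c(24, 24, 1)), 1)
  ours <- distance_map(vol)$data[, , 1]
  eb <- EBImage::distmap(EBImage::Image(mask2d * 1), metric = "euclidean")
  expect_equal(ours, EBImage::imageData(eb), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("slab distance maps peak at half thickness; dilation is monotone", {
  fg <- array(FALSE, c(30, 30, 21))
  fg[, , 6:15] <- TRUE  # slab of thickness 10
  bin <- binary_volume(fg, 4)
  dm <- distance_map(bin)
  expect_lte(abs(max(dm$data) - ceiling(10 / 2) * 4), 4)
  # dilating the foreground never decreases foreground distances
  fg2 <- fg; fg2[, , 5] <- TRUE
  dm2 <- distance_map(binary_volume(fg2, 4))
  expect_true(all(dm2$data[fg] >= dm$data[fg]))
})

test_that("signed distances are negative inside, positive outside", {
  fg <- array(FALSE, c(15, 15, 15))
  fg[4:12, 4:12, 6:10] <- TRUE
  bin <- binary_volume(fg, 1)
  sdm <- signed_distance_map(bin)
  expect_true(all(sdm$data[fg] < 0))
  expect_true(all(sdm$data[!fg] > 0))
  # center of the slab is the most negative value in its column
  expect_equal(which.min(sdm$data[8, 8, ]), 8)
  # negating the mask negates the field
  sdm2 <- signed_distance_map(binary_volume(!fg, 1))
  expect_equal(sdm2$data, -sdm$data, tolerance = 1e-12)
  expect_error(distance_map(binary_volume(array(TRUE, c(3, 3, 3)), 1)),
               "all-foreground")
})

test_that("two separated blobs give two labels; persistence merges them", {
  m <- dumbbell_mask(c(40, 19, 19), c1 = c(12, 10, 10), c2 = c(28, 10, 10),
                     r = 6, bridge_r = 2.2)
  bin <- binary_volume(m, 1)
  dm <- distance_map(bin)
  lab_keep <- watershed_instances(dm, persistence = 1)
  expect_equal(max(lab_keep$data), 2)
  # saddle depth is about r - bridge_r; a larger persistence merges
  lab_merge <- watershed_instances(dm, persistence = 6)
  expect_equal(max(lab_merge$data), 1)
  # labels never cross the background
  expect_true(all(lab_keep$data[!m] == 0))
  expect_true(all(lab_keep$data[m] > 0))
})

test_that("hierarchical watershed agrees with the exhaustive merge-tree oracle", {
  mk_img <- function(peaks) {
    img <- matrix(0, 28, 28)
    for (p in peaks) {
      co <- expand.grid(i = 1:28, j = 1:28)
      v <- pmax(0, p$h - sqrt((co$i - p$ci)^2 + (co$j - p$cj)^2))
      img <- pmax(img, matrix(v, 28, 28))
    }
    img
  }
  cases <- list(
    list(peaks = list(list(ci = 8, cj = 8, h = 6),
                      list(ci = 20, cj = 20, h = 9))),
    list(peaks = list(list(ci = 7, cj = 14, h = 5),
                      list(ci = 17, cj = 7, h = 8),
                      list(ci = 21, cj = 21, h = 6))),
    list(peaks = list(list(ci = 10, cj = 10, h = 7),
                      list(ci = 16, cj = 14, h = 7.5))))
  for (cs in cases) for (pers in c(0.5, 2, 4, 10)) {
    img <- mk_img(cs$peaks)
    expected <- bf_watershed_count(img, pers)
    dm <- distance_volume(array(img, c(28, 28, 1)), 1)
    lab <- watershed_instances(dm, persistence = pers)
    expect_equal(max(lab$data), expected,
                 label = sprintf("persistence %.1f", pers))
  }
})

test_that("watershed is deterministic and refuses bad inputs", {
  ph <- small_phantom(n = 10, extent = 150)
  seg1 <- segment_shell(ph$gray, 0.5, persistence = 12)
  seg2 <- segment_shell(ph$gray, 0.5, persistence = 12)
  expect_identical(seg1$labels$data, seg2$labels$data)
  expect_error(watershed_instances(seg1$distance, persistence = -1), ">= 0")
  sdm <- signed_distance_map(seg1$binary)
  expect_error(watershed_instances(sdm, 1), "unsigned")
})

test_that("merge and split edits behave as exact inverse partitions", {
  ph <- small_phantom(n = 10, extent = 150, noise_sd = 0, lacunae = c(0, 0))
  lab <- ph$labels
  n0 <- length(unique(lab$data[lab$data > 0]))
  merged <- edit_labels(lab, list(merge_edit(1, 2)))
  expect_equal(length(unique(merged$data[merged$data > 0])), n0 - 1)
  expect_equal(nrow(merged$log), 1)
  # split the merged region from two interior seed points
  tr <- ph$truth
  seeds <- rbind(unlist(tr[tr$id == 1, c("x", "y", "z")]),
                 unlist(tr[tr$id == 2, c("x", "y", "z")]))
  support_before <- merged$data == 1
  split <- edit_labels(merged, list(split_edit(1, seeds)))
  ids_after <- unique(split$data[support_before])
  expect_equal(length(ids_after), 2)
  expect_true(all(split$data[support_before] %in% ids_after))
  expect_true(all(split$data[!support_before] == merged$data[!support_before]))
  # empty edit list is the identity; bad ids fail
  expect_identical(edit_labels(lab, list())$data, lab$data)
  expect_error(edit_labels(lab, list(merge_edit(1, 999))), "unknown label")
  expect_error(edit_labels(lab, list(split_edit(1, rbind(c(1, 1, 1))))),
               "outside")
})

test_that("partial-tile removal conserves label counts", {
  ph <- small_phantom(n = 10, extent = 150, noise_sd = 0, lacunae = c(0, 0))
  lab <- ph$labels
  # inject a 3-voxel fragment
  frag_id <- max(lab$data) + 1L
  lab$data[1:3, 1, 1] <- frag_id
  n0 <- length(unique(lab$data[lab$data > 0]))
  out <- remove_partial_tesserae(lab, min_volume = 4 * lab$voxel^3)
  kept <- length(unique(out$data[out$data > 0]))
  removed <- sum(out$log$op == "remove")
  expect_equal(removed, 1)
  expect_equal(kept + removed, n0)
  expect_false(frag_id %in% out$data)
  # zero thresholds are the identity
  expect_identical(remove_partial_tesserae(ph$labels, 0, 0)$data,
                   ph$labels$data)
})
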