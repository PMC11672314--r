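grow_tess <- function(n = 120, extent = 800, seed = 1, min_spacing = 25) {
  surf <- surface_spec("plane", extent = c(extent, extent))
  pts <- sample_hardcore_points(surf, n, min_spacing, seed = seed)
  voronoi_tessellation(pts, surf)
}

test_that("initialization shrinks Voronoi cells to the target fill", {
  tess <- grow_tess(seed = 2)
  st <- init_state(tess, fill_fraction = 1)
  expect_equal(max(tesserate:::edge_gaps(st)), 0, tolerance = 1e-9)
  st8 <- init_state(tess, fill_fraction = 0.8)
  # interior coverage approximates the fill fraction
  inset <- 150
  region <- cbind(c(inset, 800 - inset, 800 - inset, inset),
                  c(inset, inset, 800 - inset, 800 - inset))
  expect_lt(abs(coverage_fraction(st8, region) - 0.8), 0.02)
  expect_equal(nrow(st8$centers), length(tess$faces))
  expect_error(init_state(tess, 0), "fill_fraction")
  expect_error(init_state(tess, 1.2), "fill_fraction")
})

test_that("substrate expansion opens gaps by exactly (lambda - 1) d_ij", {
  # two tiles, d = 100, fronts 40 each: gap 20 -> 30 at lambda = 1.1
  st <- chain_state(c(0, 100), fronts = cbind(40, 40))
  expect_equal(tesserate:::edge_gaps(st), 20)
  st2 <- expand_substrate(st, 1.1)
  expect_equal(tesserate:::edge_gaps(st2), 30)
  # general tessellation: exact algebra, and positive gap-size coupling
  tess <- grow_tess(seed = 3)
  s0 <- init_state(tess, 0.9)
  d0 <- tesserate:::edge_lengths(s0)
  g0 <- tesserate:::edge_gaps(s0)
  s1 <- expand_substrate(s0, 1.07)
  inc <- tesserate:::edge_gaps(s1) - g0
  expect_equal(inc, 0.07 * d0, tolerance = 1e-9)
  expect_gt(stats::cor(inc, d0), 0.99)
  expect_error(expand_substrate(s0, 1), "> 1")
})

test_that("constant apposition closes uniform tilings but not heterogeneous ones", {
  # uniform spacing: delta = g/2 closes every gap exactly
  st <- chain_state(seq(0, 400, by = 100), fill_fraction = 0.81)
  g <- tesserate:::edge_gaps(st)
  expect_equal(length(unique(round(g, 9))), 1)
  st2 <- appose_constant(st, unique(round(g, 9)) / 2)
  expect_equal(max(abs(tesserate:::edge_gaps(st2))), 0, tolerance = 1e-9)
  expect_equal(coverage_fraction(st2), 1, tolerance = 1e-9)
  # heterogeneous 1D chain: centers 0/100/260, fronts 40, lambda 1.1
  ch <- chain_state(c(0, 100, 260), fronts = cbind(c(40, 40), c(40, 40)))
  ch <- expand_substrate(ch, 1.1)
  g1 <- tesserate:::edge_gaps(ch)   # 30 and 96 by algebra
  expect_equal(g1, c(110 - 80, 176 - 80))
  ch2 <- appose_constant(ch, g1[1] / 2)
  g2 <- tesserate:::edge_gaps(ch2)
  expect_equal(g2[1], 0, tolerance = 1e-12)
  expect_equal(g2[2], g1[2] - g1[1])
  expect_gt(g2[2], 0)
  # delta = 0 is the identity
  ch3 <- appose_constant(ch, 0)
  expect_equal(ch3$edges$fa, ch$edges$fa)
})

test_that("proportional apposition closes all gaps at k = 1, keeping tile count", {
  tess <- grow_tess(seed = 4)
  st <- expand_substrate(init_state(tess, 0.85), 1.1)
  st1 <- appose_proportional(st, 1)
  expect_equal(max(abs(tesserate:::edge_gaps(st1))), 0, tolerance = 1e-9)
  expect_equal(nrow(st1$centers), nrow(st$centers))
  # larger tiles accrete more area per cycle
  a0 <- tile_areas(st)
  a1 <- tile_areas(st1)
  expect_gt(stats::cor(a1 - a0, a0, method = "spearman"), 0)
  expect_error(appose_proportional(st, 0), "k")
  expect_error(appose_proportional(st, 1.5), "k")
})

test_that("coverage is monotone under apposition and bounded by 1", {
  tess <- grow_tess(seed = 5)
  st <- expand_substrate(init_state(tess, 0.8), 1.05)
  c0 <- coverage_fraction(st)
  st2 <- appose_constant(st, 2)
  c1 <- coverage_fraction(st2)
  st3 <- appose_proportional(st2, 0.5)
  c2 <- coverage_fraction(st3)
  expect_true(c0 <= c1 && c1 <= c2)
  expect_lte(c2, 1 + 1e-12)
})

test_that("new-tile sites appear exactly where constant growth leaves big gaps", {
  # fully covered: no proposals
  tess <- grow_tess(seed = 6)
  st_full <- init_state(tess, 1)
  expect_equal(nrow(propose_new_tiles(st_full, 1)), 0)
  # the heterogeneous 3-tile chain leaves exactly one site at the wide gap
  ch <- chain_state(c(0, 100, 260), fronts = cbind(c(40, 40), c(40, 40)))
  ch <- expand_substrate(ch, 1.1)
  g <- tesserate:::edge_gaps(ch)
  ch <- appose_constant(ch, g[1] / 2)
  sites <- propose_new_tiles(ch, gap_area_threshold = 1)
  expect_equal(nrow(sites), 1)
  # the site sits inside the second joint (between tiles 2 and 3, scaled)
  expect_gt(sites$x, 1.1 * 100)
  expect_lt(sites$x, 1.1 * 260)
  # threshold above the total gap area: nothing proposed
  expect_equal(nrow(propose_new_tiles(ch, gap_area_threshold = 1e6)), 0)
})

test_that("voronoi deviation measures front asymmetry and shrinks with growth", {
  tess <- grow_tess(seed = 7)
  st <- init_state(tess, 0.9)
  expect_equal(voronoi_deviation(st), 0)
  # single fiber: closed form |fa - fb| / (2 d)
  ch <- chain_state(c(0, 100), fronts = cbind(30, 50))
  expect_equal(voronoi_deviation(ch), abs(30 - 50) / 200)
  # asymmetric fronts + expand/proportional cycles: nonincreasing deviation
  for (seed in 1:10) {
    sp <- perturb_fronts(init_state(grow_tess(seed = seed, n = 80), 0.85),
                         amount = 0.3, seed = seed)
    dev <- voronoi_deviation(sp)
    expect_gt(dev, 0)
    for (cyc in 1:6) {
      sp <- appose_proportional(expand_substrate(sp, 1.07), 0.7)
      dev_new <- voronoi_deviation(sp)
      expect_lte(dev_new, dev + 1e-12)
      dev <- dev_new
    }
  }
})

test_that("tiles never overlap after any operation sequence", {
  tess <- grow_tess(seed = 8, n = 60, extent = 500)
  st <- perturb_fronts(init_state(tess, 0.9), 0.2, seed = 8)
  ops <- list(function(s) expand_substrate(s, 1.06),
              function(s) appose_constant(s, 3),
              function(s) expand_substrate(s, 1.04),
              function(s) appose_proportional(s, 0.8))
  for (f in ops) {
    st <- f(st)
    g <- tesserate:::edge_gaps(st)
    expect_true(all(g >= -1e-9 * max(tesserate:::edge_lengths(st))))
    # pairwise polygon intersections of neighbors are empty
    polys <- tesserate:::tile_polygons(st)
    e <- st$edges
    for (r in sample(nrow(e), 20)) {
      A <- polys[[e$a[r]]]; B <- polys[[e$b[r]]]
      inter <- polyclip::polyclip(list(list(x = A[, 1], y = A[, 2])),
                                  list(list(x = B[, 1], y = B[, 2])),
                                  op = "intersection")
      area <- sum(vapply(inter, function(q) bf_shoelace(q$x, q$y), 1.0))
      # polyclip rasterizes to an integer grid; genuine overlaps would be
      # orders of magnitude above its sliver resolution
      expect_lt(area, 1e-5 * bf_shoelace(A[, 1], A[, 2]))
    }
  }
})

test_that("trajectories record one row per cycle with the expected shapes", {
  tess <- grow_tess(seed = 9, n = 60, extent = 500)
  st <- init_state(tess, 0.9)
  tr <- run_cycles(st, 1.05, rule_proportional(1), 4)
  expect_equal(nrow(tr$summary), 4)
  expect_equal(tr$summary$cycle, 1:4)
  expect_equal(length(tr$areas), 4)
  expect_true(all(tr$summary$n_tiles == length(tess$faces)))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
})

test_that("proportional and constant scenarios separate over many seeds", {
  for (seed in 1:10) {
    tess <- grow_tess(seed = seed, n = 150, extent = 900)
    st <- init_state(tess, 0.85)
    g0 <- tesserate:::edge_gaps(st)
    prop <- run_cycles(st, 1.07, rule_proportional(1), 10)
    cons <- run_cycles(st, 1.07, rule_constant(stats::median(g0) / 2), 10)
    expect_true(all(prop$summary$n_tiles == prop$summary$n_tiles[1]))
    expect_gte(prop$summary$coverage[10], 0.999)
    expect_lt(cons$summary$coverage[10], prop$summary$coverage[10])
    expect_lt(cons$summary$coverage[10], 1)
  }
})

test_that("proportional growth keeps the rescaled area distribution self-similar", {
  for (seed in 1:5) {
    tess <- grow_tess(seed = seed, n = 500, extent = 1500, min_spacing = 30)
    st <- init_state(tess, 0.85)
    tr <- run_cycles(st, 1.07, rule_proportional(1), 10)
    d5 <- rescale_distribution(tr$areas[[5]])
    d10 <- rescale_distribution(tr$areas[[10]])
    expect_lt(self_similarity_distance(d5, d10), 0.05)
  }
})
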