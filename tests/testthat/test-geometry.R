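g1 <- grid_spec(1)
gc1 <- distance_model("great_circle", g1)

test_that("great-circle distances match closed-form and geosphere values", {
  # equatorial band whose centroids sit exactly on the equator
  geq <- grid_spec(1, -180, 180, -0.5, 0.5)
  meq <- distance_model("great_circle", geq)
  a <- cell_at(geq, 0.5, 0)
  expect_equal(cell_distance(a, a, meq), 0)
  b <- cell_at(geq, 10.5, 0)
  expect_equal(cell_distance(a, b, meq), 10)
  # (45N, 0E) to (45N, 180E): cos d = sin^2 45 + cos^2 45 cos 180 = 0
  g45 <- grid_spec(1, -180, 180, 44.5, 45.5)
  m45 <- distance_model("great_circle", g45)
  p <- cell_at(g45, 0.5, 45)
  q <- cell_at(g45, -179.5, 45)
  expect_equal(cell_distance(p, q, m45), 90)
  set.seed(7)
  ids <- sample.int(g1$n_cell, 50)
  jds <- sample.int(g1$n_cell, 50)
  got <- cell_distance(ids, jds, gc1)
  ref <- geosphere::distHaversine(cell_centroid(g1, ids),
                                  cell_centroid(g1, jds),
                                  r = 180 / pi)
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("range_clusters splits at the closed threshold and chains", {
  cells <- gcell(g1, c(0, 3, 20), 0)
  expect_equal(canon_partition(range_clusters(cells, 5, gc1)),
               canon_partition(list(cells[1:2], cells[3])))
  chain <- gcell(g1, c(0, 4, 8), 0)
  expect_length(range_clusters(chain, 5, gc1), 1)
  expect_length(range_clusters(integer(0), 5, gc1), 0)
})

test_that("range_clusters agrees with the union-find oracle", {
  set.seed(11)
  for (i in 1:25) {
    cells <- sample.int(g1$n_cell, sample(3:60, 1))
    d_s <- runif(1, 1, 30)
    expect_equal(canon_partition(range_clusters(cells, d_s, gc1)),
                 canon_partition(oracle_clusters(cells, d_s, gc1)))
  }
})

test_that("range_clusters block count is monotone in the threshold", {
  set.seed(3)
  cells <- sample.int(g1$n_cell, 80)
  nb <- vapply(c(2, 5, 10, 20, 40, 90),
               function(d) length(range_clusters(cells, d, gc1)), integer(1))
  expect_true(all(diff(nb) <= 0))
})

test_that("reachable_cells honours its limits and thresholds", {
  src <- gcell(g1, 0, 0)
  hab <- c(src, gcell(g1, c(10, -10, 25), 0), gcell(g1, 0, c(10, -10)))
  expect_equal(reachable_cells(src, hab, 0, gc1), src)
  expect_equal(reachable_cells(src, hab, 360, gc1), hab)
  ring <- setdiff(hab, c(src, gcell(g1, 25, 0)))  # four cells at exactly 10
  expect_length(reachable_cells(src, ring, 9.5, gc1), 0)
  expect_equal(sort(reachable_cells(src, ring, 10, gc1)), sort(ring))
})

test_that("reachable_cells is monotone in reach and in sources", {
  set.seed(5)
  hab <- sample.int(g1$n_cell, 300)
  src1 <- sample(hab, 5)
  src2 <- c(src1, sample(hab, 5))
  r1 <- reachable_cells(src1, hab, 8, gc1)
  expect_true(all(r1 %in% reachable_cells(src1, hab, 15, gc1)))
  expect_true(all(r1 %in% reachable_cells(src2, hab, 8, gc1)))
})

test_that("sea-graph distances dominate great-circle and obey the triangle inequality", {
  g <- grid_spec(1, 0, 12, 0, 8)
  # a land wall with a southern strait
  land <- which(cell_centroid(g, seq_len(g$n_cell))[, 1] > 5.4 &
                  cell_centroid(g, seq_len(g$n_cell))[, 1] < 6.6 &
                  cell_centroid(g, seq_len(g$n_cell))[, 2] > 1)
  sea <- distance_model("sea_graph", g, land = land)
  gc <- distance_model("great_circle", g)
  cells <- setdiff(seq_len(g$n_cell), land)
  set.seed(9)
  pick <- sample(cells, 8)
  dsea <- reefdyn:::cross_distance(pick, pick, sea)
  dgc <- reefdyn:::cross_distance(pick, pick, gc)
  expect_true(all(dsea >= dgc - 1e-9))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(dsea[i, j], dsea[i, k] + dsea[k, j] + 1e-9)
  expect_error(cell_distance(land[1], pick[1], sea), "land")
})

test_that("sea-graph paths detour around land", {
  g <- grid_spec(1, 0, 11, 0, 5)
  ctr <- cell_centroid(g, seq_len(g$n_cell))
  # full-height wall: no sea path remains
  wall <- which(ctr[, 1] > 5 & ctr[, 1] < 6)
  sea <- distance_model("sea_graph", g, land = wall)
  a <- cell_at(g, 1.5, 2.5)
  b <- cell_at(g, 9.5, 2.5)
  expect_equal(cell_distance(a, b, sea), Inf)
  # gap in the wall: finite but longer than the straight line
  sea2 <- distance_model("sea_graph", g, land = setdiff(wall, cell_at(g, 5.5, 0.5)))
  gdist <- cell_distance(a, b, distance_model("great_circle", g))
  expect_gt(cell_distance(a, b, sea2), gdist)
  expect_lt(cell_distance(a, b, sea2), Inf)
})
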