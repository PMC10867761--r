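test_that("a straight 10-px path yields the expected nodes and edges", {
  coords <- cbind(5, 3:12)
  g <- build_vessel_graph(px_matrix(coords, c(10, 16)))
  expect_equal(nrow(g$nodes), 10)
  expect_equal(sum(g$nodes$class == "endpoint"), 2)
  expect_equal(sum(g$nodes$class == "slab"), 8)
  expect_equal(nrow(g$edges), 9)
})

test_that("a Y-shape yields 3 endpoints and 1 branch node", {
  img <- y_skeleton(10)
  g <- build_vessel_graph(img)
  expect_equal(sum(g$nodes$class == "endpoint"), 3)
  expect_equal(sum(g$nodes$class == "branch"), 1)
  # degrees agree with the per-pixel oracle
  deg <- degree_oracle(img)
  expect_equal(g$nodes$degree, deg[cbind(g$nodes$row, g$nodes$col)])
})

test_that("an isolated pixel is an isolated node with no edges", {
  g <- build_vessel_graph(px_matrix(cbind(4, 4), c(8, 8)))
  expect_equal(nrow(g$nodes), 1)
  expect_equal(g$nodes$class, "isolated")
  expect_equal(nrow(g$edges), 0)
})

test_that("disc exclusion removes nodes and recomputes topology", {
  img <- px_matrix(cbind(20, 6:55), c(40, 60))
  g <- build_vessel_graph(img)
  # radius 0 is the identity
  g0 <- exclude_disc_region(g, disc_center(19, 29), 0)
  expect_identical(g0$nodes, g$nodes)
  # a path through the disc center splits into two components
  g5 <- exclude_disc_region(g, disc_center(19, 29), 5)   # 0-based (19,29) = px (20,30)
  expect_lt(nrow(g5$nodes), nrow(g$nodes))
  expect_equal(count_components8(px_matrix(cbind(g5$nodes$row, g5$nodes$col), c(40, 60))), 2)
  # disc far away from the content leaves the graph unchanged
  gfar <- exclude_disc_region(g, disc_center(2, 2), 5)
  expect_identical(gfar$nodes, g$nodes)
})

test_that("a straight 50-px path becomes one segment with exact arc length", {
  img <- px_matrix(cbind(20, 6:55), c(40, 60))
  segs <- extract_segments(build_vessel_graph(img))
  expect_length(segs, 1)
  expect_equal(segs[[1]]$arc_length_px, 49)
  expect_equal(segs[[1]]$arc_length_px, step_sum_oracle(segs[[1]]$chain))
  expect_equal(segs[[1]]$n_points, 50)
})

test_that("a Y with 30-px arms yields 3 segments sharing the junction", {
  img <- y_skeleton(30)
  segs <- extract_segments(build_vessel_graph(img))
  expect_length(segs, 3)
  # segment cover: every skeleton pixel appears in some chain
  covered <- unique(do.call(rbind, lapply(segs, function(s) round(s$chain))))
  all_px <- which(img, arr.ind = TRUE)
  expect_equal(nrow(covered), nrow(all_px))
  # arc lengths match the independent step-sum oracle
  for (s in segs) expect_equal(s$arc_length_px, step_sum_oracle(s$chain))
})

test_that("short terminal spurs are pruned before segmentation", {
  img <- spur_skeleton(50, 5)
  segs <- extract_segments(build_vessel_graph(img), spur_length_px = 10)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$n_points, 50)            # full path, no branch remains
  expect_equal(segs[[1]]$from_class, "endpoint")
  expect_equal(segs[[1]]$to_class, "endpoint")
  # with pruning disabled the spur splits the path into three segments
  segs0 <- extract_segments(build_vessel_graph(img), spur_length_px = 0,
                            min_length_px = 3)
  expect_length(segs0, 3)
})

test_that("segments are oriented proximal-to-distal about the disc", {
  r <- generate_retina(synth_config(image_size = c(512, 512),
                                    amplitude_px = 10, seed = 5))
  res <- measure_tortuosity(r$mask, r$disc)
  sk <- skeletonize_mask(r$mask)
  g <- exclude_disc_region(build_vessel_graph(sk), r$disc, 50)
  segs <- extract_segments(g, disc = r$disc, mask = r$mask)
  expect_gte(length(segs), 8)
  dc <- c(r$disc$row + 1, r$disc$col + 1)
  for (s in segs) {
    d_first <- sqrt(sum((s$chain[1, ] - dc)^2))
    d_last <- sqrt(sum((s$chain[nrow(s$chain), ] - dc)^2))
    expect_lte(d_first, d_last)
  }
})

test_that("segments below the minimum length are discarded", {
  img <- px_matrix(cbind(20, 6:20), c(40, 30))   # 15-px path
  expect_length(extract_segments(build_vessel_graph(img), min_length_px = 20), 0)
  expect_length(extract_segments(build_vessel_graph(img), min_length_px = 10), 1)
  expect_length(extract_segments(build_vessel_graph(px_matrix(cbind(1, 1), c(4, 4)))), 0)
})
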