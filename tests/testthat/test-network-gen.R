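test_that("Murray daughter radii conserve the cubed parent radius", {
  # symmetric bifurcation: both daughters at 2^(-1/3)
  rr <- murray_daughter_radii(1, 0.5, 3)
  expect_equal(rr, rep(2^(-1 / 3), 2))
  expect_equal(sum(rr^3), 1)
  # asymmetric split, conservation checked by direct evaluation
  rr <- murray_daughter_radii(1.2, 0.3, 3)
  expect_equal(sum(rr^3), 1.2^3)
  expect_equal(rr[1]^3, 0.3 * 1.2^3)
  # general exponent
  rr <- murray_daughter_radii(2, 0.4, 2.5)
  expect_equal(sum(rr^2.5), 2^2.5)
  expect_error(murray_daughter_radii(-1, 0.5), "positive")
  expect_error(murray_daughter_radii(1, 0), "split_fraction")
  expect_error(murray_daughter_radii(1, 0.5, -3), "exponent")
})

test_that("bifurcating trees terminate at the terminal radius (inclusive)", {
  cfg <- model_config()
  # symmetric splits: radius after k generations is 2^(-k/3); 0.25 is hit
  # exactly at depth 6 and the inclusive tie terminates there
  tree <- build_bifurcating_tree(1, 0.25, cfg)
  expect_equal(max(tree$depth), 6L)
  depth_oracle <- 0L; r <- 1
  while (r > 0.25 * (1 + 1e-9)) { r <- r * 2^(-1 / 3); depth_oracle <- depth_oracle + 1L }
  expect_equal(max(tree$depth), depth_oracle)
  leaves <- tree[tree$is_leaf, ]
  expect_true(all(leaves$radius_mm <= 0.25 * (1 + 1e-9)))
  # Murray conservation: leaf cubes sum to the root cube
  expect_equal(sum(leaves$radius_mm^3), 1, tolerance = 1e-10)
  # lengths follow the length-radius ratio
  expect_equal(tree$length_mm, 10 * tree$radius_mm)
  # barely-smaller terminal radius gives a single split
  tiny <- build_bifurcating_tree(0.2525, 0.25, cfg)
  expect_equal(max(tiny$depth), 1L)
  expect_equal(nrow(tiny), 3L)
  expect_error(build_bifurcating_tree(0.2, 0.25, cfg), "smaller")
})

test_that("jittered trees stay Murray-conserving and are seed-reproducible", {
  cfg <- model_config()
  t1 <- build_bifurcating_tree(1, 0.4, cfg, split_jitter = 0.2, seed = 7)
  t2 <- build_bifurcating_tree(1, 0.4, cfg, split_jitter = 0.2, seed = 7)
  expect_identical(t1, t2)
  expect_equal(sum(t1$radius_mm[t1$is_leaf]^3), 1, tolerance = 1e-10)
})

test_that("the pial network is the hexagonal dual of the triangulated surface", {
  cfg <- model_config("network.surface_resolution" = 2)
  pial <- build_pial_network(cfg)
  # one dual node per triangle of the subdivided icosahedron
  expect_equal(nrow(pial$nodes), 20 * 4^2)
  # every dual node of a closed triangulation has degree 3
  deg <- table(c(pial$vessels$from, pial$vessels$to))
  expect_gte(mean(deg == 3), 0.95)
  expect_equal(nrow(pial$vessels), 3 * nrow(pial$nodes) / 2)
  # all pial vessels at the pial reference radius
  expect_true(all(pial$vessels$r0_mm == 0.2))
  # territory-crossing vessels flagged as collateral candidates
  terr <- stats::setNames(pial$nodes$territory, pial$nodes$id)
  crossing <- terr[as.character(pial$vessels$from)] !=
    terr[as.character(pial$vessels$to)]
  expect_equal(unname(pial$vessels$is_collateral), unname(crossing))
  # all eight territories represented
  expect_setequal(unique(pial$nodes$territory),
                  setdiff(territory_levels(), "systemic"))
})

test_that("collateral thinning is binomial and reproducible", {
  cfg <- model_config("network.surface_resolution" = 3)
  pial <- build_pial_network(cfg)
  n_cand <- sum(pial$vessels$is_collateral)
  expect_gt(n_cand, 100)
  none <- select_collaterals(pial, 0, seed = 1)
  expect_equal(sum(none$vessels$is_collateral), 0)
  all_kept <- select_collaterals(pial, 1, seed = 1)
  expect_equal(sum(all_kept$vessels$is_collateral), n_cand)
  # non-crossing vessels are untouched in every case
  expect_equal(sum(!none$vessels$is_collateral),
               sum(!pial$vessels$is_collateral))
  # retained count within 3 sigma of Binomial(n_cand, p)
  p <- 0.25
  kept <- sum(select_collaterals(pial, p, seed = 42)$vessels$is_collateral)
  expect_lt(abs(kept - n_cand * p), 3 * sqrt(n_cand * p * (1 - p)))
  # identical seeds give identical networks
  a <- select_collaterals(pial, p, seed = 5)
  b <- select_collaterals(pial, p, seed = 5)
  expect_identical(a, b)
})

test_that("every pial node gets exactly one degree-1 outlet", {
  cfg <- small_config()
  pial <- attach_outlets(select_collaterals(build_pial_network(cfg), 0.5, 1),
                         cfg)
  n_pial <- sum(pial$nodes$role == "pial")
  expect_equal(nrow(pial$outlets), n_pial)
  out_nodes <- pial$nodes$id[pial$nodes$role == "outlet"]
  deg <- table(c(pial$vessels$from, pial$vessels$to))
  expect_true(all(deg[as.character(out_nodes)] == 1))
  # territory counts partition the outlet total
  expect_equal(sum(table(pial$outlets$territory)), n_pial)
})

test_that("generated networks are connected, Murray-conserving and seed-stable", {
  net <- small_network()
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  # a path exists from the inlet to every outlet
  inlet <- as.character(net$nodes$id[net$nodes$role == "inlet"])
  dists <- igraph::distances(g, v = inlet,
                             to = as.character(net$outlets$node))
  expect_true(all(is.finite(dists)))
  # Murray conservation at every internal tree bifurcation
  tree <- net$vessels[net$vessels$type == "tree", ]
  parents <- split(tree, tree$from)
  for (children in parents) {
    if (nrow(children) < 2) next
    feeder <- tree[tree$to == children$from[1], ]
    if (nrow(feeder) != 1) next
    expect_equal(sum(children$r0_mm^3), feeder$r0_mm^3, tolerance = 1e-10)
  }
  # outlet bookkeeping
  expect_equal(net$meta$N_total, sum(net$nodes$role == "outlet") - 1L) # body excluded
  expect_equal(sum(net$meta$territory_outlet_counts), net$meta$N_total)
  # identical config + seed gives byte-identical tables
  net2 <- generate_network(small_config())
  expect_identical(net2$nodes, generate_network(small_config())$nodes)
  expect_identical(net2$vessels, generate_network(small_config())$vessels)
})

test_that("collateral fraction tracks the configured probability", {
  cfg3 <- model_config("network.surface_resolution" = 3)
  pial <- build_pial_network(cfg3)
  n_cand <- sum(pial$vessels$is_collateral)
  p <- 0.5
  kept <- vapply(1:3, function(s)
    sum(select_collaterals(pial, p, seed = s)$vessels$is_collateral),
    numeric(1))
  expect_lt(abs(mean(kept) / n_cand - p), 3 * sqrt(p * (1 - p) / (3 * n_cand)))
})
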