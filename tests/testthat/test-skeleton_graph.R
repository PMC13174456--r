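test_that("thinning produces 1-px skeletons of expected extent", {
  band <- matrix(FALSE, 20, 110)
  band[8:12, 6:105] <- TRUE
  sk <- skeletonize_component(band)
  expect_true(all(band[sk]))                       # skeleton within mask
  expect_gte(sum(sk), 95)                          # ~band length
  expect_lte(sum(sk), 105)
  # thinning idempotence
  expect_identical(skeletonize_component(sk), sk)
  # single pixel maps to itself
  solo <- matrix(FALSE, 5, 5); solo[3, 3] <- TRUE
  expect_identical(skeletonize_component(solo), solo)
  # a filled disk collapses to a few central pixels
  disk <- outer(1:41, 1:41, function(r, c) (r - 21)^2 + (c - 21)^2 <= 15^2)
  expect_lte(sum(skeletonize_component(disk)), 12)
})

test_that("node and branch detection follows the 3x3 neighbour rules", {
  line <- line_mask(10)
  nb <- detect_nodes_and_branches(line)
  expect_equal(sum(nb$nodes$kind == "endpoint"), 2)
  expect_equal(nrow(nb$branches), 1)
  expect_equal(nb$branches$length, 8)

  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  nbp <- detect_nodes_and_branches(plus)
  expect_equal(sum(nbp$nodes$kind == "junction"), 1)
  expect_equal(sum(nbp$nodes$kind == "endpoint"), 4)
  expect_equal(nrow(nbp$branches), 4)

  seg2 <- matrix(FALSE, 5, 6); seg2[3, 3:4] <- TRUE
  nb2 <- detect_nodes_and_branches(seg2)
  expect_equal(sum(nb2$nodes$kind == "endpoint"), 2)
  expect_equal(nrow(nb2$branches), 0)  # no non-node pixels to connect them
})

test_that("graph construction collapses multi-edges and finds the MST", {
  nodes <- tibble::tibble(node_id = 1:3, kind = "junction",
                          centroid_r = 1, centroid_c = 1, n_pixels = 1L)
  tri <- tibble::tibble(branch_id = 1:3, length = c(1, 2, 3),
                        node_a = c(1, 2, 1), node_b = c(2, 3, 3))
  g <- build_graph_and_mst(nodes, tri)
  expect_equal(sum(igraph::E(g$mst)$weight), 3) # edges 1 and 2

  par <- tibble::tibble(branch_id = 1:2, length = c(7, 4),
                        node_a = c(1, 1), node_b = c(2, 2))
  gp <- build_graph_and_mst(nodes[1:2, ], par)
  expect_equal(igraph::E(gp$graph)$weight, 4)   # lighter parallel edge kept

  tree <- tibble::tibble(branch_id = 1:2, length = c(5, 9),
                         node_a = c(1, 2), node_b = c(2, 3))
  gt <- build_graph_and_mst(nodes, tree)
  expect_equal(igraph::ecount(gt$mst), 2)       # already acyclic
})

test_that("MST weight matches an independent Kruskal oracle on random graphs", {
  for (s in 1:20) {
    withr::with_seed(1000 + s, {
      n <- sample(5:30, 1)
      m <- sample(n:(min(n * (n - 1) / 2, 3 * n)), 1)
      pairs <- t(utils::combn(n, 2))
      pick <- sample(nrow(pairs), m)
      ed <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                       w = sample(1:50, m, replace = TRUE))
    })
    nodes <- tibble::tibble(node_id = 1:n, kind = "junction",
                            centroid_r = 1, centroid_c = 1, n_pixels = 1L)
    br <- tibble::tibble(branch_id = seq_len(nrow(ed)), length = ed$w,
                         node_a = ed$a, node_b = ed$b)
    g <- build_graph_and_mst(nodes, br)
    # oracle on the same collapsed simple graph
    simple <- data.frame(a = g$branches$node_a, b = g$branches$node_b,
                         w = g$branches$length)
    expect_equal(sum(igraph::E(g$mst)$weight), kruskal_weight(simple))
  }
})

test_that("longest path equals the exhaustive all-pairs tree diameter", {
  # stated examples
  nodes <- tibble::tibble(node_id = 1:4, kind = "junction",
                          centroid_r = 1, centroid_c = 1, n_pixels = 1L)
  path <- tibble::tibble(branch_id = 1:3, length = c(3, 5, 2),
                         node_a = 1:3, node_b = 2:4)
  expect_equal(longest_path(build_graph_and_mst(nodes, path))$weight, 10)

  star <- tibble::tibble(branch_id = 1:3, length = c(10, 20, 30),
                         node_a = 1, node_b = 2:4)
  expect_equal(longest_path(build_graph_and_mst(nodes, star))$weight, 50)

  # random trees vs exhaustive all-pairs oracle
  for (s in 1:60) {
    n <- 2 + (s %% 11)
    tr <- random_tree_graph(n, seed = 2000 + s)
    g <- build_graph_and_mst(tr$nodes, tr$branches)
    lp <- longest_path(g)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = tr$branches$node_a, to = tr$branches$node_b,
                 weight = tr$branches$length), directed = FALSE)
    oracle <- max(igraph::distances(ig, weights = igraph::E(ig)$weight))
    expect_equal(lp$weight, oracle)
  }
})

test_that("components below the midline-length threshold are rejected", {
  for (n in c(499, 501)) {
    m <- line_mask(n)
    g <- analyze_component(m, boundary_index(m, "tissue"))
    expect_equal(g$midline$length_px, n)
    expect_equal(g$accepted, n >= 500)
  }
})

test_that("ridge validation is a directional filter with ties kept", {
  # boundary along the top: distance grows downward
  bmask <- matrix(TRUE, 40, 40); bmask[1, ] <- FALSE
  bi <- boundary_index(bmask, "tissue")
  # two junctions joined by a heavy trunk; long decoy arms at both ends form
  # the diameter, leaving three light arms as provisional ridges
  nodes <- tibble::tibble(
    node_id = 1:7,
    kind = c("junction", "junction", "endpoint", "endpoint", "endpoint",
             "endpoint", "endpoint"),
    centroid_r = c(20, 20, 35, 5, 20, 35, 35),
    centroid_c = c(5, 35, 8, 33, 30, 4, 37),
    n_pixels = 1L)
  branches <- tibble::tibble(branch_id = 1:6,
                             length = c(100, 10, 10, 5, 15, 15),
                             node_a = c(1, 1, 2, 2, 1, 2),
                             node_b = c(2, 3, 4, 5, 6, 7))
  g <- build_graph_and_mst(nodes, branches)
  g <- classify_and_validate(g, bi, min_path_px = 0)
  expect_setequal(g$midline$edge_branch_ids, c(1, 5, 6))
  rid <- g$ridges[order(g$ridges$branch_id), ]
  down <- rid[rid$branch_id == 2, ] # tip deeper than base -> valid
  expect_true(down$valid)
  up <- rid[rid$branch_id == 3, ]   # tip nearer the boundary -> discarded
  expect_false(up$valid)
  expect_equal(up$reason, "tip_closer_to_boundary")
  tie <- rid[rid$branch_id == 4, ]  # d_tip == d_base -> kept (strict rule)
  expect_true(tie$valid)
})

test_that("phantom ridges validate against the tissue boundary; surface spurs do not", {
  ph <- small_phantom(seed = 21, n_ridges = 4, width = 700)
  an <- analyze_phantom(ph)
  g <- an$graph
  expect_true(g$accepted)
  expect_equal(sum(g$ridges$valid), 4)
  # every valid tip points into the dermis (below the band)
  tips <- g$ridges[g$ridges$valid, ]
  expect_true(all(tips$d_tip > tips$d_base))
})

test_that("graph summaries are deterministic across runs", {
  ph <- small_phantom(seed = 8, width = 650)
  a <- analyze_phantom(ph)$graph
  b <- analyze_phantom(ph)$graph
  expect_identical(a$ridges, b$ridges)
  expect_identical(a$midline$pixels, b$midline$pixels)
})
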