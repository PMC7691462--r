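test_that("distances add along a line and vanish on the diagonal", {
  edges <- data.frame(edge_id = c("e1", "e2"),
                      node_a = c("nA", "nB"), node_b = c("nB", "nC"),
                      length_km = c(2, 3))
  sites <- data.frame(site_id = c("A", "B", "C"),
                      catchment_id = "c1",
                      edge_id = c("e1", "e1", "e2"),
                      offset_km = c(0, 2, 3))
  net <- build_network(edges, sites)
  d <- river_distance_matrix(net)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["A", "C"], 5)
  expect_equal(d["A", "B"], 2)
})

test_that("non-tree inputs are rejected with clear errors", {
  cyc <- data.frame(edge_id = c("e1", "e2", "e3"),
                    node_a = c("A", "B", "C"), node_b = c("B", "C", "A"),
                    length_km = 1)
  sites <- data.frame(site_id = "s", catchment_id = "c",
                      edge_id = "e1", offset_km = 0.5)
  expect_error(build_network(cyc, sites), "not dendritic")

  disc <- data.frame(edge_id = c("e1", "e2"),
                     node_a = c("A", "C"), node_b = c("B", "D"),
                     length_km = 1)
  expect_error(build_network(disc, sites), "disconnected")

  y <- make_y_network()
  bad_site <- data.frame(site_id = "X", catchment_id = "c",
                         edge_id = "e1", offset_km = 99)
  expect_error(build_network(y$edges, bad_site), "offset")
})

test_that("river distances match a brute-force path search on random trees", {
  for (seed in c(3, 17)) {
    nw <- random_tip_network(10, seed = seed)
    d <- river_distance_matrix(nw$network)
    ## oracle works on the raw edge list: every site sits at a tip node
    tip_node <- nw$edges$node_b[match(nw$sites$edge_id, nw$edges$edge_id)]
    for (i in 1:9) for (j in (i + 1):10) {
      expect_equal(d[i, j],
                   oracle_tree_distance(nw$edges, tip_node[i], tip_node[j]),
                   tolerance = 1e-9)
    }
  }
})

test_that("barrier counts equal brute-force path enumeration and are monotone", {
  nw <- random_tip_network(8, n_barriers = 12, seed = 5)
  bc <- barrier_count_matrix(nw$network)
  expect_true(all(diag(bc) == 0))
  expect_equal(bc, t(bc))
  tip_node <- nw$edges$node_b[match(nw$sites$edge_id, nw$edges$edge_id)]
  for (i in 1:7) for (j in (i + 1):8) {
    path_edges <- oracle_tree_path(nw$edges, tip_node[i], tip_node[j])
    n_b <- sum(nw$barriers$edge_id %in% nw$edges$edge_id[path_edges])
    expect_equal(bc[i, j], n_b)
  }
  ## adding one more barrier never decreases any entry
  extra <- rbind(nw$barriers,
                 data.frame(barrier_id = "Bx", edge_id = nw$edges$edge_id[1],
                            offset_km = nw$edges$length_km[1] / 2))
  net2 <- build_network(nw$edges, nw$sites, extra)
  expect_true(all(barrier_count_matrix(net2) >= bc))
})

test_that("no barriers anywhere gives an all-zero count matrix", {
  net <- make_y_network()
  expect_true(all(barrier_count_matrix(net) == 0))
  one <- make_y_network(barriers = data.frame(barrier_id = "b1",
                                              edge_id = "e1",
                                              offset_km = 1))
  bc <- barrier_count_matrix(one)
  expect_equal(bc["A", "B"], 1L)
  expect_equal(bc["B", "C"], 0L)
  expect_true(all(diag(bc) == 0))
})

test_that("catchment model matrix is 0 within and 1 among catchments", {
  sites <- data.frame(site_id = c("A1", "A2", "B1"),
                      catchment_id = c("a", "a", "b"))
  cm <- catchment_model_matrix(sites)
  expect_equal(cm["A1", "A2"], 0L)
  expect_equal(cm["A1", "B1"], 1L)
  expect_equal(cm["A2", "B1"], 1L)
  expect_true(all(diag(cm) == 0))
  ## against direct label comparison on a generated study
  nw <- random_tip_network(12, seed = 9)
  cm2 <- catchment_model_matrix(nw$network)
  lab <- nw$network$sites$catchment_id
  expect_equal(unname(cm2), unname(outer(lab, lab, "!=") * 1L))
  expect_error(catchment_model_matrix(
    data.frame(site_id = "A", catchment_id = NA)), "catchment")
})

test_that("path_sections is empty for identical sites and consistent with distances", {
  nw <- random_tip_network(9, n_barriers = 4, seed = 11)
  net <- nw$network
  ids <- net$sites$site_id
  expect_identical(path_sections(net, ids[1], ids[1]), character(0))
  d <- river_distance_matrix(net)
  len <- stats::setNames(net$sections$length_km, net$sections$section_id)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    expect_equal(sum(len[path_sections(net, ids[i], ids[j])]), d[i, j],
                 tolerance = 1e-9)
  }
  expect_error(path_sections(net, "nope", ids[1]), "unknown site")
})

test_that("river distance satisfies the four-point condition", {
  nw <- random_tip_network(10, seed = 23)
  d <- river_distance_matrix(nw$network)
  k <- nrow(d)
  combs <- utils::combn(k, 4)
  for (c4 in seq_len(min(40, ncol(combs)))) {
    q <- combs[, c4]
    s1 <- d[q[1], q[2]] + d[q[3], q[4]]
    s2 <- d[q[1], q[3]] + d[q[2], q[4]]
    s3 <- d[q[1], q[4]] + d[q[2], q[3]]
    sums <- sort(c(s1, s2, s3))
    expect_lte(sums[3] - sums[2], 1e-9)
  }
})

test_that("a barrier at a site's exact position separates it from downstream", {
  ## site and barrier share offset 1 on a 2 km edge; the barrier goes to the
  ## node_b (downstream) side, so it lies between the site and node_b
  edges <- data.frame(edge_id = "e1", node_a = "up", node_b = "down",
                      length_km = 2)
  sites <- data.frame(site_id = c("S", "D"), catchment_id = "c",
                      edge_id = "e1", offset_km = c(1, 2))
  barr <- data.frame(barrier_id = "b", edge_id = "e1", offset_km = 1)
  net <- build_network(edges, sites, barr)
  expect_equal(barrier_count_matrix(net)["S", "D"], 1L)
})
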