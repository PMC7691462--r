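test_that("incidence has one row per pair with the right topology", {
  ## two sites on a single edge -> one pair, one traversed section
  edges <- data.frame(edge_id = "e1", node_a = "a", node_b = "b",
                      length_km = 10)
  sites <- data.frame(site_id = c("A", "B"), catchment_id = "c",
                      edge_id = "e1", offset_km = c(0, 10))
  net <- build_network(edges, sites)
  inc <- build_incidence(net)
  expect_equal(nrow(inc$incidence), 1)
  expect_equal(sum(inc$incidence), 1)

  ## three leaf sites on a Y: 3 pairs x 3 sections, each row has two 1s
  y <- make_y_network()
  inc_y <- build_incidence(y)
  expect_equal(dim(inc_y$incidence), c(3, 3))
  expect_equal(unname(rowSums(inc_y$incidence)), c(2, 2, 2))

  ## row sums equal path section counts on a random tree
  nw <- random_tip_network(10, n_barriers = 3, seed = 2)
  inc_r <- build_incidence(nw$network)
  for (r in seq_len(nrow(inc_r$pairs))) {
    expect_equal(sum(inc_r$incidence[r, ]),
                 length(path_sections(nw$network, inc_r$pairs$site_i[r],
                                      inc_r$pairs$site_j[r])))
  }
})

test_that("a single pair on a single section is fitted exactly", {
  edges <- data.frame(edge_id = "e1", node_a = "a", node_b = "b",
                      length_km = 1)
  sites <- data.frame(site_id = c("A", "B"), catchment_id = "c",
                      edge_id = "e1", offset_km = c(0, 1))
  net <- build_network(edges, sites)
  obs <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  fit <- suppressWarnings(streamtree(net, obs))
  expect_equal(unname(coef(fit)["e1.1"]), 0.3)
  expect_equal(fit$fitted[1], 0.3)
})

test_that("tree-additive distances are recovered exactly with R^2 = 1", {
  for (seed in c(4, 12, 30)) {
    nw <- random_tip_network(9, n_barriers = 0, seed = seed)
    inc <- build_incidence(nw$network)
    set.seed(seed)
    d_true <- runif(ncol(inc$incidence), 0, 0.1)
    obs_vec <- as.numeric(inc$incidence %*% d_true)
    fit <- suppressWarnings(streamtree(inc, obs_vec))
    ident <- fit$sections$identifiable
    expect_true(any(ident))
    expect_lt(max(abs(fit$sections$distance[ident] - d_true[ident])), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_lt(sqrt(fit$rss), 1e-8)
    ## structural invariant: fitted == incidence %*% distances
    d0 <- ifelse(is.na(fit$sections$distance), 0, fit$sections$distance)
    expect_lt(max(abs(fit$fitted - as.numeric(fit$incidence %*% d0))), 1e-9)
    expect_true(all(d0 >= 0))
  }
})

test_that("NNLS clamps negative-demand sections at zero with residual left over", {
  ## Y network, observations chosen so unconstrained LS wants a negative arm
  y <- make_y_network(lengths = c(1, 1, 1))
  inc <- build_incidence(y)
  A <- inc$incidence[, colSums(inc$incidence) > 0]
  obs <- c(0.05, 0.05, 0.5)           # A close to both, B-C far: infeasible additively
  ls <- coef(lm(obs ~ A + 0))
  expect_lt(min(ls), 0)
  fit <- streamtree(inc, obs)
  d <- fit$sections$distance[fit$sections$identifiable]
  expect_true(all(d >= 0))
  expect_gt(fit$rss, 0)
})

test_that("fits are invariant to site order and drop undefined pairs", {
  nw <- random_tip_network(8, seed = 19)
  inc <- build_incidence(nw$network)
  set.seed(19)
  d_true <- runif(ncol(inc$incidence), 0, 0.2)
  obs <- refold(as.numeric(inc$incidence %*% d_true),
                nw$network$sites$site_id)
  fit1 <- suppressWarnings(streamtree(nw$network, obs))
  perm <- rev(nw$network$sites$site_id)
  fit2 <- suppressWarnings(streamtree(nw$network, obs[perm, perm]))
  s1 <- fit1$sections[order(fit1$sections$section_id), ]
  s2 <- fit2$sections[order(fit2$sections$section_id), ]
  expect_equal(s1$distance, s2$distance, tolerance = 1e-9)

  obs_na <- obs
  obs_na[1, 2] <- obs_na[2, 1] <- NA
  expect_message(fit3 <- streamtree(nw$network, obs_na), "dropping 1 pair")
  expect_equal(sum(fit3$used), nrow(inc$incidence) - 1)
})

test_that("sections split by a barrier share one merged contribution", {
  barr <- data.frame(barrier_id = "b1", edge_id = "e1", offset_km = 1)
  y <- make_y_network(barriers = barr)
  obs <- matrix(c(0, .4, .2, .4, 0, .2, .2, .2, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fit <- suppressWarnings(streamtree(y, obs))
  sec <- fit$sections
  halves <- sec[sec$section_id %in% c("e1.1", "e1.2"), ]
  expect_false(any(halves$identifiable))
  expect_equal(halves$distance[1], halves$distance[2])
})

test_that("section classes bin at the documented half-open boundaries", {
  d <- c(a = 0, b = 0.0099, c = 0.01, d = 0.049, e = 0.05, f = 0.3)
  cls <- section_fst_breaks(d)
  expect_equal(as.character(cls[c("a", "b")]), rep("0-0.01", 2))
  expect_equal(as.character(cls[c("c", "d")]), rep("0.01-0.05", 2))
  expect_equal(as.character(cls[c("e", "f")]), rep("0.05+", 2))
  ## random fit: counts equal direct binning
  set.seed(6)
  dv <- runif(50, 0, 0.1)
  expect_equal(unname(table(section_fst_breaks(dv))),
               unname(table(cut(dv, c(-Inf, 0.01, 0.05, Inf), right = FALSE))))
})
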