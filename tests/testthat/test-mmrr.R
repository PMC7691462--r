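test_that("unfold and refold are exact inverses in canonical order", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[lower.tri(m)] <- c(1, 2, 3); m <- m + t(m)
  v <- unfold(m)
  expect_length(v, 3)
  expect_equal(unname(refold(v, letters[1:3])), unname(m))
  ## 25 sites -> 300 dyads
  big <- euclidean_distance_matrix(matrix(rnorm(25), 25,
                                          dimnames = list(paste0("s", 1:25),
                                                          NULL)))
  expect_length(unfold(big), 300)
  asym <- m; asym[1, 2] <- asym[1, 2] + 1
  expect_error(unfold(asym), "symmetric")
})

test_that("ztransform standardises and rejects constants", {
  z <- ztransform(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_lt(abs(mean(ztransform(rnorm(50)))), 1e-12)
  expect_error(ztransform(rep(2, 5), "catchment"), "catchment")
})

test_that("regressing a matrix on itself gives beta 1, R^2 1 and minimal p", {
  set.seed(2)
  X <- euclidean_distance_matrix(matrix(rnorm(20), 10,
                                        dimnames = list(paste0("s", 1:10),
                                                        NULL)))
  f <- mmrr(X, list(d = X), n_perm = 99, seed = 3)
  expect_equal(unname(coef(f)), 1, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(f$p), 1 / 100)
  expect_equal(f$model_p, 1 / 100)
})

test_that("a single-predictor coefficient equals the Pearson correlation", {
  set.seed(4)
  mk <- function() euclidean_distance_matrix(
    matrix(rnorm(30), 15, dimnames = list(paste0("s", 1:15), NULL)))
  Y <- mk(); X <- mk()
  f <- mmrr(Y, list(x = X), n_perm = 0)
  expect_equal(unname(coef(f)),
               cor(ztransform(unfold(Y)), ztransform(unfold(X))),
               tolerance = 1e-12)
})

test_that("coefficients are invariant to site relabelling", {
  set.seed(9)
  labs <- paste0("s", 1:12)
  Y <- euclidean_distance_matrix(matrix(rnorm(24), 12,
                                        dimnames = list(labs, NULL)))
  X <- euclidean_distance_matrix(matrix(rnorm(24), 12,
                                        dimnames = list(labs, NULL)))
  f1 <- mmrr(Y, list(x = X), n_perm = 0)
  perm <- sample(labs)
  f2 <- mmrr(Y[perm, perm], list(x = X[perm, perm]), n_perm = 0)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("null p-values are uniform and collinearity is rejected", {
  set.seed(14)
  mk <- function() euclidean_distance_matrix(
    matrix(rnorm(28), 14, dimnames = list(paste0("s", 1:14), NULL)))
  ps <- replicate(150, mmrr(mk(), list(x = mk()), n_perm = 99,
                            seed = sample.int(1e6, 1))$p[1])
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  X <- mk()
  expect_error(mmrr(mk(), list(a = X, b = X * 2), n_perm = 0), "collinear")
})

test_that("planted barrier and catchment effects are both detected", {
  set.seed(77)
  nw <- random_tip_network(15, n_barriers = 8, seed = 77)
  cm <- catchment_model_matrix(nw$network)
  bm <- barrier_count_matrix(nw$network)
  noise <- euclidean_distance_matrix(
    matrix(rnorm(15), 15, dimnames = list(rownames(cm), NULL)))
  Y <- 0.05 * cm + 0.03 * bm + 0.005 * noise
  f <- mmrr(Y, list(catchment = cm, barriers = bm), n_perm = 199, seed = 5)
  expect_true(all(coef(f) > 0))
  expect_true(all(f$p < 0.05))
})

test_that("vif_filter keeps orthogonal sets and prunes duplicates", {
  set.seed(21)
  n <- 40
  base <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("v", 1:4)))
  expect_setequal(vif_filter(as.data.frame(base)), paste0("v", 1:4))

  dup <- cbind(base, v4b = base[, "v4"])
  kept <- vif_filter(as.data.frame(dup))
  expect_length(kept, 4)
  expect_length(intersect(c("v4", "v4b"), kept), 1)

  ## retained VIFs all at or below the threshold (direct recomputation)
  cors <- matrix(rnorm(n * 8), n, 8)
  cors[, 2] <- cors[, 1] * 0.99 + rnorm(n, 0, 0.05)
  cors[, 4] <- cors[, 3] * 0.99 + rnorm(n, 0, 0.05)
  colnames(cors) <- paste0("w", 1:8)
  kept2 <- vif_filter(as.data.frame(cors), threshold = 10)
  for (v in kept2) {
    r2 <- summary(lm(cors[, v] ~ cors[, setdiff(kept2, v)]))$r.squared
    expect_lte(1 / (1 - r2), 10 + 1e-8)
  }
})

test_that("pca_reduce applies the Kaiser rule and falls back to raw variables", {
  set.seed(33)
  n <- 200
  a <- rnorm(n)
  two <- data.frame(x = a, y = a)           # perfectly correlated
  red <- pca_reduce(two)
  expect_equal(red$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(red$kind, "raw")             # a single qualifying PC -> raw

  ## several independent latent factors: retained set matches direct eigen
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 2] <- X[, 1] + rnorm(n, 0, 0.3)
  X[, 4] <- X[, 3] + rnorm(n, 0, 0.3)
  red2 <- pca_reduce(as.data.frame(X))
  ev <- eigen(cor(X))$values
  expect_equal(red2$eigenvalues, ev, tolerance = 1e-8)
  if (red2$kind == "pc")
    expect_equal(ncol(red2$scores), sum(ev > 1))

  expect_warning(pca_reduce(data.frame(x = rnorm(10), const = 1)),
                 "constant")
  ## single variable category passes through
  expect_equal(pca_reduce(data.frame(only = rnorm(10)))$kind, "raw")
})

test_that("euclidean distances match the double-loop definition", {
  sc <- c(a = 0, b = 3, c = 4)
  m <- euclidean_distance_matrix(sc)
  expect_equal(m["a", "b"], 3)
  expect_equal(m["a", "c"], 4)
  expect_equal(m["b", "c"], 1)
  set.seed(3)
  S <- matrix(rnorm(12 * 3), 12, dimnames = list(paste0("s", 1:12), NULL))
  m2 <- euclidean_distance_matrix(S)
  for (i in 1:12) for (j in 1:12)
    expect_equal(m2[i, j], sqrt(sum((S[i, ] - S[j, ])^2)), tolerance = 1e-12)
  expect_error(euclidean_distance_matrix(c(1, NA)), "missing")
})

test_that("variance shares follow the absolute-coefficient rule", {
  expect_equal(unname(variance_share(c(0.725, 0.462))), c(61, 39))
  expect_equal(unname(variance_share(c(1, 1))), c(50, 50))
  expect_equal(unname(variance_share(c(2, 1, 1))), c(50, 25, 25))
  expect_error(variance_share(c(0, 0)), "zero")
})

test_that("univariate gating feeds only significant predictors to the joint model", {
  set.seed(55)
  nw <- random_tip_network(14, n_barriers = 6, seed = 55)
  cm <- catchment_model_matrix(nw$network)
  bm <- barrier_count_matrix(nw$network)
  labs <- rownames(cm)
  irrelevant <- euclidean_distance_matrix(
    matrix(rnorm(14), 14, dimnames = list(labs, NULL)))
  Y <- 0.06 * cm + 0.04 * bm + refold(rnorm(14 * 13 / 2, 0, 0.01), labs)
  res <- mmrr_analysis(Y, list(catchment = cm, barriers = bm,
                               env = irrelevant),
                       n_perm = 199, seed = 8)
  expect_setequal(res$selected, c("catchment", "barriers"))
  expect_false("env" %in% names(res$multivariate$coefficients))
  expect_true(all(c("model", "variable", "coefficient", "ci_lo", "ci_hi",
                    "p", "R2", "model_p") %in% names(res$table)))
})
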