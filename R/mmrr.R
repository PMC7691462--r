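#' Unfold a symmetric distance matrix into its pair vector
#'
#' Extracts the off-diagonal pairs in the canonical order (1,2), (1,3), ...,
#' (1,k), (2,3), ... used throughout the package, after checking symmetry.
#'
#' @param m square symmetric numeric matrix with zero diagonal.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `k(k-1)/2`, named by site pair when the
#'   matrix carries labels.
#' @export
unfold <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  pr <- site_pairs(labels)
  stats::setNames(m[cbind(pr$i, pr$j)],
                  paste(pr$site_i, pr$site_j, sep = "-"))
}

#' Refold a pair vector into a symmetric matrix
#'
#' Inverse of [unfold]: builds the symmetric zero-diagonal matrix whose
#' unfolded vector equals `v`.
#'
#' @param v pair vector in canonical order.
#' @param labels site labels (length k with `length(v) == k(k-1)/2`).
#' @export
refold <- function(v, labels) {
  k <- length(labels)
  if (length(v) != k * (k - 1) / 2)
    stop("length(v) does not match k(k-1)/2", call. = FALSE)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  pr <- site_pairs(labels)
  m[cbind(pr$i, pr$j)] <- v
  m[cbind(pr$j, pr$i)] <- v
  m
}

#' Z-transform a vector to zero mean and unit (sample) standard deviation
#'
#' @param v numeric vector.
#' @param label name used in the error message for constant input.
#' @export
ztransform <- function(v, label = "input") {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop(sprintf("cannot z-transform constant matrix/vector: %s", label),
         call. = FALSE)
  (v - mean(v)) / s
}

check_shared_labels <- function(mats) {
  labs <- rownames(mats[[1]])
  if (is.null(labs)) stop("matrices must carry site labels", call. = FALSE)
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), labs))
      stop(sprintf("matrix '%s' does not share the site labels/order", nm),
           call. = FALSE)
  }
  labs
}

#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses an unfolded dependent distance matrix (typically pairwise FST)
#' on one or more unfolded predictor distance/model matrices. All matrices
#' are z-transformed so partial regression coefficients are directly
#' comparable. Because the dyads of a distance matrix are not independent,
#' significance is assessed by randomization: the rows and columns of the
#' dependent matrix are permuted jointly `n_perm` times, the t-statistics are
#' recomputed each time, and `p = (1 + #{|t_perm| >= |t_obs|})/(n_perm + 1)`
#' per coefficient (model p analogously from the permuted R-squared, which is
#' monotone in the F statistic here). Normal-theory 95% CIs are reported for
#' presentation but are nominal; the permutation p-values carry the
#' inference.
#'
#' @param Y dependent matrix (or `pairwise_fst` object).
#' @param X named list of predictor matrices sharing `Y`'s labels.
#' @param n_perm number of permutations (default 10000; 0 skips inference).
#' @param seed RNG seed, required when `n_perm > 0`.
#' @return object of class `mmrr` with `coefficients` (standardized, no
#'   intercept -- it is 0 after z-transformation), `ci`, `t`, `p`,
#'   `r_squared`, `model_p`, `n_perm`, `seed`.
#' @export
mmrr <- function(Y, X, n_perm = 10000, seed = NULL) {
  if (inherits(Y, "pairwise_fst")) Y <- Y$fst
  if (is.matrix(X)) X <- list(X = X)
  if (is.null(names(X)) || any(names(X) == ""))
    names(X) <- paste0("X", seq_along(X))
  labs <- check_shared_labels(c(list(Y = Y), X))
  k <- length(labs)
  y <- ztransform(unfold(Y), "Y")
  Xv <- vapply(names(X), function(nm) ztransform(unfold(X[[nm]]), nm),
               numeric(length(y)))
  n <- length(y)
  p <- ncol(Xv)
  D <- cbind(`(Intercept)` = 1, Xv)
  XtX <- crossprod(D)
  if (kappa(XtX) > 1e10)
    stop("predictor matrices are (near-)collinear; apply vif_filter first",
         call. = FALSE)
  Cinv <- solve(XtX)
  Cmat <- Cinv %*% t(D)                    # maps y -> coefficients
  b <- as.numeric(Cmat %*% y)
  fitted <- as.numeric(D %*% b)
  rss <- sum((y - fitted)^2)
  dfree <- n - p - 1
  s2 <- rss / dfree
  se <- sqrt(s2 * diag(Cinv))
  tval <- b / se
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  ci <- cbind(b - stats::qt(0.975, dfree) * se,
              b + stats::qt(0.975, dfree) * se)
  dimnames(ci) <- list(colnames(D), c("2.5 %", "97.5 %"))

  p_perm <- model_p <- NULL
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required when n_perm > 0", call. = FALSE)
    set.seed(seed)
    pr <- site_pairs(labs)
    pos <- matrix(0L, k, k)
    pos[cbind(pr$i, pr$j)] <- seq_len(n)
    pos[cbind(pr$j, pr$i)] <- seq_len(n)
    Yperm <- matrix(0, n, n_perm)
    for (bcol in seq_len(n_perm)) {
      sg <- sample.int(k)
      Yperm[, bcol] <- y[pos[cbind(sg[pr$i], sg[pr$j])]]
    }
    Bm <- Cmat %*% Yperm                   # (p+1) x B
    Fm <- D %*% Bm
    RSSp <- colSums((Yperm - Fm)^2)
    s2p <- RSSp / dfree
    Tp <- Bm / sqrt(outer(diag(Cinv), s2p))
    p_perm <- vapply(seq_len(p + 1), function(jj)
      (1 + sum(abs(Tp[jj, ]) >= abs(tval[jj]))) / (n_perm + 1), numeric(1))
    names(p_perm) <- colnames(D)
    R2p <- 1 - RSSp / tss                  # TSS is permutation-invariant
    model_p <- (1 + sum(R2p >= r2)) / (n_perm + 1)
  }

  structure(list(coefficients = stats::setNames(b[-1], colnames(Xv)),
                 intercept = b[1],
                 se = stats::setNames(se[-1], colnames(Xv)),
                 t = stats::setNames(tval[-1], colnames(Xv)),
                 ci = ci[-1, , drop = FALSE],
                 p = if (is.null(p_perm)) NULL else p_perm[-1],
                 r_squared = r2, model_p = model_p,
                 n = n, n_perm = n_perm, seed = seed,
                 labels = labs), class = "mmrr")
}

#' @export
print.mmrr <- function(x, ...) {
  cat(sprintf("MMRR: %d dyads, R^2 = %.3f", x$n, x$r_squared))
  if (!is.null(x$model_p))
    cat(sprintf(", model p = %.4g (%d permutations)", x$model_p, x$n_perm))
  cat("\n")
  tab <- data.frame(coefficient = x$coefficients,
                    ci_lo = x$ci[, 1], ci_hi = x$ci[, 2])
  if (!is.null(x$p)) tab$p <- x$p
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.mmrr <- function(object, ...) { print(object); invisible(object) }

#' @export
coef.mmrr <- function(object, ...) object$coefficients

#' @export
plot.mmrr <- function(x, Y, X, predictor = 1, ...) {
  ## partial-style display: dependent vs one predictor's unfolded values
  yv <- ztransform(unfold(if (inherits(Y, "pairwise_fst")) Y$fst else Y))
  xv <- ztransform(unfold(X[[predictor]]))
  graphics::plot(xv, yv, pch = 19, col = "grey30",
                 xlab = paste0(names(X)[predictor], " (z)"),
                 ylab = "genetic distance (z)", ...)
  graphics::abline(stats::lm(yv ~ xv), col = "firebrick")
  invisible(x)
}

#' Iterative variance-inflation-factor filtering
#'
#' Repeatedly drops the variable with the largest VIF until all VIFs are at
#' or below `threshold` (ties broken by variable name). If at any step the
#' number of variables is not smaller than the number of sites (so OLS VIFs
#' are undefined), variables are first discarded from the most correlated
#' pair -- dropping the member with the larger mean absolute correlation --
#' until VIFs become computable.
#'
#' @param env data.frame or matrix of site-level variables (numeric columns;
#'   a `site_id` column is ignored).
#' @param threshold maximum acceptable VIF (default 10).
#' @return character vector of retained variable names.
#' @export
vif_filter <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  env$site_id <- NULL
  if (ncol(env) < 2) return(names(env))
  X <- as.matrix(env)
  if (!is.numeric(X)) stop("environmental variables must be numeric", call. = FALSE)
  vars <- colnames(X)
  n <- nrow(X)

  vif_of <- function(v, others) {
    if (!length(others)) return(1)
    ## a perfect fit (exact duplicate) is expected input here: VIF = Inf
    r2 <- suppressWarnings(
      summary(stats::lm(X[, v] ~ X[, others, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  ## pairwise fallback when the OLS system is under-determined
  while (length(vars) >= n - 1 && length(vars) > 2) {
    cr <- abs(stats::cor(X[, vars]))
    diag(cr) <- 0
    top <- which(cr == max(cr), arr.ind = TRUE)[1, ]
    cand <- vars[top]
    meanr <- colMeans(cr[, cand, drop = FALSE])
    drop <- cand[order(-meanr, cand)][1]
    message(sprintf("vif_filter: under-determined, dropping '%s' by pairwise |r|",
                    drop))
    vars <- setdiff(vars, drop)
  }
  repeat {
    if (length(vars) < 2) break
    v <- vapply(vars, function(vn) vif_of(vn, setdiff(vars, vn)), numeric(1))
    if (all(v <= threshold)) break
    worst <- vars[v == max(v)]
    drop <- sort(worst)[1]
    vars <- setdiff(vars, drop)
  }
  vars
}

#' Reduce an environmental category to principal components
#'
#' Correlation-matrix PCA of a category's variables. Components with
#' eigenvalue above 1 (Kaiser criterion) are retained. If the criterion
#' would retain one component or none, the category's raw (standardized)
#' variables are returned instead, since a single-PC summary of a category is
#' not more interpretable than its variables. Constant variables are dropped
#' with a warning.
#'
#' @param env data.frame/matrix of one category's site variables.
#' @param prefix name prefix for the PC score columns.
#' @return list with `scores` (site x component/variable matrix),
#'   `eigenvalues`, and `kind` (`"pc"` or `"raw"`).
#' @export
pca_reduce <- function(env, prefix = "PC") {
  env <- as.data.frame(env)
  env$site_id <- NULL
  X <- as.matrix(env)
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(colnames(X)[const], collapse = ", ")), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no usable variables", call. = FALSE)
  if (ncol(X) == 1) {
    return(list(scores = scale(X), eigenvalues = 1, kind = "raw"))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  keep <- ev > 1
  if (sum(keep) <= 1) {
    return(list(scores = scale(X), eigenvalues = ev, kind = "raw"))
  }
  sc <- pc$x[, keep, drop = FALSE]
  colnames(sc) <- paste0(prefix, seq_len(ncol(sc)))
  rownames(sc) <- rownames(env)
  list(scores = sc, eigenvalues = ev, kind = "pc")
}

#' Pairwise Euclidean distance matrix from site scores
#'
#' @param scores numeric matrix/data.frame (sites x dimensions) or vector;
#'   rownames/names are the site labels.
#' @export
euclidean_distance_matrix <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1,
                                             dimnames = list(names(scores), NULL))
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("missing score(s)", call. = FALSE)
  m <- as.matrix(stats::dist(scores))
  dimnames(m) <- list(rownames(scores), rownames(scores))
  m
}

#' Build the environmental predictor distance matrices
#'
#' Full predictor-construction chain for isolation-by-environment testing:
#' VIF filtering across all variables, per-category PCA with the Kaiser
#' criterion (raw variables kept where fewer than two components qualify),
#' and one site-by-site Euclidean distance matrix per retained component or
#' variable.
#'
#' @param env data.frame of site variables; rownames (or a `site_id` column)
#'   identify sites.
#' @param categories named character vector mapping variable -> category.
#' @param vif_threshold VIF threshold (default 10).
#' @return list with `matrices` (named list of distance matrices),
#'   `retained_vars`, and per-category PCA summaries.
#' @export
env_predictor_set <- function(env, categories, vif_threshold = 10) {
  env <- as.data.frame(env)
  if ("site_id" %in% names(env)) {
    rownames(env) <- env$site_id
    env$site_id <- NULL
  }
  retained <- vif_filter(env, threshold = vif_threshold)
  mats <- list()
  pcs <- list()
  for (cat_name in unique(categories[retained])) {
    vars <- retained[categories[retained] == cat_name]
    red <- pca_reduce(env[, vars, drop = FALSE],
                      prefix = paste0(cat_name, "PC"))
    pcs[[cat_name]] <- red
    for (cn in colnames(red$scores)) {
      mats[[cn]] <- euclidean_distance_matrix(red$scores[, cn, drop = FALSE])
    }
  }
  list(matrices = mats, retained_vars = retained, pca = pcs)
}

#' Share of explained variation attributed to each predictor
#'
#' For a multivariate MMRR on z-transformed matrices, attributes the
#' explained variation to predictors in proportion to the absolute
#' standardized coefficients: `share_i = |b_i| / sum(|b_j|) * 100`, rounded
#' to whole percent.
#'
#' @param coefficients numeric vector of standardized coefficients (an
#'   `mmrr` object is also accepted).
#' @return named integer percentage vector.
#' @export
variance_share <- function(coefficients) {
  if (inherits(coefficients, "mmrr")) coefficients <- coefficients$coefficients
  b <- abs(as.numeric(coefficients))
  if (all(b == 0)) stop("all coefficients are zero; shares undefined",
                        call. = FALSE)
  stats::setNames(as.integer(round(100 * b / sum(b))), names(coefficients))
}

#' Univariate screening followed by a multivariate MMRR
#'
#' Mirrors the conventional two-stage workflow: each candidate predictor is
#' tested in its own single-predictor MMRR, and predictors whose coefficient
#' permutation p-value passes `gate` are combined in one multivariate model.
#'
#' @param Y dependent distance matrix (or `pairwise_fst`).
#' @param X named list of candidate predictor matrices.
#' @param n_perm permutations for each model.
#' @param seed RNG seed.
#' @param gate univariate inclusion threshold on the coefficient p-value
#'   (default 0.05).
#' @return list with `univariate` (list of `mmrr` fits), `multivariate`
#'   (`mmrr` fit or `NULL`), `selected`, and a Table-style data.frame
#'   `table` (`model, variable, coefficient, ci_lo, ci_hi, p, R2, model_p`).
#' @export
mmrr_analysis <- function(Y, X, n_perm = 10000, seed = NULL, gate = 0.05) {
  uni <- lapply(names(X), function(nm)
    mmrr(Y, X[nm], n_perm = n_perm, seed = seed))
  names(uni) <- names(X)
  rows <- lapply(names(X), function(nm) {
    f <- uni[[nm]]
    data.frame(model = nm, variable = nm,
               coefficient = unname(f$coefficients),
               ci_lo = f$ci[1, 1], ci_hi = f$ci[1, 2],
               p = unname(f$p), R2 = f$r_squared, model_p = f$model_p)
  })
  tab <- do.call(rbind, rows)
  selected <- names(X)[vapply(uni, function(f) f$p[1] <= gate, logical(1))]
  multi <- NULL
  if (length(selected) >= 1) {
    multi <- mmrr(Y, X[selected], n_perm = n_perm, seed = seed)
    mt <- data.frame(model = paste(selected, collapse = " + "),
                     variable = names(multi$coefficients),
                     coefficient = unname(multi$coefficients),
                     ci_lo = multi$ci[, 1], ci_hi = multi$ci[, 2],
                     p = unname(multi$p), R2 = multi$r_squared,
                     model_p = multi$model_p)
    tab <- rbind(tab, mt)
  }
  rownames(tab) <- NULL
  list(univariate = uni, multivariate = multi, selected = selected,
       table = tab)
}
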