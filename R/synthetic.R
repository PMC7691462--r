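#' Generate a random dendritic river network with sites and barriers
#'
#' Draws a random binary tree (sites at the tips), scales its branch lengths
#' to kilometres, assigns catchments as subtrees, and scatters in-stream
#' barriers uniformly along the network (edge chosen proportional to length,
#' position uniform within the edge). Deterministic under `seed`.
#'
#' @param n_sites number of sampling sites (tree tips).
#' @param n_catchments number of catchments (subtree groups, <= n_sites).
#' @param n_barriers number of barriers.
#' @param mean_edge_km average edge length in km.
#' @param n_ind_range range of individuals per site, sampled uniformly.
#' @param seed RNG seed.
#' @return list with `edges`, `sites`, `barriers` data.frames (the
#'   [build_network] input format) and the built `network`.
#' @export
generate_network <- function(n_sites = 25, n_catchments = 13,
                             n_barriers = 15, mean_edge_km = 20,
                             n_ind_range = c(6, 18), seed = 1L) {
  if (n_catchments > n_sites)
    stop("n_catchments must not exceed n_sites", call. = FALSE)
  if (n_sites < 2) stop("need at least 2 sites", call. = FALSE)
  set.seed(seed)
  tr <- ape::rtree(n_sites)
  tr$edge.length <- tr$edge.length * 2 * mean_edge_km  # runif(0,1) branches
  n_nodes <- max(tr$edge)
  edges <- data.frame(
    edge_id = sprintf("e%02d", seq_len(nrow(tr$edge))),
    node_a = paste0("n", tr$edge[, 1]),
    node_b = paste0("n", tr$edge[, 2]),
    length_km = round(tr$edge.length, 3))

  ## catchments: repeatedly split the largest tip group at its subtree root
  groups <- list(seq_len(n_sites))
  children_of <- split(tr$edge[, 2], tr$edge[, 1])
  tips_under <- function(node) {
    if (node <= n_sites) return(node)
    unlist(lapply(children_of[[as.character(node)]], tips_under))
  }
  mrca_of <- function(tips) {
    if (length(tips) == 1) return(tips)
    anc <- function(x) {
      path <- x
      while (TRUE) {
        par <- tr$edge[tr$edge[, 2] == x, 1]
        if (!length(par)) break
        path <- c(path, par); x <- par
      }
      path
    }
    paths <- lapply(tips, anc)
    common <- Reduce(intersect, paths)
    common[1]
  }
  while (length(groups) < n_catchments) {
    sizes <- lengths(groups)
    gi <- which.max(sizes)
    if (sizes[gi] < 2) break
    node <- mrca_of(groups[[gi]])
    kids <- children_of[[as.character(node)]]
    parts <- lapply(kids, function(k) intersect(tips_under(k), groups[[gi]]))
    parts <- parts[lengths(parts) > 0]
    groups <- c(groups[-gi], parts)
  }
  catch <- integer(n_sites)
  for (g in seq_along(groups)) catch[groups[[g]]] <- g

  ## one site at each tip: tips are node_b of their pendant edge
  tip_edge <- match(paste0("n", seq_len(n_sites)), edges$node_b)
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    catchment_id = sprintf("C%02d", catch),
    edge_id = edges$edge_id[tip_edge],
    offset_km = edges$length_km[tip_edge],
    n_individuals = sample(seq(n_ind_range[1], n_ind_range[2]),
                           n_sites, replace = TRUE))

  barriers <- NULL
  if (n_barriers > 0) {
    be <- sample(nrow(edges), n_barriers, replace = TRUE,
                 prob = edges$length_km)
    barriers <- data.frame(
      barrier_id = sprintf("B%02d", seq_len(n_barriers)),
      edge_id = edges$edge_id[be],
      offset_km = round(stats::runif(n_barriers) * edges$length_km[be], 3))
  }
  net <- build_network(edges, sites, barriers)
  list(edges = edges, sites = sites, barriers = barriers, network = net)
}

#' Generate hierarchically structured genotypes on a river network
#'
#' Builds a per-pair target divergence from a linear barrier/catchment model
#' (`F = base + catchment * I(different catchment) + barrier * n_barriers`,
#' truncated to `[0.01, 0.8]`), projects the target matrix onto the nearest
#' tree-additive set of per-section contributions (non-negative least
#' squares on the path incidence matrix), and then evolves allele
#' frequencies down the network under the Balding-Nichols model: ancestral
#' frequencies uniform on (0.05, 0.95) at an arbitrary root, and a Beta step
#' with divergence parameter equal to the section's contribution along every
#' section. Because a pairwise Weir-Cockerham FST averages the two branches
#' of a pair's path, section contributions are fitted to twice the target so
#' realized FST sits on the target scale. Diploid genotypes are binomial
#' draws from the site frequencies, with optional missingness.
#'
#' @param network a [river_network] (or the list from [generate_network]).
#' @param fst_model list with `base`, `catchment`, `barrier` effect sizes.
#' @param n_ind named vector of individuals per site (default: the
#'   `n_individuals` column of the network's site table, else 10).
#' @param n_loci number of SNPs.
#' @param missing_rate genotype missingness probability.
#' @param noise_sd sd of non-additive noise added to the target matrix
#'   before projection (0 keeps targets exactly tree-additive).
#' @param seed RNG seed.
#' @return list: `genotypes` (a [genotypes] object), `truth` (target matrix,
#'   fitted section contributions, per-site divergence, model, seed).
#' @export
generate_genotypes <- function(network,
                               fst_model = list(base = 0.03,
                                                catchment = 0.10,
                                                barrier = 0.04),
                               n_ind = NULL, n_loci = 3443,
                               missing_rate = 0.05, noise_sd = 0,
                               seed = 1L) {
  if (!inherits(network, "river_network")) network <- network$network
  set.seed(seed)
  sites <- network$sites
  k <- nrow(sites)
  cm <- catchment_model_matrix(network)
  bm <- barrier_count_matrix(network)
  target <- fst_model$base + fst_model$catchment * cm +
    fst_model$barrier * bm
  if (noise_sd > 0) {
    pr <- site_pairs(sites$site_id)
    noise <- stats::rnorm(nrow(pr), 0, noise_sd)
    target <- target + refold(noise, sites$site_id)
  }
  target <- pmin(pmax(target, 0.01), 0.8)
  diag(target) <- 0
  dimnames(target) <- list(sites$site_id, sites$site_id)

  ## nearest tree-additive decomposition of 2x target (see Details)
  inc <- build_incidence(network)
  y <- 2 * unfold(target)
  sol <- pracma::lsqnonneg(inc$incidence, y)
  f_sec <- stats::setNames(sol$x, colnames(inc$incidence))
  resid <- sqrt(mean((y - inc$incidence %*% sol$x)^2))
  if (resid > 1e-6)
    message(sprintf(paste0("generate_genotypes: target matrix projected onto ",
                           "nearest additive matrix (rms gap %.4f)"), resid))

  ## evolve frequencies over the re-segmented tree from an arbitrary root
  ## (plain BFS over the section table; divergence above the pairs' common
  ## ancestors is shared and cancels out of pairwise comparisons)
  secs <- network$sections
  root <- secs$node_from[1]
  adj <- rbind(secs[, c("node_from", "node_to", "section_id")],
               stats::setNames(secs[, c("node_to", "node_from", "section_id")],
                               c("node_from", "node_to", "section_id")))
  bn_step <- function(pv, f) {
    if (is.na(f) || f <= 0) return(pv)
    f <- min(f, 0.95)
    pv <- pmin(pmax(pv, 1e-6), 1 - 1e-6)
    stats::rbeta(length(pv), pv * (1 - f) / f, (1 - pv) * (1 - f) / f)
  }
  freqs <- list(); div <- c()
  freqs[[root]] <- stats::runif(n_loci, 0.05, 0.95)
  div[root] <- 0
  queue <- root; seen <- root
  while (length(queue)) {
    nd <- queue[1]; queue <- queue[-1]
    out <- adj[adj$node_from == nd & !(adj$node_to %in% seen), , drop = FALSE]
    for (e in seq_len(nrow(out))) {
      child <- out$node_to[e]
      f <- unname(f_sec[out$section_id[e]])
      freqs[[child]] <- bn_step(freqs[[nd]], f)
      div[child] <- div[nd] + ifelse(is.na(f), 0, f)
      seen <- c(seen, child); queue <- c(queue, child)
    }
  }

  if (is.null(n_ind)) {
    n_ind <- if ("n_individuals" %in% names(sites))
      stats::setNames(sites$n_individuals, sites$site_id)
    else stats::setNames(rep(10L, k), sites$site_id)
  }
  G <- NULL; pops <- character(0)
  for (s in seq_len(k)) {
    ps <- freqs[[sites$node[s]]]
    ni <- n_ind[[sites$site_id[s]]]
    Gs <- matrix(stats::rbinom(ni * n_loci, 2L, rep(ps, each = ni)),
                 ni, n_loci)
    G <- rbind(G, Gs)
    pops <- c(pops, rep(sites$site_id[s], ni))
  }
  rownames(G) <- paste0(pops, "_", stats::ave(seq_along(pops), pops,
                                              FUN = seq_along))
  colnames(G) <- sprintf("snp%05d", seq_len(n_loci))
  if (missing_rate > 0)
    G[matrix(stats::runif(length(G)) < missing_rate, nrow(G))] <- NA

  ## per-site root-to-site divergence and its drift-equivalent Ne over a
  ## 160-generation isolation horizon (summary truth, not a model input)
  site_div <- div[sites$node] / 2
  ne_equiv <- 1 / (2 * (1 - (1 - pmin(site_div, 0.95))^(1 / 160)))

  list(genotypes = genotypes(G, pops,
                             locus_groups = colnames(G)),
       truth = list(target_fst = target, section_f = f_sec,
                    fst_model = fst_model, projection_rms = resid,
                    site_divergence = stats::setNames(site_div,
                                                      sites$site_id),
                    ne_drift_equivalent = stats::setNames(ne_equiv,
                                                          sites$site_id),
                    seed = seed))
}

#' Generate site-level environmental covariates with planted collinearity
#'
#' Draws `n_vars` standard-normal site variables split evenly over
#' `n_categories` categories (temperature, precipitation, flow, disturbance,
#' topography by default), planting `collinear_groups` pairs of variables
#' correlated at about `r = 0.95` so that VIF filtering has real work to do.
#' Variables are independent of any genetic structure, emulating a study
#' system without isolation by environment.
#'
#' @param sites site table (needs `site_id`) or a [river_network].
#' @param n_vars total variables (default 40).
#' @param n_categories number of categories (default 5).
#' @param collinear_groups number of planted highly-correlated pairs.
#' @param seed RNG seed.
#' @return list: `env` data.frame (`site_id` + variables), `categories`
#'   named vector variable -> category, `collinear_pairs`.
#' @export
generate_env <- function(sites, n_vars = 40, n_categories = 5,
                         collinear_groups = 5, seed = 1L) {
  if (inherits(sites, "river_network")) sites <- sites$sites
  set.seed(seed)
  k <- nrow(sites)
  cat_names <- c("temp", "precip", "flow", "disturb", "topo")[
    seq_len(n_categories)]
  per_cat <- rep(n_vars %/% n_categories, n_categories)
  per_cat[seq_len(n_vars %% n_categories)] <-
    per_cat[seq_len(n_vars %% n_categories)] + 1
  vars <- unlist(lapply(seq_len(n_categories), function(i)
    sprintf("%s%02d", cat_names[i], seq_len(per_cat[i]))))
  categories <- stats::setNames(rep(cat_names, per_cat), vars)
  X <- matrix(stats::rnorm(k * n_vars), k, n_vars,
              dimnames = list(sites$site_id, vars))
  pairs <- list()
  if (collinear_groups > 0) {
    idx <- seq_len(min(collinear_groups * 2, n_vars))
    for (gidx in seq_len(length(idx) %/% 2)) {
      a <- idx[2 * gidx - 1]; b <- idx[2 * gidx]
      X[, b] <- 0.95 * X[, a] + sqrt(1 - 0.95^2) * stats::rnorm(k)
      pairs[[gidx]] <- vars[c(a, b)]
    }
  }
  list(env = data.frame(site_id = sites$site_id, X, check.names = FALSE),
       categories = categories, collinear_pairs = pairs)
}

#' Generate a complete synthetic riverscape study
#'
#' Bundles [generate_network], [generate_genotypes] and [generate_env] into
#' one reproducible study object with its full ground truth, emulating a
#' basin-wide survey: ~25 sites in ~13 catchments, a few thousand SNPs from
#' 6-18 individuals per site, divergence increasing with catchment
#' boundaries and barrier counts, and 40 collinear environmental covariates
#' in 5 categories. The fixed default `seed = 42` defines the package's
#' reference ("golden") study.
#'
#' @param n_sites,n_catchments,n_barriers network layout.
#' @param n_loci SNP count.
#' @param fst_model divergence model, see [generate_genotypes].
#' @param missing_rate genotype missingness.
#' @param noise_sd non-additive target noise.
#' @param seed master seed (sub-seeds are derived deterministically).
#' @return object of class `synthetic_study`.
#' @export
synthetic_study <- function(n_sites = 25, n_catchments = 13,
                            n_barriers = 15, n_loci = 3443,
                            fst_model = list(base = 0.03, catchment = 0.10,
                                             barrier = 0.04),
                            missing_rate = 0.05, noise_sd = 0, seed = 42L) {
  net <- generate_network(n_sites, n_catchments, n_barriers, seed = seed)
  gen <- generate_genotypes(net$network, fst_model = fst_model,
                            n_loci = n_loci, missing_rate = missing_rate,
                            noise_sd = noise_sd, seed = seed + 1L)
  env <- generate_env(net$sites, seed = seed + 2L)
  structure(list(edges = net$edges, sites = net$sites,
                 barriers = net$barriers, network = net$network,
                 env = env$env, categories = env$categories,
                 genotypes = gen$genotypes, truth = gen$truth,
                 seed = seed), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic riverscape study (seed %d): %d sites / %d ",
                     "catchments, %d barriers,\n  %d individuals x %d SNPs, ",
                     "%d environmental variables\n"),
              x$seed, nrow(x$sites), length(unique(x$sites$catchment_id)),
              if (is.null(x$barriers)) 0L else nrow(x$barriers),
              nrow(x$genotypes$G), ncol(x$genotypes$G),
              ncol(x$env) - 1L))
  invisible(x)
}
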