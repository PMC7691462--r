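## Independent oracles used across the suite. These deliberately re-derive
## quantities by direct enumeration / textbook formulas, not by calling the
## package's vectorized implementations.

## unique tree path between two nodes by depth-first search on a raw edge
## list (data.frame node_a, node_b, length_km); returns the edge row indices
oracle_tree_path <- function(edges, from, to) {
  if (from == to) return(integer(0))
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    adj[[a]] <- rbind(adj[[a]], c(i, b))
    adj[[b]] <- rbind(adj[[b]], c(i, a))
  }
  walk <- function(node, prev_edge, path) {
    if (node == to) return(path)
    nb <- adj[[node]]
    if (is.null(nb)) return(NULL)
    for (r in seq_len(nrow(nb))) {
      ei <- as.integer(nb[r, 1])
      if (!is.na(prev_edge) && ei == prev_edge) next
      res <- walk(nb[r, 2], ei, c(path, ei))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  walk(from, NA_integer_, integer(0))
}

oracle_tree_distance <- function(edges, from, to) {
  sum(edges$length_km[oracle_tree_path(edges, from, to)])
}

## textbook Weir & Cockerham (1984) theta: explicit per-locus loop over the
## a, b, c variance components, ratio of sums
oracle_wc_theta <- function(G, pops) {
  pop_ids <- unique(pops)
  A <- B <- C <- 0
  for (l in seq_len(ncol(G))) {
    n <- p <- h <- numeric(0)
    for (pp in pop_ids) {
      g <- G[pops == pp, l]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      n <- c(n, length(g))
      p <- c(p, sum(g) / (2 * length(g)))
      h <- c(h, mean(g == 1))
    }
    r <- length(n)
    if (r < 2) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nC <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nC) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

## exact HWE probabilities by direct enumeration of the conditional
## distribution of heterozygote counts
oracle_hwe_probs <- function(n_ind, n_rare) {
  hs <- seq(n_rare %% 2, n_rare, by = 2)
  pr <- sapply(hs, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n_ind - hom_r - h
    exp(lfactorial(n_ind) - lfactorial(hom_r) - lfactorial(h) -
          lfactorial(hom_c) + h * log(2))
  })
  names(pr) <- hs
  pr / sum(pr)
}

## a small fixed Y-shaped network: three 1-edge branches from a hub
make_y_network <- function(lengths = c(2, 3, 4), barriers = NULL) {
  edges <- data.frame(edge_id = c("e1", "e2", "e3"),
                      node_a = c("hub", "hub", "hub"),
                      node_b = c("tA", "tB", "tC"),
                      length_km = lengths)
  sites <- data.frame(site_id = c("A", "B", "C"),
                      catchment_id = c("c1", "c1", "c2"),
                      edge_id = c("e1", "e2", "e3"),
                      offset_km = lengths)
  build_network(edges, sites, barriers)
}

## random dendritic network with sites at every tip (full identifiability
## when barrier-free); returns generate_network-style list
random_tip_network <- function(n_sites, n_barriers = 0, seed = 1) {
  generate_network(n_sites = n_sites, n_catchments = max(2, n_sites %/% 3),
                   n_barriers = n_barriers, seed = seed)
}

## genotype matrix from per-site allele frequencies under HWE
sample_genotypes <- function(freqs_by_site, n_per_site) {
  G <- NULL; pops <- character(0)
  for (s in names(freqs_by_site)) {
    p <- freqs_by_site[[s]]
    n <- n_per_site[[s]]
    G <- rbind(G, matrix(stats::rbinom(n * length(p), 2, rep(p, each = n)),
                         n, length(p)))
    pops <- c(pops, rep(s, n))
  }
  genotypes(G, pops)
}
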