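#' Build a dendritic river network
#'
#' Constructs a validated `river_network` object from an edge list of stream
#' sections, a table of sampling sites and a table of in-stream barriers.
#' Sites and barriers are placed on edges by `(edge_id, offset_km)`; the
#' network is internally re-segmented so that every site and barrier becomes a
#' node, which makes every site-to-site path a unique, unambiguous sequence of
#' stream sections.
#'
#' The input graph must be a tree (connected and acyclic): dendritic river
#' networks have a unique path between any two points. Offsets are measured
#' from `node_a` along the edge. When a barrier sits at exactly the same
#' offset as a site, the barrier is placed on the `node_b` side of the site
#' (the `node_b` end of an edge is treated as downstream), so the barrier
#' separates the site from everything beyond it in that direction.
#'
#' @param edges data.frame with columns `edge_id`, `node_a`, `node_b`,
#'   `length_km` (non-negative).
#' @param sites data.frame with columns `site_id`, `catchment_id`, `edge_id`,
#'   `offset_km`.
#' @param barriers data.frame with columns `barrier_id`, `edge_id`,
#'   `offset_km`, or `NULL` for a barrier-free network.
#' @return An object of class `river_network`: a list with the re-segmented
#'   `sections` table, the `sites` and `barriers` tables (now carrying internal
#'   node ids), and the underlying `igraph` graph.
#' @examples
#' edges <- data.frame(edge_id = c("e1", "e2", "e3"),
#'                     node_a = c("n1", "n2", "n2"),
#'                     node_b = c("n2", "n3", "n4"),
#'                     length_km = c(2, 3, 4))
#' sites <- data.frame(site_id = c("A", "B", "C"),
#'                     catchment_id = c("c1", "c1", "c2"),
#'                     edge_id = c("e1", "e2", "e3"),
#'                     offset_km = c(0, 3, 4))
#' net <- build_network(edges, sites)
#' river_distance_matrix(net)
#' @export
build_network <- function(edges, sites, barriers = NULL) {
  edges <- as.data.frame(edges)
  sites <- as.data.frame(sites)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing columns: %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  req(edges, c("edge_id", "node_a", "node_b", "length_km"), "edge")
  req(sites, c("site_id", "catchment_id", "edge_id", "offset_km"), "site")
  if (is.null(barriers) || nrow(as.data.frame(barriers)) == 0L) {
    barriers <- data.frame(barrier_id = character(), edge_id = character(),
                           offset_km = numeric())
  } else {
    barriers <- as.data.frame(barriers)
    req(barriers, c("barrier_id", "edge_id", "offset_km"), "barrier")
  }
  edges$edge_id <- as.character(edges$edge_id)
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  sites$site_id <- as.character(sites$site_id)
  sites$edge_id <- as.character(sites$edge_id)
  barriers$barrier_id <- as.character(barriers$barrier_id)
  barriers$edge_id <- as.character(barriers$edge_id)

  if (anyDuplicated(edges$edge_id))
    stop("duplicate edge ids", call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("duplicate site ids", call. = FALSE)
  if (any(!is.finite(edges$length_km)) || any(edges$length_km < 0))
    stop("section lengths must be finite and non-negative", call. = FALSE)

  ## tree validation on the raw edge list
  g0 <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE)
  if (!igraph::is_connected(g0))
    stop("disconnected network", call. = FALSE)
  if (igraph::ecount(g0) != igraph::vcount(g0) - 1L)
    stop("not dendritic: edge list contains a cycle", call. = FALSE)

  check_placement <- function(df, what) {
    bad <- setdiff(df$edge_id, edges$edge_id)
    if (length(bad))
      stop(sprintf("%s placed on unknown edge(s): %s", what,
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
    len <- edges$length_km[match(df$edge_id, edges$edge_id)]
    out <- !is.finite(df$offset_km) | df$offset_km < 0 | df$offset_km > len
    if (any(out))
      stop(sprintf("%s offset out of [0, length_km] on edge(s): %s", what,
                   paste(unique(df$edge_id[out]), collapse = ", ")),
           call. = FALSE)
  }
  check_placement(sites, "site")
  check_placement(barriers, "barrier")

  ## re-segment: every site and barrier becomes an internal node.
  ## point ordering within an edge: offset, then sites before barriers
  ## (downstream = node_b tie-break), then id for determinism.
  pts <- rbind(
    if (nrow(sites)) data.frame(id = sites$site_id, edge_id = sites$edge_id,
                                offset = sites$offset_km, type = "site") else NULL,
    if (nrow(barriers)) data.frame(id = barriers$barrier_id,
                                   edge_id = barriers$edge_id,
                                   offset = barriers$offset_km,
                                   type = "barrier") else NULL)

  sec_from <- character(0); sec_to <- character(0)
  sec_len <- numeric(0); sec_edge <- character(0)
  node_of_point <- character(0)
  ord_edges <- edges[order(edges$edge_id), , drop = FALSE]
  for (k in seq_len(nrow(ord_edges))) {
    e <- ord_edges[k, ]
    p <- pts[!is.na(pts$edge_id) & pts$edge_id == e$edge_id, , drop = FALSE]
    if (nrow(p)) {
      p <- p[order(p$offset, p$type == "barrier", p$id), , drop = FALSE]
      ## sites at an edge end reuse the terminal node (no zero-length stub);
      ## sites sharing an exact interior position share one node; barriers
      ## always get their own node so they split the edge wherever they sit
      node_ids <- character(nrow(p))
      interior <- logical(nrow(p))
      for (i in seq_len(nrow(p))) {
        if (p$type[i] == "site" && p$offset[i] == 0) {
          node_ids[i] <- e$node_a
        } else if (p$type[i] == "site" && p$offset[i] == e$length_km) {
          node_ids[i] <- e$node_b
        } else if (p$type[i] == "site" && i > 1L &&
                   p$type[i - 1L] == "site" &&
                   p$offset[i] == p$offset[i - 1L]) {
          node_ids[i] <- node_ids[i - 1L]
          interior[i] <- FALSE
        } else {
          node_ids[i] <- paste0(".pt:", p$id[i])
          interior[i] <- TRUE
        }
      }
      node_of_point[p$id] <- node_ids
      new_pt <- interior & !duplicated(node_ids)
      chain_nodes <- c(e$node_a, node_ids[new_pt], e$node_b)
      chain_off <- c(0, p$offset[new_pt], e$length_km)
    } else {
      chain_nodes <- c(e$node_a, e$node_b)
      chain_off <- c(0, e$length_km)
    }
    n_seg <- length(chain_nodes) - 1L
    sec_from <- c(sec_from, chain_nodes[-length(chain_nodes)])
    sec_to <- c(sec_to, chain_nodes[-1L])
    sec_len <- c(sec_len, diff(chain_off))
    sec_edge <- c(sec_edge, rep(e$edge_id, n_seg))
  }
  ## stable deterministic ids: number sections within each original edge,
  ## in offset order (edges themselves processed in sorted id order)
  idx <- stats::ave(seq_along(sec_edge), sec_edge, FUN = seq_along)
  sections <- data.frame(
    section_id = paste0(sec_edge, ".", idx),
    node_from = sec_from, node_to = sec_to,
    length_km = sec_len, edge_id = sec_edge,
    stringsAsFactors = FALSE)

  sites$node <- unname(node_of_point[sites$site_id])
  barriers$node <- if (nrow(barriers)) unname(node_of_point[barriers$barrier_id]) else character(0)

  g <- igraph::graph_from_data_frame(
    data.frame(from = sections$node_from, to = sections$node_to,
               weight = sections$length_km,
               section_id = sections$section_id),
    directed = FALSE)
  barrier_nodes <- unique(barriers$node)

  structure(list(graph = g, sections = sections, sites = sites,
                 barriers = barriers, barrier_nodes = barrier_nodes,
                 edges = edges),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("Dendritic river network\n")
  cat(sprintf("  %d sections (%.1f km total), %d sites in %d catchments, %d barriers\n",
              nrow(x$sections), sum(x$sections$length_km),
              nrow(x$sites), length(unique(x$sites$catchment_id)),
              nrow(x$barriers)))
  invisible(x)
}

site_nodes <- function(net, site_ids = NULL) {
  if (is.null(site_ids)) site_ids <- net$sites$site_id
  m <- match(site_ids, net$sites$site_id)
  if (anyNA(m))
    stop(sprintf("unknown site(s): %s",
                 paste(site_ids[is.na(m)], collapse = ", ")), call. = FALSE)
  stats::setNames(net$sites$node[m], site_ids)
}

label_matrix <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  m
}

#' Pairwise river distances between sampling sites
#'
#' Entry (i, j) is the total length (km) of the unique path through the
#' network between sites i and j.
#'
#' @param net a `river_network`.
#' @param site_ids sites to include (default: all, in table order).
#' @return symmetric numeric matrix (km) with zero diagonal.
#' @export
river_distance_matrix <- function(net, site_ids = NULL) {
  nodes <- site_nodes(net, site_ids)
  d <- igraph::distances(net$graph, v = nodes, to = nodes,
                         weights = igraph::E(net$graph)$weight)
  label_matrix(unname(d), names(nodes))
}

#' Pairwise in-stream barrier counts between sampling sites
#'
#' Entry (i, j) is the number of barriers lying on the unique path between
#' sites i and j. Counts are undirected: a barrier is counted regardless of
#' travel direction.
#'
#' @inheritParams river_distance_matrix
#' @return symmetric integer matrix with zero diagonal.
#' @export
barrier_count_matrix <- function(net, site_ids = NULL) {
  nodes <- site_nodes(net, site_ids)
  ## each section is weighted by half a barrier per barrier endpoint, so a
  ## path through a barrier node (degree-2 in the re-segmented tree)
  ## accumulates exactly 1; path endpoints are site nodes, never barriers.
  ends <- igraph::ends(net$graph, igraph::E(net$graph))
  w <- 0.5 * (ends[, 1] %in% net$barrier_nodes) +
       0.5 * (ends[, 2] %in% net$barrier_nodes)
  d <- igraph::distances(net$graph, v = nodes, to = nodes, weights = w)
  m <- round(unname(d))
  storage.mode(m) <- "integer"
  label_matrix(m, names(nodes))
}

#' Catchment-membership model matrix
#'
#' Binary model matrix for stream hierarchy: 0 for pairs of sites in the same
#' catchment, 1 for pairs in different catchments, 0 on the diagonal.
#'
#' @param sites data.frame with `site_id` and `catchment_id` (a
#'   `river_network`'s `sites` table works directly).
#' @return symmetric 0/1 matrix.
#' @export
catchment_model_matrix <- function(sites) {
  if (inherits(sites, "river_network")) sites <- sites$sites
  if (any(is.na(sites$catchment_id)))
    stop("missing catchment_id", call. = FALSE)
  cm <- outer(sites$catchment_id, sites$catchment_id, "!=") * 1L
  diag(cm) <- 0L
  label_matrix(cm, sites$site_id)
}

#' Ordered stream sections on the path between two sites
#'
#' @param net a `river_network`.
#' @param site_i,site_j site ids.
#' @return character vector of section ids along the unique path (empty when
#'   `site_i == site_j`).
#' @export
path_sections <- function(net, site_i, site_j) {
  nodes <- site_nodes(net, c(site_i, site_j))
  if (nodes[1] == nodes[2]) return(character(0))
  p <- igraph::shortest_paths(net$graph, from = nodes[1], to = nodes[2],
                              weights = igraph::E(net$graph)$weight,
                              output = "epath")$epath[[1]]
  igraph::edge_attr(net$graph, "section_id", p)
}

#' @export
plot.river_network <- function(x, ...) {
  lay <- igraph::layout_as_tree(x$graph)
  vn <- igraph::V(x$graph)$name
  col <- ifelse(vn %in% x$sites$node, "dodgerblue3",
                ifelse(vn %in% x$barrier_nodes, "firebrick", "grey60"))
  igraph::plot.igraph(x$graph, layout = lay, vertex.size = 6,
                      vertex.color = col, vertex.label = NA,
                      edge.width = 2, ...)
  invisible(x)
}
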