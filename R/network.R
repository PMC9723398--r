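# Network construction from differentially phosphorylated proteins,
# evidence-channel edge filtering, the ten-centrality battery, and
# above-mean-betweenness hub selection.

#' Filter interaction edges by evidence-channel scores
#'
#' An edge is retained when its `experiments` evidence score is present
#' and at least `experiments_min`, or its `databases` score is present and
#' at least `databases_min` (inclusive bounds, disjunctive channels) —
#' the usual filtering applied to STRING-style evidence exports.
#'
#' @param edges Edge table with columns `node_a`, `node_b`,
#'   `score_experiments`, `score_databases` (scores in \[0, 1\] or `NA`).
#' @param experiments_min,databases_min Channel thresholds in \[0, 1\].
#' @return The retained rows of `edges`.
#' @export
filter_edges <- function(edges, experiments_min = 0.15,
                         databases_min = 0.35) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b") %in% names(edges)))
  for (th in c(experiments_min, databases_min)) {
    if (!is.numeric(th) || th < 0 || th > 1) {
      stop_("channel thresholds must lie in [0, 1]")
    }
  }
  se <- if ("score_experiments" %in% names(edges)) edges$score_experiments
        else rep(NA_real_, nrow(edges))
  sd_ <- if ("score_databases" %in% names(edges)) edges$score_databases
         else rep(NA_real_, nrow(edges))
  for (s in list(se, sd_)) {
    if (any(!is.na(s) & (s < 0 | s > 1))) {
      stop_("evidence scores must lie in [0, 1]")
    }
  }
  keep <- (!is.na(se) & se >= experiments_min) |
          (!is.na(sd_) & sd_ >= databases_min)
  tibble::as_tibble(edges[keep, , drop = FALSE])
}

#' Build a network model on differentially phosphorylated proteins
#'
#' Induces the network on the supplied protein list: edges with both
#' endpoints in `dpps` are kept (or, with `keep_interactors = TRUE`, edges
#' with at least one endpoint, extending the node set by the interactors),
#' self-loops are rejected, duplicate edges collapsed, and proteins
#' without any surviving edge are retained as isolated nodes. In
#' `ppi_undirected` mode all edges are undirected; in `signaling_mixed`
#' mode `activation`/`inhibition` edges are directed from `node_a` to
#' `node_b` while `docking` (or unannotated) edges are undirected — edge
#' signs carry semantics but do not alter topology.
#'
#' @param dpps Non-empty character vector of protein identifiers.
#' @param edges Edge table (e.g. from [filter_edges()]) with `node_a`,
#'   `node_b` and, in signaling mode, a `relation` column.
#' @param mode `"ppi_undirected"` or `"signaling_mixed"`.
#' @param node_annotations Optional data frame with columns `node` and
#'   annotation columns (e.g. fold-change direction) carried onto nodes.
#' @param keep_interactors Keep non-DPP interactors as nodes?
#' @return A `phos_network` object: list with `nodes` (tibble), `edges`
#'   (tibble `from`, `to`, `relation`) and `mode`.
#' @export
build_network <- function(dpps, edges,
                          mode = c("ppi_undirected", "signaling_mixed"),
                          node_annotations = NULL,
                          keep_interactors = FALSE) {
  mode <- match.arg(mode)
  if (length(dpps) == 0L) stop_("'dpps' must be a non-empty protein list")
  dpps <- unique(as.character(dpps))
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b") %in% names(edges)))
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  rel <- if ("relation" %in% names(edges)) as.character(edges$relation)
         else rep("", nrow(edges))
  rel[is.na(rel)] <- ""
  if (mode == "ppi_undirected") rel <- rep("", length(rel))
  keep <- a != b & if (keep_interactors) (a %in% dpps | b %in% dpps)
                   else (a %in% dpps & b %in% dpps)
  a <- a[keep]; b <- b[keep]; rel <- rel[keep]
  directed <- rel %in% c("activation", "inhibition")
  key <- ifelse(directed, paste(a, b, rel, sep = ">"),
                paste(pmin(a, b), pmax(a, b), rel, sep = "~"))
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]; rel <- rel[!dup]
  nodes <- union(dpps, c(a, b))
  node_tab <- tibble::tibble(node = nodes, is_dpp = nodes %in% dpps)
  if (!is.null(node_annotations)) {
    stopifnot(is.data.frame(node_annotations),
              "node" %in% names(node_annotations))
    idx <- match(node_tab$node, node_annotations$node)
    for (cl in setdiff(names(node_annotations), "node")) {
      node_tab[[cl]] <- node_annotations[[cl]][idx]
    }
  }
  if (length(a) == 0L) {
    warning("no edges survive among the supplied proteins; ",
            "the network is edgeless", call. = FALSE)
  }
  structure(list(nodes = node_tab,
                 edges = tibble::tibble(from = a, to = b, relation = rel),
                 mode = mode),
            class = "phos_network")
}

#' @export
print.phos_network <- function(x, ...) {
  cat(sprintf("<phos_network> mode=%s, %d nodes, %d edges\n",
              x$mode, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a network model to an igraph graph
#'
#' In signaling mode the graph is directed, with docking/unannotated edges
#' expanded into reciprocal arcs; in PPI mode it is undirected.
#'
#' @param network A `phos_network`.
#' @return An igraph graph with a `relation` edge attribute.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "phos_network"))
  directed <- network$mode == "signaling_mixed"
  e <- network$edges
  if (directed) {
    undir <- !(e$relation %in% c("activation", "inhibition"))
    e <- rbind(e, data.frame(from = e$to[undir], to = e$from[undir],
                             relation = e$relation[undir]))
  }
  igraph::graph_from_data_frame(e, directed = directed,
                                vertices = network$nodes)
}

# integer arc list (from, to) with both directions for undirected edges
network_arcs <- function(network) {
  nodes <- network$nodes$node
  e <- network$edges
  from <- match(e$from, nodes)
  to <- match(e$to, nodes)
  directed <- network$mode == "signaling_mixed" &
    e$relation %in% c("activation", "inhibition")
  list(n = length(nodes), nodes = nodes,
       from = c(from, to[!directed]), to = c(to, from[!directed]),
       directed = directed)
}

arcs_to_adj <- function(arcs) {
  adj <- vector("list", arcs$n)
  for (v in seq_len(arcs$n)) adj[[v]] <- integer(0)
  if (length(arcs$from) > 0L) {
    sp <- split(arcs$to, arcs$from)
    for (nm in names(sp)) adj[[as.integer(nm)]] <- unique(sp[[nm]])
  }
  adj
}

# BFS from s: geodesic distances and shortest-path counts to every node
bfs_paths <- function(adj, s, n) {
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  d <- 0L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- d + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == d + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
    d <- d + 1L
  }
  dist_num <- as.numeric(dist)
  dist_num[is.na(dist_num)] <- Inf
  list(dist = dist_num, sigma = sigma)
}

# all-pairs geodesic census: D[s,t] distances, S[s,t] shortest-path counts
path_census <- function(adj, n) {
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    b <- bfs_paths(adj, s, n)
    D[s, ] <- b$dist
    S[s, ] <- b$sigma
  }
  list(D = D, S = S)
}

# betweenness (ordered pairs, unnormalized) and stress from a census:
# a node v lies on an s-t geodesic iff d(s,v) + d(v,t) = d(s,t), and then
# sigma_st(v) = sigma_sv * sigma_vt
betweenness_stress <- function(census) {
  D <- census$D
  S <- census$S
  n <- nrow(D)
  btw <- numeric(n)
  str <- numeric(n)
  finite <- is.finite(D)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], "+") == D
    on_path[!finite] <- FALSE
    on_path[v, ] <- FALSE
    on_path[, v] <- FALSE
    diag(on_path) <- FALSE
    if (!any(on_path)) next
    w <- outer(S[, v], S[v, ])
    str[v] <- sum(w[on_path])
    btw[v] <- sum(w[on_path] / S[on_path])
  }
  list(betweenness = btw, stress = str)
}

# fast path used by the null model: betweenness only
betweenness_only <- function(adj, n) {
  betweenness_stress(path_census(adj, n))$betweenness
}

#' Compute the ten-centrality battery of a network
#'
#' Per node v over geodesics (unweighted shortest paths; in signaling
#' mode directed edges are traversed only along their direction, docking
#' edges both ways; sums run over reachable nodes only):
#' \describe{
#'   \item{betweenness}{sum over ordered pairs (s, t), s != t != v, of the
#'     fraction of shortest s-t paths through v (unnormalized).}
#'   \item{stress}{absolute number of shortest paths through v.}
#'   \item{closeness}{reciprocal of the total geodesic distance from v to
#'     its reachable nodes (0 for isolated nodes).}
#'   \item{eccentricity}{reciprocal of the largest finite geodesic
#'     distance from v.}
#'   \item{radiality}{sum over reachable t of (diameter + 1 - d(v, t)),
#'     divided by (component size - 1); the diameter is the component's.}
#'   \item{centroid}{min over other nodes w of gamma_v(w) - gamma_w(v),
#'     where gamma_v(w) counts nodes strictly closer to v than to w.}
#'   \item{eigenvector}{principal eigenvector of the underlying undirected
#'     adjacency, scaled to unit maximum.}
#'   \item{bridging}{betweenness times the bridging coefficient
#'     (1/deg(v)) / sum over neighbors i of 1/deg(i).}
#'   \item{in_degree, out_degree}{arc counts (equal to the degree in
#'     undirected mode; docking edges count toward both).}
#' }
#'
#' @param network A `phos_network` with at least one node.
#' @return A tibble with one row per node, the ten centralities, and a
#'   `hub` flag (betweenness strictly above the network mean, see
#'   [select_hubs()]).
#' @export
compute_centralities <- function(network) {
  stopifnot(inherits(network, "phos_network"))
  arcs <- network_arcs(network)
  n <- arcs$n
  if (n == 0L) stop_("network has no nodes")
  adj <- arcs_to_adj(arcs)
  census <- path_census(adj, n)
  D <- census$D
  bs <- betweenness_stress(census)

  finite_off <- is.finite(D) & D > 0
  reach_sum <- rowSums(ifelse(finite_off, D, 0))
  n_reach <- rowSums(finite_off)
  closeness <- ifelse(reach_sum > 0, 1 / reach_sum, 0)
  ecc_raw <- apply(D, 1, function(r) {
    f <- r[is.finite(r) & r > 0]
    if (length(f) == 0L) 0 else max(f)
  })
  eccentricity <- ifelse(ecc_raw > 0, 1 / ecc_raw, 0)

  # components of the underlying undirected graph, for radiality
  comp <- undirected_components(arcs)
  radiality <- numeric(n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) < 2L) next
    Dc <- D[members, members, drop = FALSE]
    fin <- is.finite(Dc) & Dc > 0
    diam <- max(Dc[is.finite(Dc)])
    for (i in seq_along(members)) {
      f <- fin[i, ]
      radiality[members[i]] <-
        sum(diam + 1 - Dc[i, f]) / (length(members) - 1)
    }
  }

  centroid <- numeric(n)
  if (n >= 2L) {
    for (v in seq_len(n)) {
      others <- setdiff(seq_len(n), v)
      gamma_vw <- vapply(others, function(w) {
        sum(D[v, ] < D[w, ]) - sum(D[v, w] < D[w, w])
      }, numeric(1))
      gamma_wv <- vapply(others, function(w) {
        sum(D[w, ] < D[v, ]) - sum(D[w, v] < D[v, v])
      }, numeric(1))
      centroid[v] <- min(gamma_vw - gamma_wv)
    }
  }

  A <- matrix(0, n, n)
  if (length(arcs$from) > 0L) {
    A[cbind(arcs$from, arcs$to)] <- 1
  }
  A_sym <- pmax(A, t(A))
  eig <- rep(0, n)
  if (any(A_sym > 0)) {
    ev <- eigen(A_sym, symmetric = TRUE)
    v1 <- abs(ev$vectors[, 1])
    if (max(v1) > 0) eig <- v1 / max(v1)
  }

  deg_sym <- rowSums(A_sym)
  bridging_coef <- vapply(seq_len(n), function(v) {
    if (deg_sym[v] == 0) return(0)
    nb <- which(A_sym[v, ] > 0)
    (1 / deg_sym[v]) / sum(1 / deg_sym[nb])
  }, numeric(1))

  out_degree <- as.integer(rowSums(A))
  in_degree <- as.integer(colSums(A))

  prof <- tibble::tibble(node = arcs$nodes,
                         betweenness = bs$betweenness,
                         bridging = bs$betweenness * bridging_coef,
                         centroid = centroid,
                         closeness = closeness,
                         eccentricity = eccentricity,
                         eigenvector = eig,
                         radiality = radiality,
                         stress = bs$stress,
                         in_degree = in_degree,
                         out_degree = out_degree)
  prof$hub <- prof$betweenness > mean(prof$betweenness)
  prof
}

undirected_components <- function(arcs) {
  n <- arcs$n
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(arcs$from)) {
    a <- find(arcs$from[i])
    b <- find(arcs$to[i])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Select hub nodes by above-mean betweenness
#'
#' Hubs are the nodes whose betweenness strictly exceeds the arithmetic
#' mean betweenness over all nodes of the network; when all values are
#' equal no node is a hub. The rule is invariant under uniform scaling of
#' the betweenness values.
#'
#' @param profiles Centrality table from [compute_centralities()] (any
#'   data frame with `node` and `betweenness` columns).
#' @return Character vector of hub node identifiers.
#' @export
select_hubs <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L,
            all(c("node", "betweenness") %in% names(profiles)))
  profiles$node[profiles$betweenness > mean(profiles$betweenness)]
}

#' Write a network as a SIF interaction file
#'
#' @param network A `phos_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "phos_network"))
  e <- network$edges
  rel <- ifelse(nzchar(e$relation), e$relation, "pp")
  lines <- sprintf("%s\t%s\t%s", e$from, rel, e$to)
  isolated <- setdiff(network$nodes$node, c(e$from, e$to))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param network A `phos_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
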