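# Shared fixtures and independent oracles for the test suite.

# independent brute-force oracle: enumerate every shortest path with
# igraph::all_shortest_paths and tally pass-throughs per interior vertex
# (ordered source/target pairs, unnormalized)
brute_betweenness_stress <- function(g) {
  n <- igraph::vcount(g)
  btw <- numeric(n)
  str <- numeric(n)
  for (s in seq_len(n)) {
    res <- igraph::all_shortest_paths(g, from = s, mode = "out")$res
    ends <- vapply(res, function(p) as.integer(p[length(p)]), integer(1))
    for (t in unique(ends)) {
      if (t == s) next
      paths <- res[ends == t]
      sigma <- length(paths)
      for (p in paths) {
        inner <- as.integer(p)
        inner <- inner[-c(1, length(inner))]
        if (length(inner) > 0L) {
          str[inner] <- str[inner] + 1
          btw[inner] <- btw[inner] + 1 / sigma
        }
      }
    }
  }
  list(betweenness = btw, stress = str)
}

# build a phos_network from an integer edge list on n nodes
net_from_edgelist <- function(el, n, mode = "ppi_undirected",
                              relation = NULL) {
  nodes <- sprintf("V%02d", seq_len(n))
  edges <- tibble::tibble(
    node_a = nodes[el[, 1]], node_b = nodes[el[, 2]],
    relation = relation %||% rep("", nrow(el)))
  suppressWarnings(build_network(nodes, edges, mode = mode))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# iterate over every connected labeled graph on n nodes, calling
# fn(edge_list_matrix); masks selects a subset of edge-set bitmasks
for_each_connected_graph <- function(n, fn, masks = NULL) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  bits <- 2 ^ (0:(m - 1))
  if (is.null(masks)) masks <- seq_len(2 ^ m - 1)
  count <- 0L
  for (mask in masks) {
    sel <- which(bitwAnd(mask, bits) > 0)
    el <- pairs[sel, , drop = FALSE]
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (i in seq_len(nrow(el))) {
      a <- find(el[i, 1])
      b <- find(el[i, 2])
      if (a != b) parent[a] <- b
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) > 1L) next
    count <- count + 1L
    fn(el)
  }
  count
}

# adjacency list of an undirected integer edge list
adj_from_edgelist <- function(el, n) {
  lapply(seq_len(n), function(v) {
    c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
  })
}

# two-community network joined only through one connector node; the
# connector carries all inter-community shortest paths
planted_connector_network <- function(community_size = 10L, p = 0.6,
                                      n_attach = 2L, seed = 1L,
                                      signaling = FALSE) {
  simulate_network(n_nodes = 2L * community_size + 1L,
                   model = "erdos_renyi", model_params = list(p = p),
                   n_planted_connectors = 1L, n_attach = n_attach,
                   signaling = signaling, seed = seed)
}

# hand-built table matching the documented TSV dialect
tiny_phospho_table <- function(ratios, condition = "T3") {
  n <- nrow(ratios)
  tab <- tibble::tibble(
    site_id = sprintf("s%02d", seq_len(n)),
    protein_id = sprintf("P%02d", seq_len(n)),
    amino_acid = rep("S", n),
    position = seq_len(n) + 10L,
    sequence_window = rep("GGGGGGSGGGGGG", n))
  for (k in seq_len(ncol(ratios))) {
    tab[[sprintf("ratio_%s_rep%d", condition, k)]] <- ratios[, k]
  }
  tab
}
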