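# Degree-preserving network randomization and empirical null statistics
# for the topology results.

# double-edge swaps within one edge pool; ep is a 2-column integer-free
# character matrix of endpoints. directed = FALSE swaps undirected edges
# (a-b, c-d -> a-d, c-b), directed = TRUE swaps arc heads (a->b, c->d ->
# a->d, c->b), preserving out- and in-degree sequences. Moves creating
# self-loops or multi-edges (within the pool) are rejected.
swap_pool <- function(ep, n_swaps, directed) {
  m <- nrow(ep)
  if (m < 2L) return(ep)
  key <- function(a, b) {
    if (directed) paste(a, b, sep = ">")
    else paste(pmin(a, b), pmax(a, b), sep = "~")
  }
  keys <- key(ep[, 1], ep[, 2])
  for (it in seq_len(n_swaps)) {
    ij <- sample.int(m, 2L)
    i <- ij[1]; j <- ij[2]
    a <- ep[i, 1]; b <- ep[i, 2]
    c_ <- ep[j, 1]; d <- ep[j, 2]
    if (!directed && runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    # proposed: (a, d) and (c_, b)
    if (a == d || c_ == b) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (k1 == k2 || k1 %in% keys || k2 %in% keys) next
    ep[i, 2] <- d
    ep[j, 1] <- c_
    ep[j, 2] <- b
    keys[i] <- k1
    keys[j] <- k2
  }
  ep
}

#' Degree-preserving rewiring of a network
#'
#' Randomizes a network by attempted double-edge swaps that exactly
#' conserve every node's degree (out- and in-degree sequences in directed
#' mode), rejecting moves that would create self-loops or duplicate
#' edges. In `signaling_mixed` mode the directed
#' (activation/inhibition) and undirected (docking) edge pools are
#' rewired separately, so each pool's degree sequence is conserved.
#' Networks too small to rewire (fewer than 2 edges in every pool) are
#' returned unchanged with attribute `rewire_warning` set.
#'
#' @param network A `phos_network`.
#' @param n_swaps Attempted swaps (default 10 times the edge count).
#' @param seed Optional integer seed.
#' @return A rewired `phos_network` with the same nodes and mode.
#' @export
rewire_network <- function(network, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(network, "phos_network"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  e <- network$edges
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(e)
  directed <- network$mode == "signaling_mixed" &
    e$relation %in% c("activation", "inhibition")
  if (nrow(e) < 2L || (sum(directed) < 2L && sum(!directed) < 2L)) {
    warning("network too small to rewire; returning the input",
            call. = FALSE)
    attr(network, "rewire_warning") <- TRUE
    return(network)
  }
  out <- e
  for (pool in c(FALSE, TRUE)) {
    idx <- which(directed == pool)
    if (length(idx) < 2L) next
    ep <- cbind(e$from[idx], e$to[idx])
    swaps <- max(1L, round(n_swaps * length(idx) / nrow(e)))
    ep <- swap_pool(ep, swaps, directed = pool)
    out$from[idx] <- ep[, 1]
    out$to[idx] <- ep[, 2]
  }
  network$edges <- out
  network
}

#' Null distribution of betweenness from randomized networks
#'
#' Generates `n_random` independent degree-preserving rewirings of the
#' observed network (each starting from the original), recomputes
#' betweenness on every replicate, and summarizes: per node, the null
#' mean and standard deviation of its betweenness and the add-one
#' empirical p-value `(1 + #\{replicates >= observed\}) / (n_random + 1)`
#' (necessarily > 0); per replicate, the network's mean betweenness, as a
#' long violin-plot-ready table.
#'
#' @param network A `phos_network`.
#' @param n_random Number of randomized replicates (>= 1).
#' @param n_swaps Attempted swaps per replicate (default 10 x edges).
#' @param seed Optional integer seed for the whole run.
#' @return A list with `nodes` (tibble: `node`, `observed`, `null_mean`,
#'   `null_sd`, `empirical_p`), `replicates` (tibble: `replicate`,
#'   `statistic`, `value`) and `n_random`.
#' @export
null_distribution <- function(network, n_random = 1000L, n_swaps = NULL,
                              seed = NULL) {
  stopifnot(inherits(network, "phos_network"))
  if (!is.numeric(n_random) || n_random < 1) stop_("'n_random' must be >= 1")
  n_random <- as.integer(n_random)
  if (!is.null(seed)) set.seed(as.integer(seed))
  arcs <- network_arcs(network)
  observed <- betweenness_only(arcs_to_adj(arcs), arcs$n)
  null_mat <- matrix(NA_real_, nrow = arcs$n, ncol = n_random)
  for (r in seq_len(n_random)) {
    rnet <- rewire_network(network, n_swaps = n_swaps)
    rarcs <- network_arcs(rnet)
    null_mat[, r] <- betweenness_only(arcs_to_adj(rarcs), rarcs$n)
  }
  ge <- rowSums(null_mat >= observed)
  nodes <- tibble::tibble(node = arcs$nodes, observed = observed,
                          null_mean = rowMeans(null_mat),
                          null_sd = apply(null_mat, 1, sd),
                          empirical_p = (1 + ge) / (n_random + 1))
  replicates <- tibble::tibble(replicate = seq_len(n_random),
                               statistic = "mean_betweenness",
                               value = colMeans(null_mat))
  list(nodes = nodes, replicates = replicates, n_random = n_random)
}
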