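# Synthetic phosphosite tables and interaction networks with recorded
# ground truth, so every downstream stage can be benchmarked without any
# external download.

#' Configuration for the synthetic phosphosite generator
#'
#' Describes a SILAC-style phosphoproteomic experiment: `n_sites`
#' phosphosites on `n_proteins` proteins, quantified as treatment/reference
#' ratios in `n_replicates` biological replicates per condition. A fraction
#' `frac_up` of sites is planted up-regulated at true ratio
#' `true_up_ratio`, `frac_down` down-regulated at `true_down_ratio`, the
#' rest centered on ratio 1. Replicate ratios carry lognormal
#' multiplicative noise (normal with standard deviation `noise_sigma` on
#' the log2 scale) and are missing completely at random with probability
#' `missing_rate`. When a `motif_library` is supplied, a fraction
#' `frac_motif_planted` of the regulated sites receives a sequence window
#' embedding one of the library's kinase motifs.
#'
#' @param n_sites,n_proteins,n_replicates Positive integer counts.
#' @param conditions Character vector of condition labels; each condition
#'   gets its own replicate ratio columns, with the same planted effect and
#'   independent noise.
#' @param frac_up,frac_down Fractions in \[0, 1\] with sum at most 1.
#' @param true_up_ratio Planted ratio for up-regulated sites (> 1).
#' @param true_down_ratio Planted ratio for down-regulated sites (in (0, 1)).
#' @param noise_sigma Standard deviation of the log2-scale noise (>= 0).
#' @param missing_rate Per-replicate missingness probability in \[0, 1\].
#' @param motif_library Optional `motif_library` for motif planting.
#' @param frac_motif_planted Fraction of regulated sites whose window
#'   embeds a planted motif (requires `motif_library`).
#' @param seed Integer random seed.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_sites = 1000L, n_proteins = 300L,
                              n_replicates = 3L, conditions = "T3",
                              frac_up = 0.1, frac_down = 0.1,
                              true_up_ratio = 2, true_down_ratio = 0.5,
                              noise_sigma = 0.25, missing_rate = 0.05,
                              motif_library = NULL,
                              frac_motif_planted = 0, seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != floor(x)) {
      stop_("'%s' must be a positive integer", nm)
    }
  }
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop_("'%s' must be a fraction in [0, 1]", nm)
    }
  }
  chk_count(n_sites, "n_sites")
  chk_count(n_proteins, "n_proteins")
  chk_count(n_replicates, "n_replicates")
  if (!is.character(conditions) || length(conditions) < 1L ||
      anyDuplicated(conditions)) {
    stop_("'conditions' must be distinct condition labels")
  }
  chk_frac(frac_up, "frac_up")
  chk_frac(frac_down, "frac_down")
  if (frac_up + frac_down > 1) {
    stop_("'frac_up' + 'frac_down' must not exceed 1")
  }
  if (!is.numeric(true_up_ratio) || true_up_ratio <= 1) {
    stop_("'true_up_ratio' must be > 1")
  }
  if (!is.numeric(true_down_ratio) || true_down_ratio <= 0 ||
      true_down_ratio >= 1) {
    stop_("'true_down_ratio' must lie in (0, 1)")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop_("'noise_sigma' must be >= 0")
  }
  chk_frac(missing_rate, "missing_rate")
  chk_frac(frac_motif_planted, "frac_motif_planted")
  if (frac_motif_planted > 0 && is.null(motif_library)) {
    stop_("'motif_library' is required when 'frac_motif_planted' > 0")
  }
  if (!is.null(motif_library) && !inherits(motif_library, "motif_library")) {
    stop_("'motif_library' must be a motif_library")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_("'seed' must be a single integer")
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_proteins = as.integer(n_proteins),
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions,
                 frac_up = frac_up, frac_down = frac_down,
                 true_up_ratio = true_up_ratio,
                 true_down_ratio = true_down_ratio,
                 noise_sigma = noise_sigma, missing_rate = missing_rate,
                 motif_library = motif_library,
                 frac_motif_planted = frac_motif_planted,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a phosphosite quantification table with ground truth
#'
#' Generates a site-level table in the package's TSV dialect: identity
#' columns (`site_id`, `protein_id`, `amino_acid`, `position`,
#' `sequence_window`) followed by `ratio_<condition>_rep<k>` columns of
#' per-replicate treatment/reference SILAC ratios. Regulated sites have
#' replicate ratios `true ratio * 2^N(0, noise_sigma)`, unchanged sites
#' center on 1, and replicates are dropped independently with probability
#' `missing_rate`. Planted motif windows are constructed to match only
#' their planted motif within the supplied library (ambiguous draws are
#' rejected and resampled), so noiseless motif counts recover the planted
#' truth exactly. The same seed always reproduces the identical table.
#'
#' @param config A [simulation_config()].
#' @return A list with `table` (tibble of phosphosite records) and `truth`
#'   (tibble with `site_id`, `protein_id`, `true_label`, `planted_kinase`).
#' @export
simulate_phosphosites <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_("'config' must be a simulation_config")
  }
  set.seed(config$seed)
  n <- config$n_sites
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  label <- sample(rep(c("up", "down", "unchanged"),
                      c(n_up, n_down, n - n_up - n_down)))
  protein_id <- sprintf("PROT%05d",
                        sample.int(config$n_proteins, n, replace = TRUE))
  amino_acid <- sample(c("S", "T", "Y"), n, replace = TRUE,
                       prob = c(0.75, 0.20, 0.05))
  position <- sample.int(800L, n, replace = TRUE) + 6L
  sequence_window <- vapply(amino_acid, random_window, character(1),
                            USE.NAMES = FALSE)

  planted <- rep(NA_character_, n)
  reg_idx <- which(label != "unchanged")
  if (config$frac_motif_planted > 0 && length(reg_idx) > 0L) {
    lib <- config$motif_library
    n_plant <- round(config$frac_motif_planted * length(reg_idx))
    plant_idx <- reg_idx[seq_len(n_plant)]
    which_motif <- sample.int(length(lib), n_plant, replace = TRUE)
    for (j in seq_along(plant_idx)) {
      m <- lib[[which_motif[j]]]
      w <- plant_motif_window(m, lib)
      i <- plant_idx[j]
      sequence_window[i] <- w$window
      amino_acid[i] <- w$center
      planted[i] <- m$kinase
    }
  }

  true_ratio <- c(up = config$true_up_ratio, down = config$true_down_ratio,
                  unchanged = 1)[label]
  tab <- tibble::tibble(site_id = sprintf("site%05d", seq_len(n)),
                        protein_id = protein_id, amino_acid = amino_acid,
                        position = position,
                        sequence_window = sequence_window)
  for (cond in config$conditions) {
    for (k in seq_len(config$n_replicates)) {
      vals <- true_ratio * 2 ^ rnorm(n, 0, config$noise_sigma)
      if (config$missing_rate > 0) {
        vals[runif(n) < config$missing_rate] <- NA_real_
      }
      tab[[sprintf("ratio_%s_rep%d", cond, k)]] <- vals
    }
  }
  truth <- tibble::tibble(site_id = tab$site_id, protein_id = protein_id,
                          true_label = label, planted_kinase = planted)
  list(table = tab, truth = truth)
}

random_window <- function(center) {
  w <- sample(AA20, WINDOW_WIDTH, replace = TRUE)
  w[WINDOW_CENTER] <- center
  paste(w, collapse = "")
}

# Build a window matching `motif` and no other library motif; wildcard
# positions are resampled on ambiguity. Structurally nested motif pairs
# cannot be disambiguated and fall through after max_tries.
plant_motif_window <- function(motif, lib, max_tries = 200L) {
  center <- if (length(motif$center_residues) == 1L) motif$center_residues
            else sample(motif$center_residues, 1L)
  win <- NULL
  for (try in seq_len(max_tries)) {
    w <- sample(AA20, WINDOW_WIDTH, replace = TRUE)
    w[WINDOW_CENTER] <- center
    for (k in seq_along(motif$offsets)) {
      res <- motif$allowed[[k]]
      off <- motif$offsets[[k]]
      if (is.null(res) || off == 0L) next
      w[WINDOW_CENTER + off] <-
        if (length(res) == 1L) res else sample(res, 1L)
    }
    win <- paste(w, collapse = "")
    other <- vapply(lib, function(o) {
      !identical(o$kinase, motif$kinase) && match_motif(win, o)
    }, logical(1))
    if (!any(other)) break
  }
  list(window = win, center = center)
}

#' Simulate an interaction network, optionally with planted connectors
#'
#' Without planted connectors, draws a single graph from the requested
#' model (`erdos_renyi`: G(n, p); `scale_free`: Barabasi-Albert
#' preferential attachment). With `n_planted_connectors = k > 0`, the
#' remaining nodes are split into `k + 1` communities, each wired
#' internally by the requested model, and consecutive communities are
#' joined only through a dedicated connector node attached to `n_attach`
#' members of each; all inter-community shortest paths therefore pass
#' through the connectors, giving them betweenness above the graph mean.
#' Edges are decorated with uniform evidence-channel scores
#' (`score_experiments`, `score_databases`) and, when `signaling = TRUE`,
#' with random `activation`/`inhibition`/`docking` relations.
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param model `"scale_free"` or `"erdos_renyi"`.
#' @param model_params List of model parameters: `p` (edge probability,
#'   Erdos-Renyi, default 0.3) or `m` (edges added per step,
#'   Barabasi-Albert, default 2).
#' @param n_planted_connectors Number of planted connector nodes
#'   (< `n_nodes`).
#' @param n_attach Community members each connector attaches to (per side).
#' @param signaling Decorate edges with signed directed relations?
#' @param node_names Optional character vector of node names (length
#'   `n_nodes`); defaults to `N001`, `N002`, ...
#' @param seed Integer random seed.
#' @return A list with `edges` (tibble: `node_a`, `node_b`,
#'   `score_experiments`, `score_databases`, `relation`) and `truth`
#'   (list with `connectors`, the planted connector node names).
#' @export
simulate_network <- function(n_nodes, model = c("scale_free", "erdos_renyi"),
                             model_params = list(),
                             n_planted_connectors = 0L, n_attach = 2L,
                             signaling = FALSE, node_names = NULL,
                             seed = 1L) {
  if (!is.numeric(n_nodes) || n_nodes < 3) stop_("'n_nodes' must be >= 3")
  n_nodes <- as.integer(n_nodes)
  if (is.character(model) && length(model) == 1L &&
      !model %in% c("scale_free", "erdos_renyi")) {
    stop_("unknown model '%s'; supported models: scale_free, erdos_renyi",
          model)
  }
  model <- match.arg(model)
  if (n_planted_connectors >= n_nodes) {
    stop_("'n_planted_connectors' must be smaller than 'n_nodes'")
  }
  if (is.null(node_names)) {
    node_names <- sprintf("N%03d", seq_len(n_nodes))
  }
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  set.seed(as.integer(seed))

  draw_model <- function(nn) {
    if (nn <= 1L) return(matrix(integer(0), ncol = 2))
    g <- switch(model,
      erdos_renyi = igraph::sample_gnp(nn, model_params$p %||% 0.3),
      scale_free = igraph::sample_pa(nn, m = min(model_params$m %||% 2L,
                                                 nn - 1L),
                                     directed = FALSE))
    igraph::as_edgelist(g, names = FALSE)
  }

  k <- as.integer(n_planted_connectors)
  if (k == 0L) {
    el <- draw_model(n_nodes)
    connectors <- character(0)
  } else {
    members <- seq_len(n_nodes - k)
    community <- rep(seq_len(k + 1L), length.out = length(members))
    connectors_idx <- n_nodes - k + seq_len(k)
    el <- matrix(integer(0), ncol = 2)
    for (cm in seq_len(k + 1L)) {
      ids <- members[community == cm]
      sub <- draw_model(length(ids))
      if (nrow(sub) > 0L) {
        el <- rbind(el, cbind(ids[sub[, 1]], ids[sub[, 2]]))
      }
    }
    for (j in seq_len(k)) {
      conn <- connectors_idx[j]
      for (cm in c(j, j + 1L)) {
        ids <- members[community == cm]
        pick <- ids[sample.int(length(ids), min(n_attach, length(ids)))]
        el <- rbind(el, cbind(conn, pick))
      }
    }
    connectors <- node_names[connectors_idx]
  }
  # simplify: drop self-loops and duplicate undirected edges
  if (nrow(el) > 0L) {
    el <- el[el[, 1] != el[, 2], , drop = FALSE]
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[!duplicated(key), , drop = FALSE]
  }
  m <- nrow(el)
  relation <- rep("", m)
  if (signaling && m > 0L) {
    relation <- sample(c("activation", "inhibition", "docking"), m,
                       replace = TRUE, prob = c(0.45, 0.25, 0.30))
  }
  edges <- tibble::tibble(node_a = node_names[el[, 1]],
                          node_b = node_names[el[, 2]],
                          score_experiments = round(runif(m), 3),
                          score_databases = round(runif(m), 3),
                          relation = relation)
  list(edges = edges, truth = list(connectors = connectors))
}
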