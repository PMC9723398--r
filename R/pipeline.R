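# End-to-end orchestration from a single YAML configuration: simulate or
# read, normalize, call, summarize, attribute motifs, build the network,
# rank by centrality, select hubs, and test against the randomized null.

config_schema <- list(
  top = c("seed", "out_dir", "receptors", "comparisons", "thresholds",
          "data", "motifs", "network", "log_level"),
  thresholds = c("up", "down", "min_present", "n_replicates"),
  comparison = c("name", "numerator", "denominator", "condition"),
  data = c("synthetic", "paths"),
  data_synthetic = c("n_sites", "n_proteins", "n_replicates", "frac_up",
                     "frac_down", "true_up_ratio", "true_down_ratio",
                     "noise_sigma", "missing_rate", "frac_motif_planted"),
  network = c("synthetic", "edges", "mode", "experiments_min",
              "databases_min", "n_random", "n_swaps"),
  network_synthetic = c("model", "p", "m", "n_planted_connectors",
                        "n_attach")
)

reject_unknown <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop_("unknown configuration key(s) under '%s': %s", where,
          paste(unknown, collapse = ", "))
  }
}

#' Validate a pipeline configuration file
#'
#' Parses a YAML run configuration, fills defaults (thresholds 1.5/0.67,
#' at least 2 of 3 replicates present, STRING-style channel minima
#' 0.15/0.35), rejects unknown keys with their key path, checks the
#' threshold and fraction invariants, and verifies that referenced input
#' files exist. Each data source must be given either as file paths or as
#' a synthetic-generation block, never both.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_("configuration file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  reject_unknown(cfg, config_schema$top, "top level")
  out <- list(
    seed = cfg$seed %||% 1L,
    out_dir = cfg$out_dir %||% "phosnet_out",
    receptors = cfg$receptors %||% c("ACKR2", "CCR5"),
    log_level = cfg$log_level %||% "info",
    config_path = normalizePath(path)
  )
  if (!is.numeric(out$seed) || length(out$seed) != 1L) {
    stop_("'seed' must be a single integer")
  }
  th <- cfg$thresholds %||% list()
  reject_unknown(th, config_schema$thresholds, "thresholds")
  out$thresholds <- regulation_thresholds(
    up_threshold = th$up %||% 1.5,
    down_threshold = th$down %||% 0.67,
    min_present = th$min_present %||% 2L,
    n_replicates = th$n_replicates %||% 3L)

  cmp_list <- cfg$comparisons %||%
    list(list(name = "agonist_T3", numerator = "stimulated_T3",
              denominator = "vehicle"),
         list(name = "agonist_T30", numerator = "stimulated_T30",
              denominator = "vehicle"))
  out$comparisons <- lapply(cmp_list, function(cc) {
    reject_unknown(cc, config_schema$comparison, "comparisons")
    if (is.null(cc$name)) stop_("every comparison needs a 'name'")
    comparison_design(cc$name,
                      numerator = cc$numerator %||% "treatment",
                      denominator = cc$denominator %||% "reference",
                      condition = cc$condition %||% cc$name)
  })

  dat <- cfg$data %||% list(synthetic = list())
  reject_unknown(dat, config_schema$data, "data")
  if (!xor(is.null(dat$synthetic), is.null(dat$paths))) {
    stop_("'data' must contain exactly one of 'synthetic' or 'paths'")
  }
  if (!is.null(dat$synthetic)) {
    reject_unknown(dat$synthetic, config_schema$data_synthetic,
                   "data.synthetic")
  } else {
    for (r in out$receptors) {
      p <- dat$paths[[r]]
      if (is.null(p)) stop_("'data.paths' lacks an entry for receptor '%s'", r)
      if (!file.exists(p)) stop_("phosphosite table not found: %s", p)
    }
  }
  out$data <- dat

  if (!is.null(cfg$motifs) && !file.exists(cfg$motifs)) {
    stop_("motif library file not found: %s", cfg$motifs)
  }
  out$motifs <- cfg$motifs

  net <- cfg$network %||% list(synthetic = list())
  reject_unknown(net, config_schema$network, "network")
  if (!xor(is.null(net$synthetic), is.null(net$edges))) {
    stop_("'network' must contain exactly one of 'synthetic' or 'edges'")
  }
  if (!is.null(net$synthetic)) {
    reject_unknown(net$synthetic, config_schema$network_synthetic,
                   "network.synthetic")
  } else if (!file.exists(net$edges)) {
    stop_("edge table not found: %s", net$edges)
  }
  net$mode <- net$mode %||% "ppi_undirected"
  if (!net$mode %in% c("ppi_undirected", "signaling_mixed")) {
    stop_("'network.mode' must be ppi_undirected or signaling_mixed")
  }
  net$experiments_min <- net$experiments_min %||% 0.15
  net$databases_min <- net$databases_min %||% 0.35
  net$n_random <- net$n_random %||% 100L
  out$network <- net
  structure(out, class = "run_config")
}

# per-stage seeds derived from the global seed so stages are independently
# reproducible; offsets are fixed per stage name
derive_seed <- function(seed, stage) {
  offsets <- c(data_ACKR2 = 11L, data_CCR5 = 12L, data_other = 13L,
               network = 101L, null = 211L)
  off <- offsets[[if (stage %in% names(offsets)) stage else "data_other"]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

log_msg <- function(level, cfg_level, fmt, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[cfg_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

#' Run the whole pipeline from a validated configuration
#'
#' Executes, per receptor: data generation or ingestion, median-zero log2
#' normalization, presence filtering and geometric-mean regulation calls;
#' then the cross-receptor distinct/shared summaries and kinetics, kinase
#' motif counting with the percentage-ratio comparison, and the network
#' stage (evidence filtering for file-based edges, network construction
#' on the differentially phosphorylated proteins, the ten-centrality
#' battery, above-mean-betweenness hubs, and the degree-preserving null
#' distribution). Every table is written as TSV under `out_dir` together
#' with a JSON run report (configuration echo and hash, seed, stage
#' counts, package version). Identical configurations and seeds reproduce
#' byte-identical TSV outputs.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   YAML configuration file.
#' @param out_dir Output directory (default from the configuration).
#' @param last_stage Run the pipeline up to this stage only:
#'   `"differential"`, `"motifs"` or `"network"` (the default, i.e.
#'   everything).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         last_stage = c("network", "motifs",
                                        "differential")) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  last_stage <- match.arg(last_stage)
  stage_rank <- c(differential = 1, motifs = 2, network = 3)
  run_stage <- function(s) stage_rank[[s]] <= stage_rank[[last_stage]]
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lvl <- config$log_level
  report <- list(seed = config$seed,
                 config_hash = unname(tools::md5sum(config$config_path)),
                 package_version = as.character(
                   utils::packageVersion("phosnet")),
                 r_version = R.version.string,
                 counts = list())
  conditions <- vapply(config$comparisons,
                       function(cc) cc$condition, character(1))
  motifs <- if (is.null(config$motifs)) default_motif_library()
            else read_motif_library(config$motifs)

  calls <- list()
  truths <- list()
  for (r in config$receptors) {
    log_msg("info", lvl, "receptor %s: loading phosphosite data", r)
    if (!is.null(config$data$synthetic)) {
      sc <- config$data$synthetic
      sim <- simulate_phosphosites(simulation_config(
        n_sites = sc$n_sites %||% 2000L,
        n_proteins = sc$n_proteins %||% 600L,
        n_replicates = sc$n_replicates %||% config$thresholds$n_replicates,
        conditions = conditions,
        frac_up = sc$frac_up %||% 0.1,
        frac_down = sc$frac_down %||% 0.1,
        true_up_ratio = sc$true_up_ratio %||% 2,
        true_down_ratio = sc$true_down_ratio %||% 0.5,
        noise_sigma = sc$noise_sigma %||% 0.25,
        missing_rate = sc$missing_rate %||% 0.05,
        motif_library = motifs,
        frac_motif_planted = sc$frac_motif_planted %||% 0.5,
        seed = derive_seed(config$seed, paste0("data_", r))))
      tab <- sim$table
      truths[[r]] <- sim$truth
      write_tsv_file(tab, file.path(out_dir,
                                    sprintf("phosphosites_%s.tsv", r)))
    } else {
      tab <- read_phosphosites(config$data$paths[[r]])
    }
    log_msg("info", lvl, "receptor %s: normalizing and calling", r)
    tab <- normalize_ratios(tab)
    cmps <- lapply(config$comparisons, function(cc) {
      comparison_design(cc$name, cc$numerator, cc$denominator,
                        receptor = r, condition = cc$condition)
    })
    calls[[r]] <- call_sites_and_proteins(tab, cmps, config$thresholds)
    write_tsv_file(calls[[r]]$sites,
                   file.path(out_dir, sprintf("site_calls_%s.tsv", r)))
    write_tsv_file(calls[[r]]$proteins,
                   file.path(out_dir, sprintf("protein_calls_%s.tsv", r)))
    lab <- calls[[r]]$sites$label
    report$counts[[r]] <- list(
      n_sites = nrow(tab),
      site_labels = as.list(table(lab)),
      n_dpps = length(unique(
        calls[[r]]$proteins$protein_id[calls[[r]]$proteins$regulated])))
    if (!is.null(truths[[r]])) {
      truth <- truths[[r]]
      per_cmp <- lapply(split(calls[[r]]$sites, calls[[r]]$sites$comparison),
                        function(sc_calls) {
        called <- sc_calls$label[match(truth$site_id, sc_calls$site_id)]
        as.data.frame(table(true = truth$true_label, called = called))
      })
      report$counts[[r]]$confusion <- per_cmp
    }
  }

  if (length(config$receptors) >= 2L) {
    ra <- config$receptors[1]
    rb <- config$receptors[2]
    log_msg("info", lvl, "summarizing %s vs %s", ra, rb)
    site_sum <- summarize_sets(calls[[ra]]$sites, calls[[rb]]$sites,
                               receptors = c(ra, rb))
    prot_sum <- summarize_sets(calls[[ra]]$proteins, calls[[rb]]$proteins,
                               receptors = c(ra, rb))
    write_tsv_file(site_sum$overlap, file.path(out_dir, "site_overlap.tsv"))
    write_tsv_file(site_sum$kinetics, file.path(out_dir,
                                                "site_kinetics.tsv"))
    write_tsv_file(prot_sum$overlap, file.path(out_dir,
                                               "protein_overlap.tsv"))
  }

  if (run_stage("motifs")) {
    log_msg("info", lvl, "kinase motif attribution")
    reg_sites <- do.call(rbind, lapply(config$receptors, function(r) {
      s <- calls[[r]]$sites
      s[s$label %in% c("up", "down"), ]
    }))
    mc <- count_motifs(reg_sites, motifs)
    write_tsv_file(mc, file.path(out_dir, "motif_counts.tsv"))
    if (length(config$receptors) >= 2L && sum(mc$count) > 0L) {
      rt <- motif_ratio_table(mc, config$receptors[1], config$receptors[2])
      write_tsv_file(rt, file.path(out_dir, "motif_ratios.tsv"))
      write_tsv_file(count_kinases_more_active(rt),
                     file.path(out_dir, "kinases_more_active.tsv"))
    }
  }

  net_cfg <- config$network
  for (r in if (run_stage("network")) config$receptors else character(0)) {
    prot <- calls[[r]]$proteins
    dpps <- unique(prot$protein_id[prot$regulated])
    if (length(dpps) == 0L) {
      log_msg("warn", lvl, "receptor %s: no DPPs, skipping network", r)
      next
    }
    log_msg("info", lvl, "receptor %s: network on %d DPPs", r, length(dpps))
    if (!is.null(net_cfg$synthetic)) {
      ns <- net_cfg$synthetic
      sim <- simulate_network(
        n_nodes = length(dpps),
        model = ns$model %||% "scale_free",
        model_params = list(p = ns$p, m = ns$m),
        n_planted_connectors = ns$n_planted_connectors %||% 0L,
        n_attach = ns$n_attach %||% 2L,
        signaling = net_cfg$mode == "signaling_mixed",
        node_names = sort(dpps),
        seed = derive_seed(config$seed, "network"))
      edges <- sim$edges
    } else {
      edges <- filter_edges(read_edges(net_cfg$edges),
                            experiments_min = net_cfg$experiments_min,
                            databases_min = net_cfg$databases_min)
    }
    dirs <- prot$directions[match(dpps, prot$protein_id)]
    net <- build_network(dpps, edges, mode = net_cfg$mode,
                         node_annotations = data.frame(
                           node = dpps, direction = dirs,
                           stringsAsFactors = FALSE))
    prof <- compute_centralities(net)
    write_tsv_file(prof, file.path(out_dir,
                                   sprintf("centralities_%s.tsv", r)))
    hubs <- select_hubs(prof)
    writeLines(sort(hubs), file.path(out_dir, sprintf("hubs_%s.tsv", r)))
    nd <- null_distribution(net, n_random = net_cfg$n_random,
                            n_swaps = net_cfg$n_swaps,
                            seed = derive_seed(config$seed, "null"))
    write_tsv_file(nd$nodes, file.path(out_dir,
                                       sprintf("null_nodes_%s.tsv", r)))
    write_tsv_file(nd$replicates,
                   file.path(out_dir, sprintf("null_replicates_%s.tsv", r)))
    write_network_sif(net, file.path(out_dir, sprintf("network_%s.sif", r)))
    write_network_graphml(net, file.path(out_dir,
                                         sprintf("network_%s.graphml", r)))
    report$counts[[r]]$network <- list(nodes = nrow(net$nodes),
                                       edges = nrow(net$edges),
                                       hubs = length(hubs))
  }

  report$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("info", lvl, "run complete: %s", out_dir)
  invisible(report)
}
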