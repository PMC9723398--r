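# Normalization, presence filtering, geometric-mean fold-change calling of
# phosphosites and phosphoproteins, and cross-receptor set summaries.

#' Regulation-call thresholds
#'
#' Defaults reproduce the standard SILAC calling rule: a site is up- or
#' down-regulated when the geometric mean of its replicate ratios is
#' strictly above 1.5 or strictly below 0.67 (a more than 50% change in
#' level), and only sites present and quantified in at least
#' `min_present` of `n_replicates` biological replicates are considered
#' positively identified.
#'
#' @param up_threshold Upper geometric-mean ratio bound (> 1).
#' @param down_threshold Lower bound (in (0, 1)).
#' @param min_present Minimum replicates quantified (default 2 of 3).
#' @param n_replicates Number of biological replicates per condition.
#' @return A `regulation_thresholds` object.
#' @export
regulation_thresholds <- function(up_threshold = 1.5, down_threshold = 0.67,
                                  min_present = 2L, n_replicates = 3L) {
  if (!is.numeric(up_threshold) || up_threshold <= 1) {
    stop_("'up_threshold' must be > 1")
  }
  if (!is.numeric(down_threshold) || down_threshold <= 0 ||
      down_threshold >= 1) {
    stop_("'down_threshold' must lie in (0, 1)")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    stop_("'n_replicates' must be >= 1")
  }
  if (!is.numeric(min_present) || min_present < 1 ||
      min_present > n_replicates) {
    stop_("'min_present' must lie in 1..n_replicates")
  }
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 min_present = as.integer(min_present),
                 n_replicates = as.integer(n_replicates)),
            class = "regulation_thresholds")
}

#' Define a comparison between SILAC channels
#'
#' In a SILAC design each mixed sample is itself a comparison: the heavy
#' and light channels carry the two states (e.g. receptor-induced,
#' agonist-stimulated cells versus vehicle), so the per-replicate ratio
#' columns of one condition already encode numerator/denominator. A
#' comparison therefore names the condition whose `ratio_<condition>_rep*`
#' columns it reads (`condition`, defaulting to `name`) and documents what
#' the two channels contained (`numerator`, `denominator`).
#'
#' @param name Comparison name (e.g. `"agonist_T3"`).
#' @param numerator,denominator Labels of the channel contents; must
#'   differ.
#' @param receptor Optional receptor label carried through to outputs.
#' @param condition Condition label selecting the ratio columns.
#' @return A `comparison_design` object.
#' @export
comparison_design <- function(name, numerator, denominator,
                              receptor = NA_character_, condition = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (identical(numerator, denominator)) {
    stop_("comparison '%s': numerator and denominator must differ", name)
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, receptor = receptor,
                 condition = condition),
            class = "comparison_design")
}

ratio_columns <- function(table, condition) {
  cols <- grep(sprintf("^ratio_%s_rep[0-9]+$", condition), names(table),
               value = TRUE)
  if (length(cols) == 0L) {
    stop_("no ratio columns found for condition '%s'", condition)
  }
  cols[order(as.integer(sub(".*_rep", "", cols)))]
}

#' Median-center SILAC ratio columns on the log2 scale
#'
#' Divides every `ratio_*` column by 2 raised to the median of its log2
#' values over present measurements, so each condition-replicate column has
#' median log2 ratio exactly zero afterwards (the usual SILAC ratio
#' normalization). Missing values are left untouched and row order is
#' preserved; the operation is idempotent.
#'
#' @param table Phosphosite table with `ratio_*` columns.
#' @return The table with normalized ratio columns.
#' @export
normalize_ratios <- function(table) {
  stopifnot(is.data.frame(table))
  cols <- grep("^ratio_", names(table), value = TRUE)
  if (length(cols) == 0L) stop_("no 'ratio_*' columns found")
  for (cl in cols) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop_("ratio column '%s' is not numeric", cl)
    present <- !is.na(x)
    if (!any(present)) {
      stop_("ratio column '%s' has no present values", cl)
    }
    if (any(x[present] <= 0)) {
      bad <- which(present & x <= 0)[1]
      stop_("nonpositive ratio in column '%s' (row %d%s)", cl, bad,
            if ("site_id" %in% names(table))
              sprintf(", site '%s'", table$site_id[bad]) else "")
    }
    table[[cl]] <- x / 2 ^ median(log2(x[present]))
  }
  table
}

#' Split a table by replicate presence for one comparison
#'
#' Sites quantified in at least `min_present` replicates of the
#' comparison's condition are retained; the rest are routed to a
#' `not_quantified` table rather than silently dropped.
#'
#' @param table Phosphosite table.
#' @param thresholds A [regulation_thresholds()].
#' @param comparison A [comparison_design()].
#' @return A list with `retained` and `not_quantified` tibbles (both carry
#'   an `n_present` column).
#' @export
filter_by_presence <- function(table, thresholds, comparison) {
  stopifnot(inherits(thresholds, "regulation_thresholds"),
            inherits(comparison, "comparison_design"))
  cols <- ratio_columns(table, comparison$condition)
  n_present <- rowSums(!is.na(as.matrix(table[cols])))
  table$n_present <- as.integer(n_present)
  keep <- n_present >= thresholds$min_present
  list(retained = tibble::as_tibble(table[keep, , drop = FALSE]),
       not_quantified = tibble::as_tibble(table[!keep, , drop = FALSE]))
}

#' Geometric mean of positive replicate ratios
#'
#' @param values Non-empty vector of positive values.
#' @return `exp(mean(log(values)))`.
#' @export
geometric_mean <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop_("geometric mean of an empty set")
  if (any(values <= 0)) stop_("geometric mean requires positive values")
  exp(mean(log(values)))
}

#' Call regulation from a geometric-mean ratio
#'
#' Strict thresholds: `up` if the geometric mean exceeds `up_threshold`,
#' `down` if below `down_threshold`, otherwise `unchanged`; values equal
#' to a threshold are `unchanged`.
#'
#' @param gm_ratio Positive geometric-mean ratio (vectorized).
#' @param thresholds A [regulation_thresholds()].
#' @return Character vector of labels in `{up, down, unchanged}`.
#' @export
call_regulation <- function(gm_ratio, thresholds = regulation_thresholds()) {
  stopifnot(inherits(thresholds, "regulation_thresholds"))
  if (any(!is.na(gm_ratio) & gm_ratio <= 0)) {
    stop_("'gm_ratio' must be positive")
  }
  ifelse(gm_ratio > thresholds$up_threshold, "up",
         ifelse(gm_ratio < thresholds$down_threshold, "down", "unchanged"))
}

#' Call regulated phosphosites and phosphoproteins
#'
#' For every comparison, computes each site's number of quantified
#' replicates and the geometric mean of its present ratios, then labels
#' the site `up`/`down`/`unchanged` by [call_regulation()], or
#' `not_quantified` when fewer than `min_present` replicates are present.
#' A protein is regulated in a comparison when at least one of its sites
#' is; its `directions` field collects the directions of its regulated
#' sites (`"up"`, `"down"`, or `"up|down"` when sites disagree, with no
#' net call taken).
#'
#' @param table Normalized phosphosite table.
#' @param design A [comparison_design()] or list of them.
#' @param thresholds A [regulation_thresholds()].
#' @return A list with `sites` (tibble: `target`, `site_id`, `protein_id`,
#'   `sequence_window`, `comparison`, `receptor`, `n_present`, `gm_ratio`,
#'   `label`) and `proteins` (tibble: `target`, `protein_id`,
#'   `comparison`, `receptor`, `regulated`, `directions`, `n_sites`,
#'   `n_up`, `n_down`).
#' @export
call_sites_and_proteins <- function(table, design,
                                    thresholds = regulation_thresholds()) {
  if (inherits(design, "comparison_design")) design <- list(design)
  stopifnot(length(design) >= 1L,
            all(vapply(design, inherits, logical(1), "comparison_design")))
  if (anyDuplicated(table$site_id)) {
    stop_("duplicate site_id rows in input table")
  }
  site_rows <- list()
  prot_rows <- list()
  for (cmp in design) {
    cols <- ratio_columns(table, cmp$condition)
    mat <- as.matrix(table[cols])
    n_present <- as.integer(rowSums(!is.na(mat)))
    gm <- vapply(seq_len(nrow(mat)), function(i) {
      v <- mat[i, ]
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else geometric_mean(v)
    }, numeric(1))
    label <- ifelse(n_present < thresholds$min_present, "not_quantified",
                    call_regulation(ifelse(is.na(gm), 1, gm), thresholds))
    sites <- tibble::tibble(target = table$site_id,
                            site_id = table$site_id,
                            protein_id = table$protein_id,
                            sequence_window =
                              if ("sequence_window" %in% names(table))
                                table$sequence_window
                              else rep(NA_character_, nrow(table)),
                            comparison = cmp$name,
                            receptor = cmp$receptor,
                            n_present = n_present, gm_ratio = gm,
                            label = label)
    site_rows[[cmp$name]] <- sites
    quant <- sites[sites$label != "not_quantified", , drop = FALSE]
    prot_ids <- unique(sites$protein_id)
    prot <- do.call(rbind, lapply(prot_ids, function(p) {
      ps <- quant[quant$protein_id == p, , drop = FALSE]
      n_up <- sum(ps$label == "up")
      n_down <- sum(ps$label == "down")
      dirs <- c(if (n_up > 0) "up", if (n_down > 0) "down")
      data.frame(target = p, protein_id = p, comparison = cmp$name,
                 receptor = cmp$receptor,
                 regulated = n_up + n_down > 0,
                 directions = paste(dirs, collapse = "|"),
                 n_sites = nrow(ps), n_up = n_up, n_down = n_down,
                 stringsAsFactors = FALSE)
    }))
    prot_rows[[cmp$name]] <- prot
  }
  list(sites = tibble::as_tibble(do.call(rbind, site_rows)),
       proteins = tibble::as_tibble(do.call(rbind, prot_rows)))
}

direction_sets <- function(calls) {
  # accepts site-level calls (label column) or protein-level calls
  # (directions column); returns per comparison a named list mapping
  # target -> character vector of directions
  stopifnot(is.data.frame(calls), "target" %in% names(calls),
            "comparison" %in% names(calls))
  out <- list()
  for (cmp in unique(calls$comparison)) {
    cc <- calls[calls$comparison == cmp, , drop = FALSE]
    sets <- list()
    if ("label" %in% names(cc)) {
      reg <- cc[cc$label %in% c("up", "down"), , drop = FALSE]
      for (i in seq_len(nrow(reg))) {
        t <- reg$target[i]
        sets[[t]] <- union(sets[[t]], reg$label[i])
      }
    } else if ("directions" %in% names(cc)) {
      reg <- cc[nzchar(cc$directions), , drop = FALSE]
      for (i in seq_len(nrow(reg))) {
        sets[[reg$target[i]]] <-
          strsplit(reg$directions[i], "|", fixed = TRUE)[[1]]
      }
    } else {
      stop_("calls need a 'label' or 'directions' column")
    }
    out[[cmp]] <- sets
  }
  out
}

#' Summarize distinct and shared regulation calls of two receptors
#'
#' For each comparison (time point), counts regulated targets unique to
#' each receptor, shared with a coherent direction (the two direction
#' sets intersect) and shared with discordant directions, plus a
#' per-receptor kinetics table of up/down counts over comparisons. Works
#' on site-level or protein-level call tables from
#' [call_sites_and_proteins()].
#'
#' @param calls_a,calls_b Call tables for the two receptors, computed
#'   under identical thresholds and comparison names.
#' @param receptors Length-2 character vector of receptor labels.
#' @return A list with `overlap` (tibble: `comparison`, `unique_a`,
#'   `unique_b`, `shared_coherent`, `shared_discordant`) and `kinetics`
#'   (tibble: `receptor`, `comparison`, `n_up`, `n_down`).
#' @export
summarize_sets <- function(calls_a, calls_b, receptors = c("A", "B")) {
  sets_a <- direction_sets(calls_a)
  sets_b <- direction_sets(calls_b)
  if (!setequal(names(sets_a), names(sets_b))) {
    stop_("comparison names differ between call sets: %s vs %s",
          paste(names(sets_a), collapse = ","),
          paste(names(sets_b), collapse = ","))
  }
  overlap <- do.call(rbind, lapply(names(sets_a), function(cmp) {
    a <- sets_a[[cmp]]
    b <- sets_b[[cmp]]
    shared <- intersect(names(a), names(b))
    coherent <- sum(vapply(shared, function(t) {
      length(intersect(a[[t]], b[[t]])) > 0
    }, logical(1)))
    data.frame(comparison = cmp,
               unique_a = length(setdiff(names(a), names(b))),
               unique_b = length(setdiff(names(b), names(a))),
               shared_coherent = coherent,
               shared_discordant = length(shared) - coherent,
               stringsAsFactors = FALSE)
  }))
  kin <- function(sets, receptor) {
    do.call(rbind, lapply(names(sets), function(cmp) {
      dirs <- sets[[cmp]]
      data.frame(receptor = receptor, comparison = cmp,
                 n_up = sum(vapply(dirs, function(d) "up" %in% d,
                                   logical(1))),
                 n_down = sum(vapply(dirs, function(d) "down" %in% d,
                                     logical(1))),
                 stringsAsFactors = FALSE)
    }))
  }
  kinetics <- rbind(kin(sets_a, receptors[1]), kin(sets_b, receptors[2]))
  list(overlap = tibble::as_tibble(overlap),
       kinetics = tibble::as_tibble(kinetics))
}
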