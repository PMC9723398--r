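# Kinase consensus motif parsing, window matching, counting, and the
# cross-receptor percentage-ratio statistic.

#' Parse a kinase motif library
#'
#' Motifs are written one per line as `kinase<TAB>pattern`, where the
#' pattern is a dash-separated list of position specifications read
#' N-terminal to C-terminal, e.g. `PKA\tR-R-x-S*`. Each specification is a
#' single residue letter, a bracketed residue set such as `[RK]`, or the
#' wildcard `x`; a trailing `*` marks the phosphoacceptor position, whose
#' residues must be a subset of S/T/Y. Offsets relative to the
#' phosphoacceptor are inferred from the `*` position, so `R-R-x-S*` places
#' R at -3 and -2. Blank lines and lines starting with `#` are ignored.
#'
#' @param text Character vector of lines, or a single string containing
#'   newlines.
#' @return A `motif_library`: a list of motif definitions, each with
#'   elements `kinase`, `pattern` (the original string), `offsets`
#'   (integer offsets -6..6), `allowed` (parallel list of allowed residue
#'   sets, `NULL` for wildcards) and `center_residues`.
#' @seealso [read_motif_library()], [default_motif_library()],
#'   [match_motif()]
#' @export
#' @examples
#' parse_motif_library(c("PKA\tR-R-x-S*", "CK2\tS*-x-x-E"))
parse_motif_library <- function(text) {
  stopifnot(is.character(text))
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  motifs <- list()
  seen <- character(0)
  for (i in seq_along(text)) {
    line <- trimws(text[[i]])
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stop_("motif library line %d: expected 'kinase<TAB>pattern', got '%s'",
            i, line)
    }
    kinase <- trimws(fields[[1]])
    pattern <- trimws(fields[[2]])
    key <- paste(kinase, pattern, sep = "\t")
    if (key %in% seen) {
      stop_("motif library line %d: duplicate kinase/pattern pair '%s'",
            i, kinase)
    }
    seen <- c(seen, key)
    motifs[[length(motifs) + 1L]] <-
      parse_one_motif(kinase, pattern, line_no = i)
  }
  structure(motifs, class = "motif_library")
}

parse_one_motif <- function(kinase, pattern, line_no) {
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 1L || length(tokens) > WINDOW_WIDTH) {
    stop_("motif library line %d: pattern must have 1-%d positions",
          line_no, WINDOW_WIDTH)
  }
  starred <- grepl("\\*$", tokens)
  if (sum(starred) != 1L) {
    stop_(paste0("motif library line %d: pattern '%s' must mark exactly one",
                 " phosphoacceptor position with '*'"), line_no, pattern)
  }
  center_pos <- which(starred)
  tokens <- sub("\\*$", "", tokens)
  allowed <- vector("list", length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[[k]]
    if (tok == "x" || tok == "X") {
      allowed[[k]] <- NULL
      next
    }
    if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
      res <- strsplit(substr(tok, 2L, nchar(tok) - 1L), "")[[1]]
    } else if (grepl("^[A-Za-z]$", tok)) {
      res <- tok
    } else {
      stop_("motif library line %d: malformed position '%s'", line_no, tok)
    }
    res <- toupper(res)
    bad <- setdiff(res, AA20)
    if (length(bad) > 0L) {
      stop_("motif library line %d: unknown residue letter(s) %s",
            line_no, paste(bad, collapse = ", "))
    }
    allowed[[k]] <- res
  }
  center_residues <- allowed[[center_pos]]
  if (is.null(center_residues)) {
    stop_("motif library line %d: phosphoacceptor position cannot be 'x'",
          line_no)
  }
  if (!all(center_residues %in% c("S", "T", "Y"))) {
    stop_("motif library line %d: phosphoacceptor residues must be S, T or Y",
          line_no)
  }
  offsets <- seq_along(tokens) - center_pos
  if (any(offsets < -6L) || any(offsets > 6L)) {
    stop_("motif library line %d: offsets must lie within -6..+6", line_no)
  }
  n_informative <- sum(!vapply(allowed, is.null, logical(1))) - 1L
  if (n_informative < 1L) {
    stop_(paste0("motif library line %d: pattern needs at least one",
                 " non-wildcard position besides the phosphoacceptor"),
          line_no)
  }
  list(kinase = kinase, pattern = pattern, offsets = as.integer(offsets),
       allowed = allowed, center_residues = center_residues)
}

#' Read a kinase motif library from a TSV file
#'
#' @param path Path to a motif file in the [parse_motif_library()] dialect.
#' @return A `motif_library`.
#' @export
read_motif_library <- function(path) {
  if (!file.exists(path)) stop_("motif library file not found: %s", path)
  parse_motif_library(readLines(path, warn = FALSE))
}

#' Built-in illustrative kinase motif library
#'
#' A small library of widely cited kinase consensus motifs (basophilic
#' PKA/PKC/CAMK2/AKT, proline-directed CDK1/MAPK, acidophilic CK2/PLK1,
#' priming-dependent GSK3, the ATM/ATR S/T-Q motif and an acidic tyrosine
#' motif). These consensus patterns are illustrative defaults for motif
#' attribution and benchmarking, not a curated substrate database; results
#' on real data depend on the library supplied.
#'
#' @return A `motif_library`.
#' @export
default_motif_library <- function() {
  path <- system.file("extdata", "kinase_motifs.tsv", package = "phosnet",
                      mustWork = TRUE)
  read_motif_library(path)
}

#' @export
print.motif_library <- function(x, ...) {
  cat(sprintf("<motif_library> %d motifs, %d kinases\n",
              length(x), length(unique(vapply(x, `[[`, "", "kinase")))))
  for (m in x) cat(sprintf("  %-8s %s\n", m$kinase, m$pattern))
  invisible(x)
}

#' Match a sequence window against a kinase motif
#'
#' A 13-mer window (positions -6..+6 around the phosphoacceptor) matches a
#' motif when its center residue is one of the motif's phosphoacceptor
#' residues and every non-wildcard offset carries an allowed residue. The
#' terminal padding character `_` never satisfies a non-wildcard position.
#'
#' @param window A 13-character sequence window.
#' @param motif A single motif definition from a `motif_library`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' lib <- parse_motif_library("PKA\tR-R-x-S*")
#' match_motif("GGGRRASGGGGGG", lib[[1]])
match_motif <- function(window, motif) {
  if (!is.character(window) || length(window) != 1L) {
    stop_("'window' must be a single string")
  }
  if (nchar(window) != WINDOW_WIDTH) {
    stop_("sequence window must have %d characters, got %d ('%s')",
          WINDOW_WIDTH, nchar(window), window)
  }
  chars <- strsplit(window, "")[[1]]
  if (!chars[WINDOW_CENTER] %in% motif$center_residues) return(FALSE)
  for (k in seq_along(motif$offsets)) {
    res <- motif$allowed[[k]]
    if (is.null(res)) next
    off <- motif$offsets[[k]]
    if (off == 0L) next
    ch <- chars[WINDOW_CENTER + off]
    if (ch == PAD_CHAR || !(ch %in% res)) return(FALSE)
  }
  TRUE
}

#' Count kinase motif matches among regulated phosphosites
#'
#' Each site is attributed to every kinase with at least one matching motif
#' (one increment per kinase, deduplicated across a kinase's patterns), so
#' a single site can count toward several kinases. The per-group total is
#' the number of (site, kinase) attributions.
#'
#' @param sites A data frame of regulated sites with columns
#'   `sequence_window` and, optionally, `receptor` and `comparison`
#'   grouping columns (missing grouping columns are treated as a single
#'   group `"all"`).
#' @param motifs A `motif_library`.
#' @return A tibble with columns `receptor`, `comparison`, `kinase`,
#'   `count`, and `total` (the group's attribution total, repeated within
#'   the group). Every library kinase appears in every group, so zero
#'   counts are explicit.
#' @export
count_motifs <- function(sites, motifs) {
  if (!inherits(motifs, "motif_library") || length(motifs) == 0L) {
    stop_("'motifs' must be a non-empty motif_library")
  }
  stopifnot(is.data.frame(sites), "sequence_window" %in% names(sites))
  receptor <- if ("receptor" %in% names(sites)) as.character(sites$receptor)
              else rep("all", nrow(sites))
  comparison <- if ("comparison" %in% names(sites))
                  as.character(sites$comparison)
                else rep("all", nrow(sites))
  kinases <- unique(vapply(motifs, `[[`, "", "kinase"))

  # per-site matched kinase sets, deduplicated per kinase
  match_sets <- lapply(sites$sequence_window, function(w) {
    hits <- vapply(motifs, function(m) match_motif(w, m), logical(1))
    unique(vapply(motifs[hits], `[[`, "", "kinase"))
  })

  groups <- unique(data.frame(receptor = receptor, comparison = comparison,
                              stringsAsFactors = FALSE))
  if (nrow(groups) == 0L) {
    groups <- data.frame(receptor = "all", comparison = "all",
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    in_g <- receptor == groups$receptor[g] & comparison == groups$comparison[g]
    hits <- unlist(match_sets[in_g], use.names = FALSE)
    counts <- vapply(kinases, function(k) sum(hits == k), numeric(1))
    data.frame(receptor = groups$receptor[g],
               comparison = groups$comparison[g],
               kinase = kinases, count = as.integer(counts),
               total = as.integer(sum(counts)),
               stringsAsFactors = FALSE)
  }))
  tibble::as_tibble(out)
}

#' Percentage-ratio of motif attribution between two receptors
#'
#' For a kinase k with counts a(k) of A's attributions (total A) and b(k)
#' of B's (total B), the statistic is `[a(k)/A] / [b(k)/B]`: the ratio of
#' the percentage of motif counts attributed to k under each receptor. A
#' value of 1 means equal relative attribution; values above 1 mean the
#' kinase is relatively more active downstream of receptor A. If b(k) = 0
#' while a(k) > 0 the ratio is `Inf`; if both counts are 0 it is `NaN`
#' (undefined); neither case is dropped.
#'
#' @param counts_a,counts_b Count tables from [count_motifs()] (or subsets
#'   of one, e.g. one receptor/time point each).
#' @param kinase Kinase name.
#' @return A single numeric ratio.
#' @export
motif_percentage_ratio <- function(counts_a, counts_b, kinase) {
  pct <- function(tab, who) {
    stopifnot(is.data.frame(tab), all(c("kinase", "count") %in% names(tab)))
    total <- sum(tab$count)
    if (total <= 0L) stop_("zero attribution total in counts_%s", who)
    k <- sum(tab$count[tab$kinase == kinase])
    c(k = k, pct = k / total)
  }
  a <- pct(counts_a, "a")
  b <- pct(counts_b, "b")
  if (a[["k"]] == 0 && b[["k"]] == 0) return(NaN)
  if (b[["k"]] == 0) return(Inf)
  a[["pct"]] / b[["pct"]]
}

#' Percentage-ratio table across all kinases
#'
#' Computes [motif_percentage_ratio()] for every kinase and comparison
#' shared by two receptors in a [count_motifs()] table.
#'
#' @param counts A [count_motifs()] table containing both receptors.
#' @param receptor_a,receptor_b Receptor labels; the ratio is A relative
#'   to B.
#' @return A tibble with columns `comparison`, `kinase`, `count_a`,
#'   `count_b`, `pct_a`, `pct_b`, `ratio`.
#' @export
motif_ratio_table <- function(counts, receptor_a, receptor_b) {
  stopifnot(is.data.frame(counts),
            all(c("receptor", "comparison", "kinase", "count") %in%
                  names(counts)))
  for (r in c(receptor_a, receptor_b)) {
    if (!r %in% counts$receptor) stop_("receptor '%s' not in counts table", r)
  }
  comps <- intersect(unique(counts$comparison[counts$receptor == receptor_a]),
                     unique(counts$comparison[counts$receptor == receptor_b]))
  rows <- list()
  for (cmp in comps) {
    ca <- counts[counts$receptor == receptor_a & counts$comparison == cmp, ]
    cb <- counts[counts$receptor == receptor_b & counts$comparison == cmp, ]
    tot_a <- sum(ca$count)
    tot_b <- sum(cb$count)
    if (tot_a <= 0L || tot_b <= 0L) {
      stop_("zero attribution total for comparison '%s'", cmp)
    }
    for (k in unique(ca$kinase)) {
      a_k <- sum(ca$count[ca$kinase == k])
      b_k <- sum(cb$count[cb$kinase == k])
      ratio <- if (a_k == 0 && b_k == 0) NaN
               else if (b_k == 0) Inf
               else (a_k / tot_a) / (b_k / tot_b)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp, kinase = k, count_a = a_k, count_b = b_k,
        pct_a = 100 * a_k / tot_a, pct_b = 100 * b_k / tot_b,
        ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

#' Count kinases relatively more active with one receptor
#'
#' Tallies, per comparison, the kinases whose percentage-ratio is strictly
#' greater than 1 (including `Inf`, i.e. kinases attributed only under
#' receptor A); `NaN` ratios (no attributions under either receptor) are
#' excluded.
#'
#' @param ratio_table Output of [motif_ratio_table()].
#' @return A tibble with columns `comparison` and `n_more_active`.
#' @export
count_kinases_more_active <- function(ratio_table) {
  stopifnot(is.data.frame(ratio_table),
            all(c("comparison", "ratio") %in% names(ratio_table)))
  comps <- unique(ratio_table$comparison)
  n <- vapply(comps, function(cmp) {
    r <- ratio_table$ratio[ratio_table$comparison == cmp]
    sum(!is.nan(r) & r > 1)
  }, numeric(1))
  tibble::tibble(comparison = comps, n_more_active = as.integer(n))
}
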