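test_that("motif parsing infers offsets from the phosphoacceptor mark", {
  lib <- parse_motif_library(c("PKA\tR-R-x-S*", "CK2\tS*-x-x-E"))
  pka <- lib[[1]]
  expect_identical(pka$offsets, c(-3L, -2L, -1L, 0L))
  expect_identical(pka$allowed[[1]], "R")
  expect_null(pka$allowed[[3]])
  expect_identical(pka$center_residues, "S")
  ck2 <- lib[[2]]
  expect_identical(ck2$offsets, c(0L, 1L, 2L, 3L))
  expect_identical(ck2$allowed[[4]], "E")
  # bracket residue sets
  m <- parse_motif_library("CDK\t[ST]*-P-x-[RK]")[[1]]
  expect_identical(m$center_residues, c("S", "T"))
  expect_identical(m$allowed[[4]], c("R", "K"))
})

test_that("malformed motif lines fail with their line number", {
  expect_error(parse_motif_library(c("PKA\tR-R-x-S*", "BAD\tR-R-S")),
               "line 2")
  expect_error(parse_motif_library("K\tR-R-x-B*-x"), "residue")
  expect_error(parse_motif_library("K\tR-x-A*"), "S, T or Y")
  expect_error(parse_motif_library("K\tS*"), "non-wildcard")
  expect_error(parse_motif_library(c("PKA\tR-R-x-S*", "PKA\tR-R-x-S*")),
               "duplicate")
  expect_error(parse_motif_library("PKA only"), "kinase<TAB>pattern")
})

test_that("window matching respects center, offsets and padding", {
  pka <- parse_motif_library("PKA\tR-x-x-S*")[[1]]
  expect_true(match_motif("GGGRKASGGGGGG", pka))
  expect_false(match_motif("GGGAKASGGGGGG", pka))
  tonly <- parse_motif_library("K\tR-x-x-S*")[[1]]
  expect_false(match_motif("GGGRKATGGGGGG", tonly))
  # padding never satisfies a non-wildcard position
  expect_false(match_motif("GGG_KASGGGGGG", pka))
  expect_true(match_motif("___RKAS______", pka))
  expect_error(match_motif("SHORT", pka), "13 characters")
})

test_that("motif counts allow multi-attribution and explicit zeros", {
  lib <- parse_motif_library(c("K1\tR-x-x-S*", "K2\tS*-x-x-E",
                               "K3\tP-P-x-S*"))
  sites <- tibble::tibble(
    receptor = "A", comparison = "T3",
    site_id = c("s1", "s2"),
    sequence_window = c("GGGRGGSGGEGGG",   # matches K1 and K2
                        "GGGRGGSGGGGGG"))  # matches K1 only
  mc <- count_motifs(sites, lib)
  expect_identical(mc$count[mc$kinase == "K1"], 2L)
  expect_identical(mc$count[mc$kinase == "K2"], 1L)
  expect_identical(mc$count[mc$kinase == "K3"], 0L)
  expect_identical(unique(mc$total), 3L)
  # a kinase with two patterns is attributed once per site
  lib2 <- parse_motif_library(c("K1\tR-x-x-S*", "K1\tS*-x-x-E"))
  mc2 <- count_motifs(sites[1, ], lib2)
  expect_identical(mc2$count, 1L)
  expect_error(count_motifs(sites, structure(list(),
                                             class = "motif_library")),
               "non-empty")
})

test_that("counts are invariant to motif library order", {
  lib <- default_motif_library()
  cfg <- simulation_config(n_sites = 150L, frac_up = 0.3, frac_down = 0.1,
                           motif_library = lib, frac_motif_planted = 1,
                           seed = 31L)
  sim <- simulate_phosphosites(cfg)
  sites <- tibble::tibble(site_id = sim$table$site_id,
                          sequence_window = sim$table$sequence_window)
  perm <- structure(lib[rev(seq_along(lib))], class = "motif_library")
  a <- count_motifs(sites, lib)
  b <- count_motifs(sites, perm)
  b <- b[match(a$kinase, b$kinase), ]
  expect_identical(a$count, b$count)
})

test_that("percentage ratios follow the count arithmetic with sentinels", {
  mk <- function(counts) {
    tibble::tibble(kinase = paste0("K", seq_along(counts)), count = counts)
  }
  # equal percentages -> 1; direct arithmetic; zero numerator -> 0
  expect_equal(motif_percentage_ratio(mk(c(20, 80)), mk(c(10, 40)), "K1"), 1)
  expect_equal(motif_percentage_ratio(mk(c(30, 70)), mk(c(10, 90)), "K1"), 3)
  expect_equal(motif_percentage_ratio(mk(c(0, 100)), mk(c(5, 95)), "K1"), 0)
  # sentinels, never dropped
  expect_identical(motif_percentage_ratio(mk(c(5, 5)), mk(c(0, 10)), "K1"),
                   Inf)
  expect_true(is.nan(motif_percentage_ratio(mk(c(0, 5)), mk(c(0, 10)),
                                            "K1")))
  expect_error(motif_percentage_ratio(mk(c(0, 0)), mk(c(1, 1)), "K1"),
               "zero attribution total")
})

test_that("the ratio statistic is antisymmetric under receptor swap", {
  lib <- default_motif_library()
  counts <- do.call(rbind, lapply(c("A", "B"), function(r) {
    cfg <- simulation_config(n_sites = 200L, frac_up = 0.3, frac_down = 0.1,
                             motif_library = lib, frac_motif_planted = 1,
                             seed = if (r == "A") 41L else 42L)
    sim <- simulate_phosphosites(cfg)
    sites <- tibble::tibble(receptor = r, comparison = "T3",
                            site_id = sim$table$site_id,
                            sequence_window = sim$table$sequence_window)
    count_motifs(sites, lib)
  }))
  ab <- motif_ratio_table(counts, "A", "B")
  ba <- motif_ratio_table(counts, "B", "A")
  ba <- ba[match(ab$kinase, ba$kinase), ]
  finite <- is.finite(ab$ratio) & ab$ratio > 0
  expect_equal(ab$ratio[finite] * ba$ratio[finite],
               rep(1, sum(finite)))
})

test_that("planted motifs are recovered exactly without noise", {
  lib <- default_motif_library()
  sims <- lapply(c(A = 51L, B = 52L), function(s) {
    cfg <- simulation_config(n_sites = 400L, frac_up = 0.25,
                             frac_down = 0.15, noise_sigma = 0,
                             missing_rate = 0, motif_library = lib,
                             frac_motif_planted = 1, seed = s)
    simulate_phosphosites(cfg)
  })
  counts <- do.call(rbind, lapply(names(sims), function(r) {
    sim <- sims[[r]]
    calls <- call_sites_and_proteins(normalize_ratios(sim$table),
                                     comparison_design("T3", "s", "v"))
    reg <- calls$sites[calls$sites$label %in% c("up", "down"), ]
    count_motifs(tibble::tibble(receptor = r, comparison = "T3",
                                site_id = reg$site_id,
                                sequence_window = reg$sequence_window), lib)
  }))
  tab_get <- function(tb, k) {
    v <- as.numeric(tb[k])
    if (is.na(v)) 0 else v
  }
  for (r in names(sims)) {
    planted <- table(sims[[r]]$truth$planted_kinase)
    cr <- counts[counts$receptor == r, ]
    for (k in cr$kinase) {
      expect_identical(cr$count[cr$kinase == k],
                       as.integer(tab_get(planted, k)),
                       info = sprintf("receptor %s kinase %s", r, k))
    }
  }
  # percentage ratio equals the ratio computed from the planted truth
  rt <- motif_ratio_table(counts, "A", "B")
  pa <- table(sims$A$truth$planted_kinase)
  pb <- table(sims$B$truth$planted_kinase)
  for (i in seq_len(nrow(rt))) {
    k <- rt$kinase[i]
    a <- tab_get(pa, k)
    b <- tab_get(pb, k)
    truth_ratio <- if (a == 0 && b == 0) NaN
                   else if (b == 0) Inf
                   else (a / sum(pa)) / (b / sum(pb))
    expect_equal(rt$ratio[i], truth_ratio, info = k)
  }
})

test_that("kinases more active with one receptor are tallied strictly", {
  rt <- tibble::tibble(comparison = "T3",
                       kinase = c("K1", "K2", "K3", "K4", "K5"),
                       ratio = c(2, 1, 0.5, Inf, NaN))
  out <- count_kinases_more_active(rt)
  expect_identical(out$n_more_active, 2L)
})
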