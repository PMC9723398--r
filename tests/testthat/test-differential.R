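test_that("normalization centers each column's median log2 ratio at zero", {
  tab <- tiny_phospho_table(cbind(c(2, 4, 8), c(1, 1, 1), c(0.5, 2, 5)))
  out <- normalize_ratios(tab)
  expect_equal(out$ratio_T3_rep1, c(0.5, 1, 2))
  for (cl in grep("^ratio_", names(out), value = TRUE)) {
    expect_lt(abs(median(log2(out[[cl]]))), 1e-12)
  }
  # idempotence and order preservation
  expect_equal(normalize_ratios(out), out)
  expect_identical(out$site_id, tab$site_id)
  # single-value column normalizes to its own median
  tab1 <- tiny_phospho_table(matrix(5.0, 1, 1))
  expect_equal(normalize_ratios(tab1)$ratio_T3_rep1, 1.0)
})

test_that("normalization is equivariant to rescaling a replicate column", {
  tab <- tiny_phospho_table(matrix(c(1.2, 0.8, 2.5, 0.3, 1, 1.7), 3, 2))
  scaled <- tab
  scaled$ratio_T3_rep2 <- scaled$ratio_T3_rep2 * 37.5
  expect_equal(normalize_ratios(tab), normalize_ratios(scaled))
})

test_that("normalization rejects empty and nonpositive columns", {
  tab <- tiny_phospho_table(cbind(c(NA, NA, NA), c(1, 2, 3)))
  expect_error(normalize_ratios(tab), "ratio_T3_rep1")
  tab2 <- tiny_phospho_table(cbind(c(1, -2, 3)))
  expect_error(normalize_ratios(tab2), "s02")
  expect_error(normalize_ratios(tab2[0, ]), "no present values")
})

test_that("presence filtering keeps >= 2-of-3 and routes the rest", {
  tab <- tiny_phospho_table(rbind(c(1, 1, 1), c(1, 1, NA), c(1, NA, NA)))
  th <- regulation_thresholds()
  cmp <- comparison_design("T3", "stimulated", "vehicle")
  out <- filter_by_presence(tab, th, cmp)
  expect_identical(out$retained$site_id, c("s01", "s02"))
  expect_identical(out$not_quantified$site_id, "s03")
  expect_identical(out$retained$n_present, c(3L, 2L))
})

test_that("geometric mean matches direct arithmetic", {
  expect_equal(geometric_mean(c(4, 1)), 2)
  expect_equal(geometric_mean(c(2, 2, 2)), 2)
  expect_equal(geometric_mean(c(1.2, 1.8, 1.5)), (1.2 * 1.8 * 1.5)^(1 / 3))
  expect_equal(geometric_mean(c(1.5, 1.2, 1.8)),
               geometric_mean(c(1.2, 1.8, 1.5)))
  expect_error(geometric_mean(numeric(0)), "empty")
  expect_error(geometric_mean(c(1, 0)), "positive")
})

test_that("regulation labels use strict fold-change thresholds", {
  th <- regulation_thresholds()
  expect_identical(call_regulation(c(1.6, 0.5, 1.0), th),
                   c("up", "down", "unchanged"))
  # boundary values are unchanged under strict inequalities
  expect_identical(call_regulation(c(1.5, 0.67), th),
                   c("unchanged", "unchanged"))
  expect_error(call_regulation(-1, th), "positive")
  expect_error(regulation_thresholds(up_threshold = 0.9), "up_threshold")
  expect_error(regulation_thresholds(min_present = 4), "min_present")
})

test_that("site and protein calls aggregate directions per protein", {
  tab <- tiny_phospho_table(rbind(c(2, 2, 2), c(1, 1, 1), c(0.4, 0.4, 0.4),
                                  c(2, NA, NA)))
  tab$protein_id <- c("P1", "P1", "P2", "P3")
  cmp <- comparison_design("T3", "stimulated", "vehicle")
  out <- call_sites_and_proteins(tab, cmp)
  expect_identical(out$sites$label,
                   c("up", "unchanged", "down", "not_quantified"))
  p1 <- out$proteins[out$proteins$protein_id == "P1", ]
  expect_true(p1$regulated)
  expect_identical(p1$directions, "up")
  p2 <- out$proteins[out$proteins$protein_id == "P2", ]
  expect_identical(p2$directions, "down")
  p3 <- out$proteins[out$proteins$protein_id == "P3", ]
  expect_false(p3$regulated)
  # conflicting site directions are both reported, no net call
  tab2 <- tiny_phospho_table(rbind(c(2, 2, 2), c(0.4, 0.4, 0.4)))
  tab2$protein_id <- "P1"
  out2 <- call_sites_and_proteins(tab2, cmp)
  expect_identical(out2$proteins$directions, "up|down")
  # duplicate site identifiers are an error
  tab3 <- tab
  tab3$site_id <- rep("dup", 4)
  expect_error(call_sites_and_proteins(tab3, cmp), "duplicate")
})

test_that("calls partition input sites and are monotone in the threshold", {
  cfg <- simulation_config(n_sites = 400L, noise_sigma = 0.4,
                           missing_rate = 0.3, seed = 21L)
  tab <- simulate_phosphosites(cfg)$table
  cmp <- comparison_design("T3", "stimulated", "vehicle")
  for (th in list(regulation_thresholds(),
                  regulation_thresholds(min_present = 3L))) {
    out <- call_sites_and_proteins(tab, cmp, th)
    expect_identical(nrow(out$sites), 400L)
    expect_true(all(out$sites$label %in%
                      c("up", "down", "unchanged", "not_quantified")))
  }
  n_up <- vapply(c(1.2, 1.5, 2, 3), function(up) {
    th <- regulation_thresholds(up_threshold = up)
    sum(call_sites_and_proteins(tab, cmp, th)$sites$label == "up")
  }, numeric(1))
  expect_true(all(diff(n_up) <= 0))
})

test_that("noiseless synthetic data is recovered perfectly", {
  cfg <- simulation_config(n_sites = 300L, frac_up = 0.2, frac_down = 0.2,
                           noise_sigma = 0, missing_rate = 0, seed = 5L)
  sim <- simulate_phosphosites(cfg)
  out <- call_sites_and_proteins(normalize_ratios(sim$table),
                                 comparison_design("T3", "s", "v"))
  called <- out$sites$label[match(sim$truth$site_id, out$sites$site_id)]
  expect_identical(called, sim$truth$true_label)
})

test_that("set summaries count unique, coherent and discordant targets", {
  mk <- function(targets, labels) {
    tibble::tibble(target = targets, comparison = "T3", label = labels)
  }
  a <- mk(c("p1", "p2"), c("up", "up"))
  b <- mk(c("p2", "p3"), c("up", "down"))
  s <- summarize_sets(a, b, receptors = c("ACKR2", "CCR5"))
  expect_identical(s$overlap$unique_a, 1L)
  expect_identical(s$overlap$unique_b, 1L)
  expect_identical(s$overlap$shared_coherent, 1L)
  expect_identical(s$overlap$shared_discordant, 0L)
  expect_identical(s$kinetics$n_up, c(2L, 1L))
  expect_identical(s$kinetics$n_down, c(0L, 1L))
  # identical call sets share everything; disjoint sets share nothing
  s2 <- summarize_sets(a, a)
  expect_identical(s2$overlap$unique_a + s2$overlap$unique_b, 0L)
  expect_identical(s2$overlap$shared_coherent, 2L)
  s3 <- summarize_sets(a, mk("p9", "up"))
  expect_identical(s3$overlap$shared_coherent +
                     s3$overlap$shared_discordant, 0L)
  # discordant direction detected
  s4 <- summarize_sets(mk("p1", "up"), mk("p1", "down"))
  expect_identical(s4$overlap$shared_discordant, 1L)
  # mismatched comparison names are an error
  bad <- tibble::tibble(target = "p1", comparison = "T30", label = "up")
  expect_error(summarize_sets(a, bad), "comparison names differ")
})
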