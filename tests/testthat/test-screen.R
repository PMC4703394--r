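test_that("normalization is depth-invariant and sums to the target scale", {
  counts <- c(10, 0, 5, 85)
  n1 <- normalize_counts(counts)
  expect_equal(sum(n1), 1e7)
  expect_equal(normalize_counts(counts * 13), n1)
  # equal-depth libraries share a common factor
  expect_equal(normalize_counts(counts, total = 100),
               counts * 1e5)
  expect_error(normalize_counts(c(0, 0)), "zero mapped reads")
})

test_that("fold change follows the pseudocount rule", {
  fc <- fold_change(1000, 40)
  expect_equal(fc$fold_change, 1001 / 41)
  expect_equal(fc$fold_change_raw, 25)
  expect_equal(fold_change(77, 77)$fold_change, 1)
  fc0 <- fold_change(500, 0)
  expect_equal(fc0$fold_change, 501)
  expect_equal(fc0$fold_change_raw, Inf)
})

test_that("screen statistics are invariant to uniform depth scaling", {
  sim <- small_sim(seed = 91, n_genes = 30)
  scaled <- sim$libraries$T24
  scaled$count <- scaled$count * 7
  a <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  b <- run_screen(sim$libraries$T0, scaled, sim$annotations, sim$sites)
  expect_equal(a$u_stat, b$u_stat)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold_change, b$fold_change)
  expect_identical(a$is_hit, b$is_hit)
})

test_that("swapping reference and selected inverts the raw fold and keeps p", {
  sim <- small_sim(seed = 92, n_genes = 25)
  a <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  b <- run_screen(sim$libraries$T24, sim$libraries$T0, sim$annotations, sim$sites)
  b <- b[match(a$gene, b$gene), ]
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$fold_change_raw, 1 / b$fold_change_raw, tolerance = 1e-12)
})

test_that("hit calls are the conjunction of p, fold and coverage curation", {
  sim <- small_sim(
    seed = 93, n_genes = 40,
    classes = sim_gene_classes(40, n_defective = 5, w_defective = 0.01)
  )
  scr <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  cfg <- attr(scr, "config")
  expect_true(all(
    scr$is_hit == (!is.na(scr$p_value) & scr$p_value < cfg$alpha &
                     scr$fold_change > cfg$fold_min &
                     !grepl("low_coverage", scr$flags))
  ))
  expect_true(all(diff(scr$p_value) >= 0, na.rm = TRUE))  # sorted by p
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1, na.rm = TRUE))
  expect_true(all(scr$fold_change > 0, na.rm = TRUE))
})

test_that("a depleted gene with very few T0 insertions is flagged, not called", {
  # gene body 1..200 with TA sites; only 3 sites ever occupied at reference
  g <- random_genome(400, 94)
  sites <- find_ta_sites(g)
  stopifnot(length(sites) >= 14)
  occupied <- sites[1:4]
  lib_ref <- insertion_library(occupied, c(300, 280, 320, 310), "T0")
  lib_sel <- insertion_library(sites[length(sites)], 900, "T24")
  ann <- gene_annotations("gA", start = 1, end = max(sites[1:12]) + 1)
  scr <- run_screen(lib_ref, lib_sel, ann, sites)
  expect_match(scr$flags[1], "low_coverage")
  expect_false(scr$is_hit[1])
  expect_lt(scr$p_value[1], 0.05)           # would otherwise qualify
  expect_gt(scr$fold_change[1], 2)
})

test_that("modest depletion with retained occupancy carries the dispersed flag", {
  sim <- small_sim(seed = 95, n_genes = 20)
  scr <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  flagged <- grepl("dispersed", scr$flags)
  retention <- scr$n_sites_occupied_sel / scr$n_sites_occupied_ref
  # neutral genes (fold ~ 1, full retention) must all be flagged
  expect_true(all(flagged == (scr$fold_change < 3 & retention >= 0.8 - 1e-9)))
})

test_that("the volcano table caps p underflow and keeps one row per gene", {
  sim <- small_sim(seed = 96, n_genes = 15)
  scr <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  scr$p_value[1] <- 0  # simulate underflow
  v <- volcano_table(scr)
  expect_equal(nrow(v), nrow(scr))
  expect_equal(v$neg_log10_p[1], 320)
  expect_true(v$p_capped[1])
  expect_equal(v$neg_log10_p[v$gene == scr$gene[5]],
               -log10(scr$p_value[5]))
  # p = 0.05 maps to ~1.301
  scr$p_value[2] <- 0.05
  expect_equal(volcano_table(scr)$neg_log10_p[2], 1.30103, tolerance = 1e-5)
})

test_that("optional BH adjustment adds a column without changing calls", {
  sim <- small_sim(seed = 97, n_genes = 15)
  a <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites,
                  screen_config(adjust = TRUE))
  expect_true("p_adjusted" %in% names(a))
  expect_equal(a$p_adjusted, p.adjust(a$p_value, "BH"))
})

test_that("screen TSV export keeps the fixed leading column order", {
  sim <- small_sim(seed = 98, n_genes = 10)
  scr <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations, sim$sites)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(scr, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(
    hdr[1:11],
    c("gene", "locus_tag", "n_ta_sites", "t_ref_reads", "t_sel_reads",
      "fold_change", "u_stat", "p_value", "neg_log10_p", "flags", "is_hit")
  )
})
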