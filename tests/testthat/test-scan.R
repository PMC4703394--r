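test_that("eligible sites are exactly the both-occupied intersection", {
  g <- random_genome(5000, 111)
  sites <- find_ta_sites(g)
  a <- random_library(sites, seed = 1, occupancy = 0.6)
  b <- random_library(sites, seed = 2, occupancy = 0.6)
  track <- eligible_sites(a, b, sites)
  brute <- intersect(a$position[a$count >= 1], b$position[b$count >= 1])
  expect_setequal(track$position, brute)
  expect_true(all(diff(track$position) > 0))
  # disjoint occupancy -> empty track
  half <- length(sites) %/% 2
  la <- insertion_library(sites[1:half], rep(5, half))
  lb <- insertion_library(sites[(half + 1):length(sites)],
                          rep(5, length(sites) - half))
  expect_equal(nrow(eligible_sites(la, lb)), 0)
  # full occupancy -> full index
  lf <- insertion_library(sites, rep(2, length(sites)))
  expect_equal(eligible_sites(lf, lf)$position, sites)
})

test_that("identical libraries yield no significant windows", {
  g <- random_genome(4000, 112)
  sites <- find_ta_sites(g)
  lib <- random_library(sites, seed = 3, occupancy = 1)
  sc <- scan_windows(eligible_sites(lib, lib))
  expect_equal(sum(sc$significant), 0)
  expect_true(all(sc$p_value > 0.99))   # complete ties
  expect_true(all(sc$fold_enrichment == 1))
})

test_that("an enriched block is detected, merged, and peak-localized exactly", {
  # 400 eligible sites; sites 10..22 carry 10x selected enrichment (the
  # enriched block must be a small fraction of the library so that global
  # depth normalization does not absorb the enrichment)
  withr::local_seed(113)
  positions <- sort(sample(100000, 400))
  ref_counts <- rpois(400, 50) + 1
  sel_counts <- ref_counts
  block <- 10:22
  sel_counts[block] <- ref_counts[block] * 10
  ref <- insertion_library(positions, ref_counts, "T0")
  sel <- insertion_library(positions, sel_counts, "T5")
  track <- eligible_sites(ref, sel)
  windows <- scan_windows(track)
  # every window fully inside the block is significant
  inside <- windows$window >= min(block) & windows$window + 12 <= max(block)
  expect_true(all(windows$significant[inside]))
  # windows not touching the block are not
  outside <- windows$window + 12 < min(block) | windows$window > max(block)
  expect_false(any(windows$significant[outside]))
  regions <- merge_windows(windows, track)
  expect_equal(nrow(regions), 1)
  # union span covers the block; trimmed peak hits the block boundaries
  expect_lte(regions$start, positions[min(block)])
  expect_gte(regions$end, positions[max(block)])
  expect_equal(regions$peak_start, positions[min(block)])
  expect_equal(regions$peak_end, positions[max(block)])
})

test_that("window p-values agree with a Monte-Carlo permutation oracle", {
  withr::local_seed(114)
  positions <- sort(sample(10000, 20))
  ref <- insertion_library(positions, rpois(20, 30) + 1)
  sel <- insertion_library(positions, c(rpois(10, 30) + 1, rpois(10, 120) + 1))
  track <- eligible_sites(ref, sel)
  windows <- scan_windows(track)
  for (i in c(1, 4, 8)) {
    m <- i:(i + 12)
    p_mc <- mwu_mc_p(track$sel_norm[m], track$ref_norm[m], n_perm = 40000)
    tol <- 3 * sqrt(max(p_mc, 1e-4) * (1 - p_mc) / 40000) + 1e-3
    expect_lt(abs(windows$p_value[i] - p_mc), max(tol, 0.01))
  }
})

test_that("window merging equals an interval-union oracle on random masks", {
  withr::local_seed(115)
  ws <- 5
  n_sites <- 60
  positions <- sort(sample(1e5, n_sites))
  track <- tibble::tibble(
    position = positions,
    ref_raw = 1, sel_raw = 1,
    ref_norm = rep(1, n_sites), sel_norm = rep(1, n_sites)
  )
  for (rep in 1:100) {
    mask <- runif(n_sites - ws + 1) < 0.15
    windows <- tibble::tibble(
      window = seq_len(n_sites - ws + 1),
      first_pos = positions[seq_len(n_sites - ws + 1)],
      last_pos = positions[seq_len(n_sites - ws + 1) + ws - 1],
      u_stat = 0, p_value = 0.001, fold_enrichment = 10,
      significant = mask
    )
    attr(windows, "params") <- list(window_size = ws, p_max = 0.02,
                                    fold_min_enrich = 3)
    regions <- merge_windows(windows, track)
    # oracle: union of covered site indices, split into maximal runs
    covered <- sort(unique(unlist(lapply(which(mask), function(i) i:(i + ws - 1)))))
    if (length(covered) == 0) {
      expect_equal(nrow(regions), 0)
    } else {
      runs <- split(covered, cumsum(c(1, diff(covered) != 1)))
      expect_equal(nrow(regions), length(runs))
      expect_equal(regions$start, positions[vapply(runs, min, 0)])
      expect_equal(regions$end, positions[vapply(runs, max, 0)])
      expect_equal(sum(regions$member_window_count), sum(mask))
    }
  }
})

test_that("region classification follows midpoint and strand rules", {
  ann <- gene_annotations(
    gene = c("inGene", "plusGene", "minusGene"),
    start = c(1000, 5000, 8000), end = c(2000, 6000, 9000),
    strand = c("+", "+", "-")
  )
  mk <- function(start, end) {
    tibble::tibble(region_id = "r", start = start, end = end,
                   peak_start = start, peak_end = end,
                   n_eligible_sites = 5L, member_window_count = 1L,
                   min_p = 0.001, peak_fold = 5)
  }
  r1 <- classify_regions(mk(1200, 1600), ann)
  expect_equal(r1$class, "intragenic")
  expect_equal(r1$gene, "inGene")
  # midpoint 4700, 300 bp 5' of plusGene start
  r2 <- classify_regions(mk(4600, 4800), ann)
  expect_equal(r2$class, "upstream")
  expect_equal(r2$gene, "plusGene")
  # midpoint 9200, 200 bp 5' of minusGene (downstream side on -)
  r3 <- classify_regions(mk(9100, 9300), ann)
  expect_equal(r3$class, "upstream")
  expect_equal(r3$gene, "minusGene")
  # gene desert
  r4 <- classify_regions(mk(3000, 3200), ann)
  expect_equal(r4$class, "unassigned")
  expect_true(is.na(r4$gene))
})

test_that("the scan is invariant to uniform depth scaling of either library", {
  sim <- small_sim(seed = 116, n_genes = 15)
  scaled <- sim$libraries$T5
  scaled$count <- scaled$count * 5
  a <- scan_windows(eligible_sites(sim$libraries$T0, sim$libraries$T5))
  b <- scan_windows(eligible_sites(sim$libraries$T0, scaled))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$fold_enrichment, b$fold_enrichment)
  expect_identical(a$significant, b$significant)
})

test_that("a track shorter than one window warns and returns nothing", {
  track <- eligible_sites(insertion_library(c(4L, 10L), c(1, 1)),
                          insertion_library(c(4L, 10L), c(2, 2)))
  expect_warning(w <- scan_windows(track), "shorter than one window")
  expect_equal(nrow(w), 0)
})
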