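test_that("the simulator is fully deterministic under a fixed seed", {
  a <- small_sim(seed = 5)
  b <- small_sim(seed = 5)
  expect_identical(as.character(a$genome$seq), as.character(b$genome$seq))
  expect_identical(a$annotations, b$annotations)
  for (cond in names(a$libraries)) {
    expect_identical(a$libraries[[cond]]$position, b$libraries[[cond]]$position)
    expect_identical(a$libraries[[cond]]$count, b$libraries[[cond]]$count)
  }
  c <- small_sim(seed = 6)
  expect_false(identical(as.character(a$genome$seq), as.character(c$genome$seq)))
})

test_that("TA density and T0 saturation match their binomial models", {
  sim <- small_sim(seed = 21, n_genes = 100)
  L <- length(sim$genome)
  n_sites <- length(sim$sites)
  p0 <- 1 / 16
  se <- sqrt(p0 * (1 - p0) / (L - 1))
  expect_lt(abs(n_sites / (L - 1) - p0), 3 * se)

  occ_frac <- nrow(sim$clones) / n_sites
  se_occ <- sqrt(0.63 * 0.37 / n_sites)
  expect_lt(abs(occ_frac - 0.63), 3 * se_occ)
  # read totals follow the configured depth
  expect_equal(total_reads(sim$libraries$T0),
               round(50 * nrow(sim$clones)))
})

test_that("degenerate configurations behave as specified", {
  # zero genes: a genome with an empty annotation set
  g0 <- simulate_genome(sim_config(seed = 1, n_genes = 0))
  expect_equal(nrow(g0$annotations), 0)
  expect_gt(length(g0$genome), 0)
  # saturation zero: empty library
  cfg <- sim_config(seed = 2, n_genes = 10, saturation = 0)
  sim <- simulate_tnseq(cfg)
  expect_equal(nrow(sim$clones), 0)
  expect_equal(total_reads(sim$libraries$T0), 0)
  # genome too small for the genes
  expect_error(
    simulate_genome(sim_config(seed = 3, n_genes = 50, genome_length = 1000)),
    "cannot fit"
  )
})

test_that("essential genes never carry insertions", {
  cfg <- sim_config(
    seed = 31, n_genes = 30,
    gene_classes = sim_gene_classes(30, n_essential = 28)
  )
  sim <- simulate_tnseq(cfg)
  ess <- sim$truth$genes |> dplyr::filter(class == "essential")
  for (i in seq_len(nrow(ess))) {
    inside <- sites_in_gene(sim$sites, ess$start[i], ess$end[i])
    expect_equal(sum(sim$libraries$T0$position %in% inside), 0)
  }
  # non-essential genes in the same pool do get insertions
  expect_gt(nrow(sim$clones), 0)
})

test_that("neutral selection without a bottleneck preserves representation", {
  cfg <- sim_config(seed = 41, n_genes = 40, bottleneck_size = Inf)
  sim <- simulate_tnseq(cfg)
  scr <- run_screen(sim$libraries$T0, sim$libraries$T5, sim$annotations,
                    sim$sites)
  # every gene's fold change should be ~1 up to read-sampling noise
  expect_true(all(scr$fold_change > 0.8 & scr$fold_change < 1.25))
  expect_lt(abs(median(scr$fold_change) - 1), 0.05)
})

test_that("designed depletion factors are recovered in the expected fold range", {
  cfg <- sim_config(
    seed = 51, n_genes = 60,
    gene_classes = sim_gene_classes(60, n_defective = 8, w_defective = 0.01)
  )
  sim <- simulate_tnseq(cfg)
  scr <- run_screen(sim$libraries$T0, sim$libraries$T24, sim$annotations,
                    sim$sites)
  def <- sim$truth$genes$gene[sim$truth$genes$class == "spo_defective"]
  rows <- scr |> dplyr::filter(gene %in% def)
  expect_true(all(rows$is_hit))
  expect_gte(median(rows$fold_change), 50)
  expect_lte(median(rows$fold_change), 200)
  # delayed class depletes at T5 but recovers by T24
  cfg2 <- sim_config(
    seed = 52, n_genes = 60,
    gene_classes = sim_gene_classes(60, n_delayed = 8, w_delayed = 0.01)
  )
  sim2 <- simulate_tnseq(cfg2)
  s5 <- run_screen(sim2$libraries$T0, sim2$libraries$T5, sim2$annotations, sim2$sites)
  s24 <- run_screen(sim2$libraries$T0, sim2$libraries$T24, sim2$annotations, sim2$sites)
  del <- sim2$truth$genes$gene[sim2$truth$genes$class == "spo_delayed"]
  expect_true(all(s5$is_hit[s5$gene %in% del]))
  expect_false(any(s24$is_hit[s24$gene %in% del]))
})

test_that("selection errors out when every clone has zero weight", {
  clones <- tibble::tibble(position = c(10L, 30L), gene = "gX", abundance = c(1, 2))
  truth <- list(
    genes = tibble::tibble(gene = "gX", class = "spo_defective", fitness = 0,
                           start = 1L, end = 100L, strand = "+"),
    regions = tibble::tibble(region_id = character(), gene = character(),
                             class = character(), start = integer(),
                             end = integer(), fitness = numeric())
  )
  expect_error(apply_selection(clones, truth, sim_config(), "T5"), "zero")
})

test_that("emitted reads conserve library counts and skip edge sites with a warning", {
  sim <- small_sim(seed = 61, n_genes = 10)
  fq <- withr::local_tempfile(fileext = ".fastq")
  # first TA site of the genome cannot yield a reverse tag if too close to the start
  res <- suppressWarnings(emit_reads(sim$libraries$T0, sim$genome,
                                     sim$config, fq))
  skipped_positions <- sim$libraries$T0$position[
    sim$libraries$T0$position - sim$config$tag_length < 1 |
      sim$libraries$T0$position + 1 + sim$config$tag_length > length(sim$genome)
  ]
  skipped_reads <- sum(sim$libraries$T0$count[
    sim$libraries$T0$position %in% skipped_positions])
  expect_equal(res$n_reads, total_reads(sim$libraries$T0) - skipped_reads)
  expect_equal(length(readLines(fq)), 4 * res$n_reads)
  # empty library -> empty FASTQ
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  res2 <- emit_reads(insertion_library(integer(), integer()), sim$genome,
                     sim$config, fq2)
  expect_equal(res2$n_reads, 0)
  expect_equal(length(readLines(fq2)), 0)
})
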