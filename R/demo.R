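#' Write a run manifest
#'
#' Records the package version, seed, a hash of the configuration, MD5
#' checksums of input files, per-stage record counts and wall time, so that
#' deterministic stages can be audited for byte-identical reproduction.
#'
#' @param out_dir Directory the manifest is written into.
#' @param seed Master seed of the run.
#' @param config Configuration object (hashed).
#' @param inputs Character vector of input file paths (checksummed).
#' @param counts Named list of per-stage record counts.
#' @param started `proc.time()` snapshot taken at run start.
#' @return Path of `manifest.json`, invisibly.
#' @export
write_manifest <- function(out_dir, seed, config = NULL, inputs = character(),
                           counts = list(), started = NULL) {
  manifest <- list(
    tool = "tnspore",
    version = as.character(utils::packageVersion("tnspore")),
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else rlang::hash(config),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    record_counts = counts,
    wall_time_s = if (is.null(started)) NA_real_ else
      round(unname((proc.time() - started)["elapsed"]), 2)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end synthetic demonstration of the pipeline
#'
#' Simulates a 200-gene genome carrying 15 sporulation-defective genes, 10
#' delayed-only genes, 3 accelerator loci and a handful of essential genes;
#' emits junction reads for T0, T5 and T24 and maps them back to TA sites;
#' runs the depletion screen in its T24 configuration (p < 0.05, > 2-fold)
#' and its more stringent T5 configuration (> 5-fold); runs the 13-site
#' sliding-window enrichment scan on T0 vs T5; and writes result tables, a
#' markdown report with recovery confusion matrices against the designed
#' truth, and a run manifest.
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param n_genes,depth Scale knobs (genes; mean reads per occupied site).
#' @param emit_fastq Route libraries through FASTQ emission and read
#'   mapping (the full pipeline); `FALSE` screens the simulated count
#'   profiles directly.
#' @return Invisibly, a list with the screens, the scan, recovery metrics
#'   and output paths.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("tnspore_demo_"),
                     n_genes = 200, depth = 50, emit_fastq = TRUE) {
  started <- proc.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_acc_ko <- 1
  n_acc_oe <- 2
  config <- sim_config(
    seed = seed, n_genes = n_genes, mean_reads_per_site = depth,
    gene_classes = sim_gene_classes(
      n_genes, n_essential = 6, n_defective = 15, n_delayed = 10,
      n_accel_ko = n_acc_ko, n_accel_oe = n_acc_oe
    )
  )
  message("tnspore demo: simulating (seed ", seed, ", ", n_genes, " genes)")
  sim <- simulate_tnseq(config)
  write_genome_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_annotations_gff3(sim$annotations, file.path(out_dir, "annotations.gff3"),
                         genome_id = sim$genome$id)
  write_truth(sim$truth, out_dir)

  libs <- sim$libraries
  map_stats <- NULL
  if (emit_fastq) {
    tag_index <- build_tag_index(sim$genome, sim$sites, config$tag_length)
    mapped <- purrr::imap(sim$libraries, function(lib, cond) {
      fq <- file.path(out_dir, paste0("reads_", cond, ".fastq"))
      em <- emit_reads(lib, sim$genome, config, fq)
      mp <- map_reads(fq, tag_index, config$itr_motif)
      message(sprintf("  %s: emitted %d reads, mapped %d (%.2f%%)", cond,
                      em$n_reads, mp$stats$n_mapped,
                      100 * mp$stats$n_mapped / max(1, em$n_reads)))
      list(lib = mp$library, stats = mp$stats |> mutate(condition = cond))
    })
    libs <- purrr::map(mapped, "lib")
    map_stats <- purrr::map(mapped, "stats") |> bind_rows()
    readr::write_tsv(map_stats, file.path(out_dir, "mapping_stats.tsv"))
  }
  for (cond in names(libs)) {
    write_profile(libs[[cond]], file.path(out_dir, paste0("profile_", cond, ".tsv")))
  }

  message("tnspore demo: depletion screens")
  screen_t24 <- run_screen(libs$T0, libs$T24, sim$annotations, sim$sites,
                           screen_config(alpha = 0.05, fold_min = 2))
  screen_t5 <- run_screen(libs$T0, libs$T5, sim$annotations, sim$sites,
                          screen_config(alpha = 0.05, fold_min = 5))
  write_screen_tsv(screen_t24, file.path(out_dir, "screen_T0_vs_T24.tsv"))
  write_screen_tsv(screen_t5, file.path(out_dir, "screen_T0_vs_T5.tsv"))
  readr::write_tsv(volcano_table(screen_t24), file.path(out_dir, "volcano_T24.tsv"))
  readr::write_tsv(volcano_table(screen_t5), file.path(out_dir, "volcano_T5.tsv"))

  message("tnspore demo: sliding-window enrichment scan (T0 vs T5)")
  scan <- scan_enriched_regions(libs$T0, libs$T5, sim$annotations, sim$sites)
  write_regions(scan$regions, file.path(out_dir, "enriched_regions.tsv"),
                genome_id = sim$genome$id)

  truth_genes <- sim$truth$genes
  conf <- function(screen, classes) {
    hits <- screen$gene[screen$is_hit]
    tg <- truth_genes |> filter(.data$class %in% classes)
    neutral <- truth_genes |> filter(.data$class == "neutral")
    tibble(
      n_true = nrow(tg),
      n_recovered = sum(tg$gene %in% hits),
      recall = sum(tg$gene %in% hits) / max(1, nrow(tg)),
      n_neutral = nrow(neutral),
      n_false = sum(neutral$gene %in% hits),
      false_hit_rate = sum(neutral$gene %in% hits) / max(1, nrow(neutral))
    )
  }
  rec_t24 <- conf(screen_t24, "spo_defective")
  rec_t5 <- conf(screen_t5, c("spo_defective", "spo_delayed"))
  region_overlap <- purrr::map_lgl(seq_len(nrow(sim$truth$regions)), function(i) {
    any(scan$regions$start <= sim$truth$regions$end[i] &
          scan$regions$end >= sim$truth$regions$start[i])
  })
  metrics <- list(
    defective_recall_t24 = rec_t24$recall,
    neutral_false_hit_rate_t24 = rec_t24$false_hit_rate,
    delayed_defective_recall_t5 = rec_t5$recall,
    n_truth_regions = nrow(sim$truth$regions),
    n_regions_reported = nrow(scan$regions),
    n_truth_regions_recovered = sum(region_overlap)
  )

  report <- c(
    "# tnspore synthetic demonstration",
    "",
    sprintf("Seed %d; %d genes; %d TA sites; %d T0 clones.",
            seed, n_genes, length(sim$sites), nrow(sim$clones)),
    "",
    "## Depletion screen, T0 vs T24 (p < 0.05, fold > 2)",
    knit_tibble(glance(screen_t24)),
    "",
    sprintf("Defective-gene recovery: %d/%d (recall %.2f); neutral false hits: %d/%d.",
            rec_t24$n_recovered, rec_t24$n_true, rec_t24$recall,
            rec_t24$n_false, rec_t24$n_neutral),
    "",
    "## Depletion screen, T0 vs T5 (p < 0.05, fold > 5)",
    knit_tibble(glance(screen_t5)),
    "",
    sprintf("Defective+delayed recovery: %d/%d (recall %.2f); neutral false hits: %d/%d.",
            rec_t5$n_recovered, rec_t5$n_true, rec_t5$recall,
            rec_t5$n_false, rec_t5$n_neutral),
    "",
    "## Enrichment scan, T0 vs T5 (13 eligible sites, p <= 0.02, fold >= 3)",
    knit_tibble(glance(scan)),
    "",
    sprintf("Accelerator-locus recovery: %d/%d truth loci overlapped by reported regions (%d reported).",
            sum(region_overlap), nrow(sim$truth$regions), nrow(scan$regions)),
    "",
    "## Top depleted genes at T24",
    knit_tibble(head(as_tibble(screen_t24) |>
                       select("gene", "n_ta_sites", "fold_change", "p_value", "is_hit"), 10))
  )
  writeLines(report, file.path(out_dir, "report.md"))

  write_manifest(
    out_dir, seed, config,
    inputs = file.path(out_dir, c("genome.fasta", "annotations.gff3",
                                  paste0("reads_", names(libs), ".fastq"))),
    counts = c(
      list(ta_sites = length(sim$sites), t0_clones = nrow(sim$clones)),
      purrr::map(libs, total_reads),
      list(genes_screened = nrow(screen_t24), scan_windows = nrow(scan$windows),
           regions = nrow(scan$regions))
    ),
    started = started
  )
  message("tnspore demo: done -> ", out_dir)
  invisible(list(
    out_dir = out_dir, sim = sim, screen_t24 = screen_t24,
    screen_t5 = screen_t5, scan = scan, map_stats = map_stats,
    metrics = metrics
  ))
}

## minimal markdown table rendering for the demo report
knit_tibble <- function(d) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
  }
  cells <- purrr::map(d, fmt)
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  rows <- purrr::map_chr(seq_len(nrow(d)), function(i) {
    paste0("| ", paste(purrr::map_chr(cells, i), collapse = " | "), " |")
  })
  paste(c(header, sep, rows), collapse = "\n")
}
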