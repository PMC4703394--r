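#' Configuration for the synthetic Tn-seq library simulator
#'
#' The generator emulates the structure of a saturating Mariner insertion
#' library passed through a heat-kill selection: a transformant pool whose
#' clone abundances are lognormally dispersed, insertion of the transposon at
#' a fixed fraction of TA sites (the screen this package models saturated 63%
#' of all TA dinucleotides, ~26 unique insertions per gene), per-gene fitness
#' factors applied through a single multinomial selection bottleneck
#' (~750,000 surviving colonies are pooled in the modelled protocol), and
#' multinomial read sampling of the surviving pool.
#'
#' @param seed Master seed; every stage draws from a named sub-stream of it.
#' @param n_genes Number of genes to tile onto the simulated genome.
#' @param mean_gene_length Mean gene length in bp. The default 660 bp gives
#'   ~41 TA sites per gene (TA density 1/16), i.e. ~26 occupied sites at 63%
#'   saturation, matching the modelled library.
#' @param mean_intergenic Mean intergenic gap in bp.
#' @param genome_length Genome length in bp; `NULL` (default) sizes the
#'   genome to exactly fit the tiled genes and gaps.
#' @param saturation Fraction of TA sites carrying an insertion at T0.
#' @param lognormal_sigma Log-scale SD of clone abundances at T0 (jackpot
#'   effects in pooled transformant libraries).
#' @param mean_reads_per_site Expected sequencing depth per occupied site.
#' @param bottleneck_size Number of surviving clones drawn at selection
#'   (single multinomial draw); `Inf` disables resampling.
#' @param gene_classes Per-gene fitness-class table from [sim_gene_classes()]
#'   (columns `gene_index`, `class`, `fitness`); `NULL` makes every gene
#'   neutral.
#' @param accel_region_bp Width (bp) of the enriched upstream window modelled
#'   for `accelerator_OE` genes.
#' @param tag_length Genomic tag length on simulated junction reads (MmeI
#'   releases ~16 nt of genomic sequence).
#' @param itr_motif Transposon inverted-terminal-repeat sequence placed 5' of
#'   the tag on simulated reads.
#' @param adapter Constant adapter filler placed 3' of the tag.
#' @param substitution_rate Per-base substitution error rate on emitted reads.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       mean_gene_length = 660,
                       mean_intergenic = 140,
                       genome_length = NULL,
                       saturation = 0.63,
                       lognormal_sigma = 0.5,
                       mean_reads_per_site = 50,
                       bottleneck_size = 7.5e5,
                       gene_classes = NULL,
                       accel_region_bp = 500,
                       tag_length = 16,
                       itr_motif = TNSPORE_ITR,
                       adapter = TNSPORE_ADAPTER,
                       substitution_rate = 0) {
  if (saturation <= 0 && saturation > 1) tn_stop("saturation must be in (0, 1]")
  if (saturation < 0 || saturation > 1) tn_stop("saturation must be in [0, 1]")
  if (mean_reads_per_site <= 0) tn_stop("mean_reads_per_site must be positive")
  if (tag_length < 10) tn_stop("tag_length must be >= 10")
  cfg <- list(
    seed = seed, n_genes = n_genes, mean_gene_length = mean_gene_length,
    mean_intergenic = mean_intergenic, genome_length = genome_length,
    saturation = saturation, lognormal_sigma = lognormal_sigma,
    mean_reads_per_site = mean_reads_per_site, bottleneck_size = bottleneck_size,
    gene_classes = gene_classes, accel_region_bp = accel_region_bp,
    tag_length = tag_length, itr_motif = itr_motif, adapter = adapter,
    substitution_rate = substitution_rate
  )
  structure(cfg, class = "sim_config")
}

#' Designed per-gene fitness classes
#'
#' Builds the `gene_classes` table for [sim_config()]. Classes:
#' `neutral` (selection factor 1), `essential` (no insertions tolerated at
#' T0), `spo_defective` (factor `w_defective` at both T5 and T24),
#' `spo_delayed` (factor `w_delayed` at T5 only), and the two accelerator
#' classes whose loci are *enriched* at T5 only (factor `w_accel > 1`):
#' `accelerator_KO` (insertions in the gene body inactivate a sporulation
#' brake) and `accelerator_OE` (insertions upstream over-express an
#' initiation-promoting locus). Special genes are placed at evenly spaced
#' gene indices, with accelerator loci maximally separated, so that enriched
#' regions never abut.
#'
#' @param n_genes Total genes.
#' @param n_essential,n_defective,n_delayed,n_accel_ko,n_accel_oe Counts per
#'   special class.
#' @param w_defective,w_delayed Fitness factors (< 1) for depleted classes.
#' @param w_accel Enrichment factor (> 1) for accelerator loci at T5.
#' @return A tibble with columns `gene_index`, `class`, `fitness`.
#' @export
sim_gene_classes <- function(n_genes,
                             n_essential = 0, n_defective = 0, n_delayed = 0,
                             n_accel_ko = 0, n_accel_oe = 0,
                             w_defective = 0.01, w_delayed = 0.01,
                             w_accel = 10) {
  k <- n_essential + n_defective + n_delayed + n_accel_ko + n_accel_oe
  if (k > n_genes) tn_stop("more special genes than genes")
  out <- tibble(gene_index = seq_len(n_genes), class = "neutral", fitness = 1)
  if (k == 0) return(out)
  slots <- unique(round(seq(2, n_genes - 1, length.out = k)))
  if (length(slots) < k) tn_stop("too many special genes to separate on ", n_genes, " genes")
  labels <- character(k)
  n_accel <- n_accel_ko + n_accel_oe
  accel_lab <- c(rep("accelerator_KO", n_accel_ko), rep("accelerator_OE", n_accel_oe))
  if (n_accel > 0) {
    at <- unique(round(seq(1, k, length.out = n_accel)))
    labels[at] <- accel_lab
  }
  rest <- c(rep("essential", n_essential), rep("spo_defective", n_defective),
            rep("spo_delayed", n_delayed))
  labels[labels == ""] <- rest
  w <- c(neutral = 1, essential = NA_real_, spo_defective = w_defective,
         spo_delayed = w_delayed, accelerator_KO = w_accel, accelerator_OE = w_accel)
  out$class[slots] <- labels
  out$fitness[slots] <- unname(w[labels])
  out
}

#' Simulate a genome with tiled gene annotations
#'
#' Bases are i.i.d. uniform (expected TA density 1/16 per position); genes
#' are non-overlapping, tiled left to right with exponential intergenic gaps
#' and gamma-distributed lengths.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [tn_genome()]) and `annotations`
#'   (a [gene_annotations()] tibble).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "genome", {
    n <- config$n_genes
    if (n > 0) {
      len <- pmax(100, round(rgamma(n, shape = 20, rate = 20 / config$mean_gene_length)))
      gap <- pmax(30, round(rexp(n + 1, 1 / config$mean_intergenic)))
      starts <- cumsum(gap[seq_len(n)]) + cumsum(c(0, len[-n])) + 1
      ends <- starts + len - 1
      needed <- ends[n] + gap[n + 1]
    } else {
      starts <- ends <- integer(0)
      needed <- 1000
    }
    L <- config$genome_length %||% needed
    if (n > 0 && needed > L) {
      tn_stop("genes cannot fit: need ", needed, " bp, genome_length is ", L)
    }
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    classes <- config$gene_classes %||%
      tibble(gene_index = seq_len(n), class = "neutral", fitness = 1)
    ann <- gene_annotations(
      gene = sprintf("g%04d", seq_len(n)),
      locus_tag = sprintf("TNS_%04d", seq_len(n)),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_essential = classes$class[match(seq_len(n), classes$gene_index)] == "essential",
      genome_length = L
    )
    list(genome = tn_genome(seq, id = "sim_genome"), annotations = ann)
  })
}

#' Designed ground truth of a simulated experiment
#'
#' @param annotations Annotation tibble from [simulate_genome()].
#' @param config A [sim_config()].
#' @param genome_length Genome length (for clipping upstream regions).
#' @return A list with `genes` (gene, class, fitness, coordinates) and
#'   `regions` (accelerator loci: the gene body for `accelerator_KO`, the
#'   strand-aware upstream window for `accelerator_OE`).
#' @export
simulation_truth <- function(annotations, config, genome_length) {
  classes <- config$gene_classes %||%
    tibble(gene_index = seq_len(nrow(annotations)), class = "neutral", fitness = 1)
  genes <- annotations |>
    mutate(
      class = classes$class[match(dplyr::row_number(), classes$gene_index)],
      fitness = classes$fitness[match(dplyr::row_number(), classes$gene_index)]
    )
  acc <- genes |> filter(.data$class %in% c("accelerator_KO", "accelerator_OE"))
  regions <- if (nrow(acc) == 0) {
    tibble(region_id = character(), gene = character(), class = character(),
           start = integer(), end = integer(), fitness = numeric())
  } else {
    up <- config$accel_region_bp
    tibble(
      region_id = sprintf("accel_%02d", seq_len(nrow(acc))),
      gene = acc$gene,
      class = acc$class,
      start = ifelse(acc$class == "accelerator_KO", acc$start,
                     ifelse(acc$strand == "+", pmax(1L, acc$start - up), acc$end + 1L)),
      end = ifelse(acc$class == "accelerator_KO", acc$end,
                   ifelse(acc$strand == "+", acc$start - 1L,
                          pmin(genome_length, acc$end + up))),
      fitness = acc$fitness
    )
  }
  list(genes = genes, regions = regions)
}

#' Simulate the T0 insertion library
#'
#' Each TA site is occupied independently with probability `saturation`,
#' except sites inside essential genes (never occupied). Occupied-clone
#' abundances are lognormal(0, `lognormal_sigma`^2); reads are a single
#' multinomial draw with expected depth `mean_reads_per_site` per occupied
#' site.
#'
#' @param sites TA-site index of the genome.
#' @param truth Truth object from [simulation_truth()].
#' @param config A [sim_config()].
#' @return A list with `clones` (tibble: position, gene, abundance for every
#'   occupied site) and `library` (insertion-library tibble of T0 read
#'   counts).
#' @export
simulate_t0_library <- function(sites, truth, config) {
  with_substream(config$seed, "t0", {
    site_gene <- assign_sites_to_genes(sites, truth$genes) |>
      distinct(.data$position, .keep_all = TRUE)
    ess <- truth$genes$gene[truth$genes$class == "essential"]
    banned <- site_gene$position[site_gene$gene %in% ess]
    occ <- sites[runif(length(sites)) < config$saturation]
    occ <- setdiff(occ, banned)
    clones <- tibble(
      position = occ,
      gene = site_gene$gene[match(occ, site_gene$position)],
      abundance = rlnorm(length(occ), 0, config$lognormal_sigma)
    )
    if (nrow(clones) == 0) {
      return(list(clones = clones,
                  library = insertion_library(integer(), integer(), "T0", "sim_genome")))
    }
    total <- round(config$mean_reads_per_site * nrow(clones))
    counts <- as.vector(rmultinom(1, total, clones$abundance))
    keep <- counts > 0
    lib <- insertion_library(clones$position[keep], counts[keep],
                             condition = "T0", genome_id = "sim_genome")
    list(clones = clones, library = lib)
  })
}

## selection factor per clone for a given timepoint label
clone_selection_weights <- function(clones, truth, label) {
  g <- truth$genes
  cls <- g$class[match(clones$gene, g$gene)]
  fit <- g$fitness[match(clones$gene, g$gene)]
  cls[is.na(cls)] <- "neutral"
  w <- rep(1, nrow(clones))
  if (label == "T24") {
    w[cls == "spo_defective"] <- fit[cls == "spo_defective"]
  } else {
    w[cls %in% c("spo_defective", "spo_delayed")] <-
      fit[cls %in% c("spo_defective", "spo_delayed")]
  }
  ## accelerator loci: transient enrichment at T5 only (positional, so
  ## intergenic clones inside an upstream window are boosted too)
  if (label != "T24" && nrow(truth$regions) > 0) {
    for (i in seq_len(nrow(truth$regions))) {
      hit <- clones$position >= truth$regions$start[i] &
        clones$position + 1 <= truth$regions$end[i]
      w[hit] <- truth$regions$fitness[i]
    }
  }
  w
}

#' Pass the T0 clone pool through the heat-kill selection
#'
#' Each clone's sampling weight is its T0 abundance times the selection
#' factor of the gene (or accelerator region) containing its insertion site;
#' neutral and intergenic clones have factor 1. `bottleneck_size` survivors
#' are drawn in one multinomial draw, then reads are drawn multinomially
#' from the survivors at the configured depth. Accelerator loci are enriched
#' at T5 and neutral again at T24.
#'
#' @param clones Clone table from [simulate_t0_library()].
#' @param truth Truth object from [simulation_truth()].
#' @param config A [sim_config()].
#' @param label Timepoint label, `"T5"` or `"T24"`.
#' @return An insertion-library tibble for the selected timepoint.
#' @export
apply_selection <- function(clones, truth, config, label = "T5") {
  with_substream(config$seed, paste0("selection_", label), {
    if (nrow(clones) == 0) {
      return(insertion_library(integer(), integer(), condition = label,
                               genome_id = "sim_genome"))
    }
    w <- clone_selection_weights(clones, truth, label)
    weights <- clones$abundance * w
    if (all(weights == 0)) tn_stop("all clone weights are zero at ", label)
    total <- round(config$mean_reads_per_site * nrow(clones))
    pool <- if (is.infinite(config$bottleneck_size)) {
      weights
    } else {
      as.vector(rmultinom(1, config$bottleneck_size, weights))
    }
    counts <- as.vector(rmultinom(1, total, pool))
    keep <- counts > 0
    insertion_library(clones$position[keep], counts[keep],
                      condition = label, genome_id = "sim_genome")
  })
}

#' Run the full synthetic Tn-seq experiment
#'
#' Simulates genome, annotations, the T0 library, and heat-selected T5 and
#' T24 libraries, together with the designed ground truth. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `tn_simulation` with elements `genome`,
#'   `annotations`, `sites`, `truth`, `clones`, and `libraries`
#'   (named list `T0`, `T5`, `T24`).
#' @export
simulate_tnseq <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  sites <- find_ta_sites(gen$genome)
  truth <- simulation_truth(gen$annotations, config, length(gen$genome))
  t0 <- simulate_t0_library(sites, truth, config)
  libs <- list(
    T0 = t0$library,
    T5 = apply_selection(t0$clones, truth, config, "T5"),
    T24 = apply_selection(t0$clones, truth, config, "T24")
  )
  structure(
    list(genome = gen$genome, annotations = gen$annotations, sites = sites,
         truth = truth, clones = t0$clones, libraries = libs, config = config),
    class = "tn_simulation"
  )
}

#' @export
print.tn_simulation <- function(x, ...) {
  cat(sprintf(
    "<tn_simulation> %d bp, %d genes, %d TA sites, %d clones; libraries: %s\n",
    length(x$genome), nrow(x$annotations), length(x$sites), nrow(x$clones),
    paste(sprintf("%s=%d reads", names(x$libraries),
                  vapply(x$libraries, total_reads, 0)), collapse = ", ")
  ))
  invisible(x)
}

#' Emit simulated transposon-junction reads
#'
#' One read per tallied count: the transposon ITR, then `tag_length` genomic
#' bases immediately 3' of the TA site on a uniformly chosen strand (the
#' MmeI-released genomic tag), then constant adapter filler; qualities are
#' constant Q40. Sites whose tag would extend beyond a genome end are
#' skipped with a warning.
#'
#' @param lib Insertion-library tibble.
#' @param genome A [tn_genome()].
#' @param config A [sim_config()] (tag length, ITR, adapter, error rate).
#' @param path Output FASTQ path (plain or `.gz`).
#' @return Invisibly, a list with `path`, `n_reads` written and
#'   `n_sites_skipped`.
#' @export
emit_reads <- function(lib, genome, config, path) {
  cond <- attr(lib, "condition") %||% "lib"
  with_substream(config$seed, paste0("reads_", cond), {
    L <- config$tag_length
    glen <- length(genome)
    gseq <- as.character(genome$seq)
    ok <- lib$position + 1 + L <= glen & lib$position - L >= 1
    if (any(!ok)) {
      warn(sprintf("emit_reads: %d site(s) skipped (tag extends beyond genome end)",
                   sum(!ok)))
    }
    use <- lib[ok, ]
    pos <- rep(use$position, use$count)
    n <- length(pos)
    if (n > 0) {
      fwd <- runif(n) < 0.5
      tags <- character(n)
      tags[fwd] <- substring(gseq, pos[fwd] + 2, pos[fwd] + 1 + L)
      if (any(!fwd)) {
        tags[!fwd] <- revcomp_chr(substring(gseq, pos[!fwd] - L, pos[!fwd] - 1))
      }
      reads <- paste0(config$itr_motif, tags, config$adapter)
      if (config$substitution_rate > 0) {
        reads <- mutate_reads(reads, config$substitution_rate)
      }
      ids <- sprintf("@tnspore_%s_%07d", cond, seq_len(n))
      qual <- strrep("I", nchar(reads))
      lines <- as.vector(rbind(ids, reads, "+", qual))
    } else {
      lines <- character(0)
    }
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
    invisible(list(path = path, n_reads = n, n_sites_skipped = sum(!ok)))
  })
}

## uniform substitution errors at rate `rate` per base
mutate_reads <- function(reads, rate) {
  m <- strsplit(reads, "", fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  vapply(m, function(ch) {
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), "")
    }
    paste(ch, collapse = "")
  }, "")
}

#' Write the designed truth tables to disk
#'
#' @param truth Truth object from [simulation_truth()].
#' @param dir Output directory.
#' @return Paths of the written TSVs, invisibly.
#' @export
write_truth <- function(truth, dir) {
  pg <- file.path(dir, "truth_genes.tsv")
  pr <- file.path(dir, "truth_regions.tsv")
  readr::write_tsv(truth$genes, pg)
  readr::write_tsv(truth$regions, pr)
  invisible(c(pg, pr))
}
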