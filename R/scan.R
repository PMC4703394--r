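#' Track of TA sites eligible for the sliding-window scan
#'
#' The enrichment scan runs across all TA sites that register at least one
#' raw read in *both* compared libraries, in genomic order.
#'
#' @param lib_ref,lib_sel Insertion-library tibbles (e.g. T0 and T5).
#' @param sites Optional TA-site index for validation and normalization
#'   context (totals are taken from the libraries themselves).
#' @return A tibble: `position`, `ref_raw`, `sel_raw`, `ref_norm`,
#'   `sel_norm`, sorted by position.
#' @export
eligible_sites <- function(lib_ref, lib_sel, sites = NULL) {
  if (!is.null(sites)) {
    if (!all(lib_ref$position %in% sites) || !all(lib_sel$position %in% sites)) {
      tn_stop("library contains positions absent from the TA-site index")
    }
  }
  ref_total <- total_reads(lib_ref)
  sel_total <- total_reads(lib_sel)
  inner <- dplyr::inner_join(
    lib_ref |> rename(ref_raw = "count"),
    lib_sel |> rename(sel_raw = "count"),
    by = "position"
  ) |>
    filter(.data$ref_raw >= 1, .data$sel_raw >= 1) |>
    arrange(.data$position)
  inner |>
    mutate(
      ref_norm = normalize_counts(.data$ref_raw, total = ref_total),
      sel_norm = normalize_counts(.data$sel_raw, total = sel_total)
    )
}

#' Sliding-window Mann-Whitney enrichment scan
#'
#' Slides a window of `window_size` consecutive eligible TA sites (step one
#' site) along the track. Each window compares the normalized selected
#' versus reference per-site counts with an exact two-sided Mann-Whitney U
#' test (the exact conditional null is enumerated for every window; at
#' n = 13 per group this is cheap) and computes the enrichment
#' `sum(sel_norm) / sum(ref_norm)`. A window is significant when
#' `p <= p_max` *and* enrichment `>= fold_min_enrich`.
#'
#' @param track Eligible-site track from [eligible_sites()].
#' @param window_size Number of eligible sites per window.
#' @param p_max Window significance threshold on the exact p-value.
#' @param fold_min_enrich Minimal selected/reference enrichment.
#' @return A tibble, one row per window: `window` (index of the first
#'   eligible site), `first_pos`, `last_pos`, `u_stat`, `p_value`,
#'   `fold_enrichment`, `significant`. Carries the scan parameters as
#'   attributes.
#' @export
scan_windows <- function(track, window_size = 13, p_max = 0.02,
                         fold_min_enrich = 3) {
  n <- nrow(track)
  nw <- n - window_size + 1
  if (nw < 1) {
    warn("track shorter than one window; no scan performed")
    out <- tibble(window = integer(), first_pos = integer(), last_pos = integer(),
                  u_stat = numeric(), p_value = numeric(),
                  fold_enrichment = numeric(), significant = logical())
    attr(out, "params") <- list(window_size = window_size, p_max = p_max,
                                fold_min_enrich = fold_min_enrich)
    return(out)
  }
  refn <- track$ref_norm
  seln <- track$sel_norm
  ## rolling sums for the fold; exact MWU per window
  csr <- cumsum(c(0, refn))
  css <- cumsum(c(0, seln))
  ref_sums <- csr[(window_size + 1):(n + 1)] - csr[1:nw]
  sel_sums <- css[(window_size + 1):(n + 1)] - css[1:nw]
  p <- numeric(nw)
  u <- numeric(nw)
  for (i in seq_len(nw)) {
    m <- i:(i + window_size - 1)
    mw <- mann_whitney_u(seln[m], refn[m], exact = TRUE)
    p[i] <- mw$p.value
    u[i] <- mw$statistic
  }
  fold <- sel_sums / ref_sums
  out <- tibble(
    window = seq_len(nw),
    first_pos = track$position[seq_len(nw)],
    last_pos = track$position[seq_len(nw) + window_size - 1],
    u_stat = u,
    p_value = p,
    fold_enrichment = fold,
    significant = p <= p_max & fold >= fold_min_enrich
  )
  attr(out, "params") <- list(window_size = window_size, p_max = p_max,
                              fold_min_enrich = fold_min_enrich)
  out
}

#' Merge significant windows into enriched regions
#'
#' Significant windows sharing at least one eligible site are merged
#' (interval union over eligible-site indices). Each region reports the
#' union span in genomic TA coordinates (`start`/`end`: min/max TA position
#' over member windows) and trimmed peak boundaries (`peak_start`/
#' `peak_end`): the outermost eligible sites whose own normalized
#' selected/reference ratio reaches the window fold threshold. The union
#' span overstates an enriched locus by up to half a window on each side,
#' because a window is already significant when roughly two-thirds of its
#' sites are enriched; the peak boundaries are the localization estimate.
#'
#' @param windows Window table from [scan_windows()].
#' @param track The eligible-site track the windows were computed on.
#' @return A tibble, one row per region: `region_id`, `start`, `end`,
#'   `peak_start`, `peak_end`, `n_eligible_sites`, `member_window_count`,
#'   `min_p`, `peak_fold`.
#' @export
merge_windows <- function(windows, track) {
  params <- attr(windows, "params")
  ws <- params$window_size
  sig <- windows |> filter(.data$significant)
  empty <- tibble(
    region_id = character(), start = integer(), end = integer(),
    peak_start = integer(), peak_end = integer(),
    n_eligible_sites = integer(), member_window_count = integer(),
    min_p = numeric(), peak_fold = numeric()
  )
  if (nrow(sig) == 0) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(start = sig$window, width = ws))
  site_fold <- track$sel_norm / track$ref_norm
  out <- purrr::map(seq_along(ir), function(k) {
    i1 <- BiocGenerics::start(ir)[k]
    i2 <- BiocGenerics::end(ir)[k]
    members <- sig |> filter(.data$window >= i1, .data$window <= i2 - ws + 1)
    span <- i1:i2
    hot <- span[site_fold[span] >= params$fold_min_enrich]
    if (length(hot) == 0) {
      ## degenerate: fall back to the span of member-window centers
      ctr <- (ws - 1) / 2
      hot <- c(min(members$window) + ctr, max(members$window) + ctr)
    }
    tibble(
      region_id = NA_character_,
      start = track$position[i1],
      end = track$position[i2],
      peak_start = track$position[min(hot)],
      peak_end = track$position[max(hot)],
      n_eligible_sites = length(span),
      member_window_count = nrow(members),
      min_p = min(members$p_value),
      peak_fold = max(members$fold_enrichment)
    )
  }) |> bind_rows()
  out$region_id <- sprintf("region_%03d", seq_len(nrow(out)))
  out
}

#' Classify enriched regions relative to gene models
#'
#' A region is `intragenic` when its midpoint lies inside a gene body
#' (insertions likely inactivate that gene); otherwise it is `upstream` of
#' the nearest downstream gene on either strand within `upstream_bp`
#' (insertions likely over-express the adjacent locus); otherwise
#' `unassigned`.
#'
#' @param regions Region table from [merge_windows()].
#' @param annotations Gene-annotation tibble.
#' @param upstream_bp Maximal distance to the downstream gene start.
#' @return `regions` with added columns `class`, `gene`, `distance_bp`.
#' @export
classify_regions <- function(regions, annotations, upstream_bp = 500) {
  if (nrow(regions) == 0) {
    return(regions |> mutate(class = character(0), gene = character(0),
                             distance_bp = numeric(0)))
  }
  res <- purrr::map(seq_len(nrow(regions)), function(k) {
    mid <- floor((regions$start[k] + regions$end[k]) / 2)
    inside <- annotations |> filter(.data$start <= mid, .data$end >= mid)
    if (nrow(inside) > 0) {
      return(tibble(class = "intragenic", gene = inside$gene[1], distance_bp = 0))
    }
    plus <- annotations |>
      filter(.data$strand == "+", .data$start > mid) |>
      mutate(distance_bp = .data$start - mid)
    minus <- annotations |>
      filter(.data$strand == "-", .data$end < mid) |>
      mutate(distance_bp = mid - .data$end)
    cand <- bind_rows(plus, minus) |>
      filter(.data$distance_bp <= upstream_bp) |>
      arrange(.data$distance_bp)
    if (nrow(cand) > 0) {
      return(tibble(class = "upstream", gene = cand$gene[1],
                    distance_bp = cand$distance_bp[1]))
    }
    tibble(class = "unassigned", gene = NA_character_, distance_bp = NA_real_)
  }) |> bind_rows()
  bind_cols(regions, res)
}

#' Scan two libraries for enriched regions, end to end
#'
#' Convenience wrapper: [eligible_sites()], [scan_windows()],
#' [merge_windows()], [classify_regions()].
#'
#' @inheritParams eligible_sites
#' @inheritParams scan_windows
#' @inheritParams classify_regions
#' @param annotations Optional gene annotations for classification.
#' @return A list of class `tnseq_scan` with `track`, `windows`, `regions`.
#' @export
scan_enriched_regions <- function(lib_ref, lib_sel, annotations = NULL,
                                  sites = NULL, window_size = 13,
                                  p_max = 0.02, fold_min_enrich = 3,
                                  upstream_bp = 500) {
  track <- eligible_sites(lib_ref, lib_sel, sites)
  windows <- scan_windows(track, window_size = window_size, p_max = p_max,
                          fold_min_enrich = fold_min_enrich)
  regions <- merge_windows(windows, track)
  if (!is.null(annotations)) {
    regions <- classify_regions(regions, annotations, upstream_bp = upstream_bp)
  }
  structure(list(track = track, windows = windows, regions = regions),
            class = "tnseq_scan")
}

#' @export
print.tnseq_scan <- function(x, ...) {
  cat(sprintf("<tnseq_scan> %d eligible sites, %d windows (%d significant), %d regions\n",
              nrow(x$track), nrow(x$windows), sum(x$windows$significant),
              nrow(x$regions)))
  invisible(x)
}

#' @export
tidy.tnseq_scan <- function(x, ...) as_tibble(x$regions)

#' @export
glance.tnseq_scan <- function(x, ...) {
  tibble(
    n_eligible_sites = nrow(x$track),
    n_windows = nrow(x$windows),
    n_significant_windows = sum(x$windows$significant),
    n_regions = nrow(x$regions)
  )
}

#' Genome-wide enrichment profile plot
#'
#' Per-window fold enrichment along the genome with significant windows and
#' merged regions highlighted.
#'
#' @param object A `tnseq_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnseq_scan <- function(object, ...) {
  w <- object$windows
  p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$first_pos,
                                       y = .data$fold_enrichment)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(data = w[w$significant, ], colour = "firebrick", size = 1) +
    ggplot2::labs(x = "genomic position (first TA site of window)",
                  y = "window fold enrichment (selected / reference)") +
    ggplot2::theme_minimal()
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick"
    )
  }
  p
}

#' Write enriched regions as BED and annotated TSV
#'
#' BED output is 0-based half-open (converted by \pkg{rtracklayer}); the TSV
#' carries all region columns.
#'
#' @param regions Region table (from [merge_windows()] or
#'   [classify_regions()]).
#' @param path Output path; the BED file gets the same stem with `.bed`.
#' @param genome_id Seqname for the BED records.
#' @return Paths written, invisibly.
#' @export
write_regions <- function(regions, path, genome_id = "genome") {
  readr::write_tsv(regions, path)
  bed <- sub("\\.tsv$", ".bed", path)
  if (bed == path) bed <- paste0(path, ".bed")
  if (nrow(regions) > 0) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome_id,
      ranges = IRanges::IRanges(regions$start, regions$end + 1L),
      name = regions$region_id,
      score = pmin(1000, round(10 * regions$peak_fold))
    )
    rtracklayer::export(gr, bed, format = "bed")
  } else {
    writeLines(character(0), bed)
  }
  invisible(c(path, bed))
}
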