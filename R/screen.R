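#' Thresholds and curation rules for the depletion screen
#'
#' Defaults reproduce the primary screen of the modelled study: raw
#' p < 0.05 with a > 2-fold reduction in insertions after selection. For an
#' early (T5-style) screen a more stringent `fold_min = 5` is conventional.
#' The curation flags replace visual inspection of insertion profiles with
#' explicit parametric rules; flagged genes are reported, never silently
#' dropped.
#'
#' @param alpha Significance level on the raw Mann-Whitney p-value.
#' @param fold_min Minimal fold reduction (reference/selected) for a hit.
#' @param low_coverage_min_sites A gene with fewer reference-occupied TA
#'   sites than this is flagged `low_coverage` (very few insertions at T0)
#'   and excluded from hit calls.
#' @param dispersed_fold_max,dispersed_retention_min A gene with fold change
#'   below `dispersed_fold_max` whose reference-occupied sites remain
#'   occupied in the selected library at a fraction of at least
#'   `dispersed_retention_min` is flagged `dispersed` (modest reduction with
#'   insertions throughout the open reading frame).
#' @param exact_max_n Use the exact Mann-Whitney null up to this many TA
#'   sites per gene; larger genes use the tie- and continuity-corrected
#'   normal approximation.
#' @param norm_scale Library-size normalization target (reads per
#'   `norm_scale` mapped reads; default reads-per-10-million).
#' @param adjust Also report Benjamini-Hochberg adjusted p-values
#'   (`p_adjusted` column); the screen itself thresholds raw p.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, fold_min = 2,
                          low_coverage_min_sites = 5,
                          dispersed_fold_max = 3,
                          dispersed_retention_min = 0.8,
                          exact_max_n = 8,
                          norm_scale = 1e7,
                          adjust = FALSE) {
  if (alpha <= 0 || alpha >= 1) tn_stop("alpha must be in (0, 1)")
  if (fold_min < 1) tn_stop("fold_min must be >= 1")
  structure(list(alpha = alpha, fold_min = fold_min,
                 low_coverage_min_sites = low_coverage_min_sites,
                 dispersed_fold_max = dispersed_fold_max,
                 dispersed_retention_min = dispersed_retention_min,
                 exact_max_n = exact_max_n, norm_scale = norm_scale,
                 adjust = adjust),
            class = "screen_config")
}

#' Normalize per-site counts for library size
#'
#' Each site count is scaled by `scale / total_mapped_reads` of its own
#' library, so libraries of unequal sequencing depth are comparable; the
#' normalized counts of a library sum exactly to `scale`.
#'
#' @param counts Numeric vector of raw per-site counts.
#' @param total Total mapped reads of the library (default `sum(counts)`).
#' @param scale Normalization target (default reads-per-10-million).
#' @return Numeric vector of normalized counts.
#' @export
normalize_counts <- function(counts, total = sum(counts), scale = 1e7) {
  if (total <= 0) tn_stop("cannot normalize a library with zero mapped reads")
  counts * scale / total
}

#' Fold change of insertion representation
#'
#' Reference over selected, on normalized gene totals, with a pseudocount of
#' one normalized read in numerator and denominator so that complete
#' depletion yields a finite value; the raw (pseudocount-free) ratio is
#' reported alongside and is `Inf` at complete depletion.
#'
#' @param ref_total,sel_total Normalized gene totals (vectorized).
#' @param pseudocount Pseudocount in normalized-read units.
#' @return A tibble with `fold_change` and `fold_change_raw`.
#' @export
fold_change <- function(ref_total, sel_total, pseudocount = 1) {
  tibble(
    fold_change = (ref_total + pseudocount) / (sel_total + pseudocount),
    fold_change_raw = ifelse(sel_total > 0, ref_total / sel_total,
                             ifelse(ref_total > 0, Inf, NaN))
  )
}

#' Per-gene insertion-depletion screen
#'
#' For every annotated gene, compares normalized per-site read counts
#' between a reference (T0) and a selected (heat-killed T5/T24) library with
#' a two-sided Mann-Whitney U test over the gene's TA sites (unoccupied
#' sites enter as zeros in both samples), computes the fold reduction in
#' insertion representation, and calls hits at `p < alpha` and
#' `fold_change > fold_min` for genes without a `low_coverage` flag.
#' Direction is enforced by the fold threshold, so the two-sided p-value
#' reproduces one-sided screening for underrepresented genes.
#'
#' @param lib_ref,lib_sel Insertion-library tibbles on the same TA-site
#'   index (reference first, e.g. T0 vs T24).
#' @param annotations Gene-annotation tibble.
#' @param sites TA-site index of the genome.
#' @param config A [screen_config()].
#' @return A tibble of class `tnseq_screen`, one row per gene, sorted by
#'   p-value: `gene`, `locus_tag`, `n_ta_sites`, `n_sites_occupied_ref`,
#'   `n_sites_occupied_sel`, `t_ref_reads`, `t_sel_reads`, `t_ref_norm`,
#'   `t_sel_norm`, `fold_change`, `fold_change_raw`, `u_stat`, `p_value`,
#'   `neg_log10_p`, `flags`, `is_hit` (+ `p_adjusted` when configured).
#' @export
run_screen <- function(lib_ref, lib_sel, annotations, sites,
                       config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  if (nrow(annotations) == 0) tn_stop("no annotated genes")
  if (max(annotations$end) > max(sites) + 1 + 10000) {
    tn_stop("annotations extend far beyond the TA-site index; genome/annotation mismatch")
  }
  ref_raw <- counts_on_index(lib_ref, sites)
  sel_raw <- counts_on_index(lib_sel, sites)
  ref_norm <- normalize_counts(ref_raw, scale = config$norm_scale)
  sel_norm <- normalize_counts(sel_raw, scale = config$norm_scale)
  site_map <- assign_sites_to_genes(sites, annotations)
  idx_of <- split(match(site_map$position, sites), site_map$gene)

  rows <- purrr::pmap(
    list(annotations$gene, annotations$locus_tag),
    function(gene, locus_tag) {
      m <- idx_of[[gene]]
      n <- length(m)
      if (n == 0) {
        return(tibble(
          gene = gene, locus_tag = locus_tag, n_ta_sites = 0L,
          n_sites_occupied_ref = 0L, n_sites_occupied_sel = 0L,
          t_ref_reads = 0, t_sel_reads = 0, t_ref_norm = 0, t_sel_norm = 0,
          fold_change = NA_real_, fold_change_raw = NA_real_,
          u_stat = NA_real_, p_value = NA_real_, flags = "no_sites"
        ))
      }
      rr <- ref_raw[m]; sr <- sel_raw[m]
      rn <- ref_norm[m]; sn <- sel_norm[m]
      mw <- mann_whitney_u(rn, sn, exact_max_n = config$exact_max_n)
      fc <- fold_change(sum(rn), sum(sn))
      occ_ref <- sum(rr >= 1)
      occ_both <- sum(rr >= 1 & sr >= 1)
      retention <- if (occ_ref > 0) occ_both / occ_ref else NA_real_
      flags <- character(0)
      if (occ_ref < config$low_coverage_min_sites) flags <- c(flags, "low_coverage")
      if (!is.na(retention) && fc$fold_change < config$dispersed_fold_max &&
          retention >= config$dispersed_retention_min) {
        flags <- c(flags, "dispersed")
      }
      if (sum(sr) == 0) flags <- c(flags, "zero_sel")
      tibble(
        gene = gene, locus_tag = locus_tag, n_ta_sites = n,
        n_sites_occupied_ref = occ_ref, n_sites_occupied_sel = sum(sr >= 1),
        t_ref_reads = sum(rr), t_sel_reads = sum(sr),
        t_ref_norm = sum(rn), t_sel_norm = sum(sn),
        fold_change = fc$fold_change, fold_change_raw = fc$fold_change_raw,
        u_stat = mw$statistic, p_value = mw$p.value,
        flags = paste(flags, collapse = ";")
      )
    }
  )
  res <- bind_rows(rows) |>
    mutate(
      neg_log10_p = pmin(320, -log10(.data$p_value)),
      is_hit = !is.na(.data$p_value) &
        .data$p_value < config$alpha &
        .data$fold_change > config$fold_min &
        !grepl("low_coverage", .data$flags)
    )
  if (config$adjust) {
    res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  }
  res <- res |> arrange(.data$p_value)
  class(res) <- c("tnseq_screen", class(res))
  attr(res, "config") <- config
  attr(res, "ref_total") <- sum(ref_raw)
  attr(res, "sel_total") <- sum(sel_raw)
  res
}

#' Plot-ready volcano table
#'
#' @param results A `tnseq_screen` tibble from [run_screen()].
#' @param cap Cap on `-log10(p)` (p-value underflow protection).
#' @return A tibble: `gene`, `fold_change`, `neg_log10_p`, `is_hit`,
#'   `flags`, `p_capped`.
#' @export
volcano_table <- function(results, cap = 320) {
  results |>
    as_tibble() |>
    mutate(
      p_capped = !is.na(.data$p_value) & (.data$p_value == 0 | -log10(.data$p_value) > cap),
      neg_log10_p = ifelse(.data$p_capped, cap,
                           ifelse(is.na(.data$p_value), NA_real_, -log10(.data$p_value)))
    ) |>
    select("gene", "fold_change", "neg_log10_p", "is_hit", "flags", "p_capped")
}

#' Write screen results as TSV
#'
#' Fixed leading column order: gene, locus_tag, n_ta_sites, t_ref_reads,
#' t_sel_reads, fold_change, u_stat, p_value, neg_log10_p, flags, is_hit;
#' any additional columns follow.
#'
#' @param results A `tnseq_screen` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(results, path) {
  lead <- c("gene", "locus_tag", "n_ta_sites", "t_ref_reads", "t_sel_reads",
            "fold_change", "u_stat", "p_value", "neg_log10_p", "flags", "is_hit")
  out <- as_tibble(results)[, c(lead, setdiff(names(results), lead))]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
tidy.tnseq_screen <- function(x, ...) as_tibble(x)

#' @export
glance.tnseq_screen <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_genes = nrow(x),
    n_hits = sum(x$is_hit, na.rm = TRUE),
    n_low_coverage = sum(grepl("low_coverage", x$flags)),
    n_dispersed = sum(grepl("dispersed", x$flags)),
    alpha = cfg$alpha,
    fold_min = cfg$fold_min,
    median_fold = median(x$fold_change, na.rm = TRUE)
  )
}

#' Volcano plot of a depletion screen
#'
#' Fold reduction (log10) against `-log10` Mann-Whitney p, with the
#' configured significance thresholds as dashed lines.
#'
#' @param object A `tnseq_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnseq_screen <- function(object, ...) {
  cfg <- attr(object, "config")
  d <- volcano_table(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$fold_change),
                                  y = .data$neg_log10_p,
                                  colour = .data$is_hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(cfg$alpha), linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = log10(cfg$fold_min), linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log10 fold reduction (reference / selected)",
      y = "-log10 Mann-Whitney p",
      colour = "hit"
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.tnseq_screen <- function(x, ...) print(autoplot(x, ...))
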