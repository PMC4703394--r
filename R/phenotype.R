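#' Colony-forming units per mL
#'
#' @param colonies Colony count on the plate.
#' @param dilution_factor Dilution factor of the plated sample.
#' @param volume_ml Volume plated in mL.
#' @return CFU/mL (vectorized).
#' @export
#' @examples
#' cfu_per_ml(200, 1e4, 0.1)
cfu_per_ml <- function(colonies, dilution_factor, volume_ml) {
  if (any(colonies < 0)) tn_stop("negative colony counts")
  if (any(dilution_factor <= 0) || any(volume_ml <= 0)) {
    tn_stop("dilution_factor and volume_ml must be positive")
  }
  colonies * dilution_factor / volume_ml
}

#' Sporulation efficiency relative to wild type
#'
#' Heat-resistant CFU/mL of each strain as a percentage of the wild-type
#' heat-resistant CFU/mL at the same timepoint.
#'
#' @param data A tibble of CFU records with columns `strain`, `timepoint`,
#'   `colonies`, `dilution_factor`, `volume_ml`, `heat_treated`.
#' @param wildtype Name of the wild-type strain in `data`.
#' @return A tibble: `strain`, `timepoint`, `cfu_per_ml`,
#'   `efficiency_pct` (100 for the wild type itself). When a strain has
#'   replicate rows, mean and SEM of the per-replicate efficiencies are
#'   reported (`efficiency_sem`, `n_replicates`).
#' @export
sporulation_efficiency <- function(data, wildtype = "WT") {
  req <- c("strain", "timepoint", "colonies", "dilution_factor", "volume_ml")
  if (!all(req %in% names(data))) {
    tn_stop("missing columns: ", paste(setdiff(req, names(data)), collapse = ", "))
  }
  if (!"heat_treated" %in% names(data)) data$heat_treated <- TRUE
  if (!all(data$heat_treated)) {
    tn_stop("sporulation efficiency is defined on heat-treated samples only")
  }
  data <- data |>
    mutate(cfu = cfu_per_ml(.data$colonies, .data$dilution_factor, .data$volume_ml),
           .rep = dplyr::row_number(), .by = c("strain", "timepoint"))
  wt <- data |> filter(.data$strain == wildtype)
  if (nrow(wt) == 0) tn_stop("wild-type strain '", wildtype, "' not found")
  if (any(wt$cfu == 0)) tn_stop("wild-type CFU is zero; efficiency undefined")
  paired <- data |>
    left_join(wt |> select("timepoint", ".rep", wt_cfu = "cfu"),
              by = c("timepoint", ".rep")) |>
    filter(!is.na(.data$wt_cfu)) |>
    mutate(eff = 100 * .data$cfu / .data$wt_cfu)
  paired |>
    group_by(.data$strain, .data$timepoint) |>
    summarise(
      cfu_per_ml = mean(.data$cfu),
      efficiency_pct = mean(.data$eff),
      efficiency_sem = if (dplyr::n() >= 2) sd(.data$eff) / sqrt(dplyr::n()) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}

#' Co-culture competitive index
#'
#' CI = (mutant/WT heat-resistant CFU at selection) divided by
#' (mutant/WT CFU at T0) in a 1:1 co-culture. A perfectly neutral mutant has
#' CI = 1; CI > 1 means earlier or faster spore maturation. The index is
#' invariant to any common dilution of all four counts, and swapping the
#' mutant/WT labels maps CI to 1/CI.
#'
#' @param mut_t0,wt_t0 Mutant and wild-type CFU at the onset of starvation.
#' @param mut_sel,wt_sel Mutant and wild-type heat-resistant CFU at the
#'   selection timepoint.
#' @return Numeric CI (vectorized).
#' @export
#' @examples
#' competitive_index(mut_t0 = 50, wt_t0 = 50, mut_sel = 200, wt_sel = 100)
competitive_index <- function(mut_t0, wt_t0, mut_sel, wt_sel) {
  if (any(c(mut_t0, wt_t0, mut_sel, wt_sel) < 0)) tn_stop("negative CFU counts")
  if (any(wt_t0 <= 0) || any(wt_sel <= 0)) {
    tn_stop("wild-type CFU must be positive for a defined competitive index")
  }
  if (any(mut_t0 <= 0)) tn_stop("mutant CFU at T0 is zero; competitive index undefined")
  (mut_sel / wt_sel) / (mut_t0 / wt_t0)
}

#' Summarize replicate measurements
#'
#' Arithmetic mean and standard error of the mean (sample SD / sqrt(n));
#' with a single value the SEM is undefined (`NA`).
#'
#' @param values Numeric vector of replicate values.
#' @return A tibble: `mean`, `sem`, `n`.
#' @export
#' @examples
#' summarize_replicates(c(2, 4))
summarize_replicates <- function(values) {
  n <- length(values)
  if (n == 0) tn_stop("no values")
  tibble(
    mean = mean(values),
    sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Per-strain competitive indices from a replicate co-culture table
#'
#' Computes a CI per replicate row and summarizes replicates per strain
#' (mean and SEM). A replicate with zero mutant heat-resistant CFU is
#' reported as censored at the detection limit (the CI value that one
#' observed colony would give) rather than as CI = 0.
#'
#' @param data A tibble with columns `strain`, `mut_t0`, `wt_t0`,
#'   `mut_sel`, `wt_sel` (one row per biological replicate).
#' @return A tibble: `strain`, `ci_mean`, `ci_sem`, `n_replicates`,
#'   `n_censored`, `detection_limit` (NA when no replicate was censored).
#' @export
competitive_index_summary <- function(data) {
  req <- c("strain", "mut_t0", "wt_t0", "mut_sel", "wt_sel")
  if (!all(req %in% names(data))) {
    tn_stop("missing columns: ", paste(setdiff(req, names(data)), collapse = ", "))
  }
  data |>
    mutate(
      censored = .data$mut_sel == 0,
      ci = competitive_index(.data$mut_t0, .data$wt_t0,
                             pmax(.data$mut_sel, 1), .data$wt_sel)
    ) |>
    group_by(.data$strain) |>
    summarise(
      ci_mean = mean(.data$ci[!.data$censored]),
      ci_sem = if (sum(!.data$censored) >= 2) {
        sd(.data$ci[!.data$censored]) / sqrt(sum(!.data$censored))
      } else NA_real_,
      n_replicates = dplyr::n(),
      n_censored = sum(.data$censored),
      detection_limit = if (any(.data$censored)) min(.data$ci[.data$censored]) else NA_real_,
      .groups = "drop"
    )
}
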