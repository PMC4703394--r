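#' Construct an insertion-count profile
#'
#' An insertion library is the per-TA-site read-count profile of one
#' sequenced condition (T0 at the onset of starvation, or a heat-selected
#' T5/T24 sample). Counts from both insertion orientations are collapsed to
#' one tally per TA site; zero-count sites may be omitted.
#'
#' @param position Integer TA-site positions (coordinate of the T).
#' @param count Non-negative integer read counts, same length.
#' @param condition Condition label, e.g. `"T0"`, `"T5"`, `"T24"`.
#' @param genome_id Identifier of the reference the positions refer to.
#' @param sites Optional TA-site index; positions outside it raise an error.
#' @return A tibble with columns `position`, `count`, carrying `condition`
#'   and `genome_id` attributes; total mapped reads is `sum(count)`.
#' @export
insertion_library <- function(position, count, condition = "custom",
                              genome_id = "genome", sites = NULL) {
  position <- as.integer(position)
  if (any(duplicated(position))) tn_stop("duplicated positions in insertion library")
  if (any(count < 0)) tn_stop("negative read counts")
  if (any(count != round(count))) tn_stop("read counts must be integers")
  if (!is.null(sites) && length(position) && !all(position %in% sites)) {
    tn_stop("library contains positions that are not TA sites of the index")
  }
  lib <- tibble(position = position, count = as.numeric(count)) |>
    arrange(.data$position)
  attr(lib, "condition") <- condition
  attr(lib, "genome_id") <- genome_id
  lib
}

#' Total mapped reads of a library
#'
#' @param lib An insertion-library tibble.
#' @return Sum of all site counts.
#' @export
total_reads <- function(lib) sum(lib$count)

#' Write an insertion profile to disk
#'
#' The TSV dialect is two tab-separated columns with header
#' `position\tcount` (1-based TA coordinates); bedgraph output is 0-based
#' half-open, one 1-bp interval per TA site (written through
#' \pkg{rtracklayer}).
#'
#' @param lib An insertion-library tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"bedgraph"`; guessed from the file extension
#'   by default.
#' @return `path`, invisibly.
#' @export
write_profile <- function(lib, path, format = c("auto", "tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedgraph" else "tsv"
  }
  if (format == "tsv") {
    readr::write_tsv(lib[, c("position", "count")], path)
  } else {
    gid <- attr(lib, "genome_id") %||% "genome"
    gr <- GenomicRanges::GRanges(
      seqnames = gid,
      ranges = IRanges::IRanges(start = lib$position, width = 1L),
      score = lib$count
    )
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(path)
}

#' Read an insertion profile from disk
#'
#' @param path Input path (TSV or bedgraph, see [write_profile()]).
#' @param format File format; guessed from the extension by default.
#' @param condition,genome_id Metadata attached to the returned library.
#' @param sites Optional TA-site index for validation.
#' @return An insertion-library tibble.
#' @export
read_profile <- function(path, format = c("auto", "tsv", "bedgraph"),
                         condition = "custom", genome_id = "genome",
                         sites = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedgraph" else "tsv"
  }
  if (format == "tsv") {
    d <- readr::read_tsv(path, col_types = readr::cols(
      position = readr::col_integer(), count = readr::col_double()
    ))
  } else {
    gr <- rtracklayer::import(path, format = "bedGraph")
    d <- tibble(position = BiocGenerics::start(gr), count = gr$score)
    if (length(gr)) genome_id <- as.character(GenomicRanges::seqnames(gr))[1]
  }
  insertion_library(d$position, d$count, condition = condition,
                    genome_id = genome_id, sites = sites)
}

#' Expand a library onto a full TA-site index
#'
#' @param lib Insertion-library tibble.
#' @param sites Integer TA-site index.
#' @return Numeric vector of counts parallel to `sites` (zero where absent).
#' @export
counts_on_index <- function(lib, sites) {
  i <- match(lib$position, sites)
  if (anyNA(i)) tn_stop("library contains positions absent from the TA-site index")
  out <- numeric(length(sites))
  out[i] <- lib$count
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
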