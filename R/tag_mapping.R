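#' Build an exact-match tag index for transposon-junction reads
#'
#' For every TA site, the `tag_length` bases immediately 3' of the TA on
#' each strand are registered as exact-match k-mers pointing at that site.
#' A k-mer occurring at more than one site is moved to the ambiguous set and
#' never assigned. Tags containing `N` or truncated by a genome end are not
#' registered. Exact matching at 16 nt on a megabase-scale genome loses
#' little and keeps the mapper bit-reproducible.
#'
#' @param genome A [tn_genome()].
#' @param sites TA-site index from [find_ta_sites()].
#' @param tag_length Tag length in nt (>= 10; MmeI releases ~16 nt).
#' @return A list of class `tag_index` with elements `tag` (character),
#'   `position` (parallel integer), `ambiguous` (character), `tag_length`.
#' @export
build_tag_index <- function(genome, sites, tag_length = 16) {
  stopifnot(inherits(genome, "tn_genome"))
  if (tag_length < 10) tn_stop("tag_length must be >= 10")
  if (tag_length > length(genome)) tn_stop("tag_length longer than genome")
  gseq <- as.character(genome$seq)
  glen <- length(genome)
  fwd_ok <- sites + 1 + tag_length <= glen
  rev_ok <- sites - tag_length >= 1
  fwd <- tibble(
    tag = substring(gseq, sites[fwd_ok] + 2, sites[fwd_ok] + 1 + tag_length),
    position = sites[fwd_ok]
  )
  rev <- tibble(
    tag = revcomp_chr(substring(gseq, sites[rev_ok] - tag_length, sites[rev_ok] - 1)),
    position = sites[rev_ok]
  )
  all <- bind_rows(fwd, rev) |>
    filter(!grepl("N", .data$tag, fixed = TRUE)) |>
    distinct()
  amb <- all |>
    group_by(.data$tag) |>
    summarise(n = dplyr::n_distinct(.data$position), .groups = "drop") |>
    filter(.data$n > 1)
  uni <- all |> filter(!.data$tag %in% amb$tag)
  structure(
    list(tag = uni$tag, position = uni$position, ambiguous = amb$tag,
         tag_length = as.integer(tag_length), genome_id = genome$id),
    class = "tag_index"
  )
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("<tag_index> %d unique %d-mers, %d ambiguous\n",
              length(x$tag), x$tag_length, length(x$ambiguous)))
  invisible(x)
}

#' Map transposon-junction reads to TA sites
#'
#' Per read: locate the transposon ITR motif by exact substring search
#' within the first 30 nt of the read (first occurrence wins); take the
#' following `tag_length` bases as the genomic tag; look the tag up in the
#' index. Reads without the motif, with ambiguous tags, or with tags that
#' are unmatched, truncated or contain `N` are counted in the corresponding
#' statistics bucket and never assigned.
#'
#' @param fastq Path to a 4-line-record FASTQ file (plain or `.gz`).
#' @param tag_index A [build_tag_index()] object.
#' @param itr_motif Transposon end sequence expected 5' of the genomic tag.
#' @return A list with `library` (insertion-library tibble of tallied
#'   counts) and `stats` (one-row tibble: `n_reads`, `n_no_itr`,
#'   `n_ambiguous`, `n_unmapped`, `n_mapped`; buckets sum to `n_reads`).
#' @export
map_reads <- function(fastq, tag_index, itr_motif = TNSPORE_ITR) {
  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "r") else file(fastq, "r")
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4 != 0) {
    tn_stop("truncated FASTQ record ", length(lines) %/% 4 + 1, " in ", fastq)
  }
  n_reads <- length(lines) %/% 4
  seqs <- lines[seq_len(n_reads) * 4 - 2]
  L <- tag_index$tag_length
  ## motif must start within the first 30 nt
  window <- substr(seqs, 1, 30 + nchar(itr_motif) - 1)
  hit <- regexpr(itr_motif, window, fixed = TRUE)
  has_itr <- hit > 0
  tag_start <- as.integer(hit) + nchar(itr_motif)
  tags <- substr(seqs, tag_start, tag_start + L - 1)
  valid_tag <- has_itr & nchar(tags) == L & !grepl("N", tags, fixed = TRUE)
  amb <- valid_tag & tags %in% tag_index$ambiguous
  idx <- match(tags, tag_index$tag)
  mapped <- valid_tag & !amb & !is.na(idx)
  pos <- tag_index$position[idx[mapped]]
  tab <- table(pos)
  lib <- insertion_library(
    as.integer(names(tab)), as.integer(tab),
    condition = "mapped", genome_id = tag_index$genome_id
  )
  stats <- tibble(
    n_reads = n_reads,
    n_no_itr = sum(!has_itr),
    n_ambiguous = sum(amb),
    n_unmapped = sum(has_itr & !amb & !mapped),
    n_mapped = sum(mapped)
  )
  list(library = lib, stats = stats)
}
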