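#' Construct a genome object
#'
#' A light container for a single reference sequence. The Mariner (himar1)
#' transposon inserts exclusively at TA dinucleotides, so all downstream
#' analysis is anchored on the TA-site coordinates of this sequence.
#'
#' @param sequence A character scalar or [Biostrings::DNAString] over
#'   `{A, C, G, T, N}`.
#' @param id Sequence identifier (used as the seqname in exported tracks).
#' @param topology `"linear"` or `"circular"`. Circular genomes are treated
#'   linearly for TA-site indexing: a site spanning the origin is not called
#'   (at most one site genome-wide is affected).
#' @return An object of class `tn_genome` with elements `id`, `seq`
#'   (a `DNAString`) and `topology`.
#' @export
#' @examples
#' g <- tn_genome("GATTACA")
#' find_ta_sites(g)
tn_genome <- function(sequence, id = "genome", topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (methods::is(sequence, "DNAString")) {
    seq <- sequence
  } else {
    stopifnot(is.character(sequence), length(sequence) == 1)
    seq <- tryCatch(
      Biostrings::DNAString(toupper(sequence)),
      error = function(e) tn_stop("sequence contains non-DNA characters: ", conditionMessage(e))
    )
  }
  if (length(seq) == 0) tn_stop("genome sequence must be non-empty")
  af <- Biostrings::alphabetFrequency(seq)
  bad <- sum(af[!names(af) %in% c("A", "C", "G", "T", "N")])
  if (bad > 0) {
    tn_stop("genome sequence contains ", bad,
            " characters outside {A,C,G,T,N} (IUPAC ambiguity codes are not accepted)")
  }
  structure(list(id = id, seq = seq, topology = topology), class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat(sprintf("<tn_genome> %s: %s bp (%s)\n", x$id, length(x$seq), x$topology))
  invisible(x)
}

#' @export
length.tn_genome <- function(x) length(x$seq)

#' Read a genome from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param id Optional record id to select; by default the first record is used.
#' @param topology Passed to [tn_genome()].
#' @return A [tn_genome()] object.
#' @export
read_genome_fasta <- function(path, id = NULL, topology = "linear") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) tn_stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  i <- 1L
  if (!is.null(id)) {
    i <- match(id, nm)
    if (is.na(i)) tn_stop("sequence id '", id, "' not found in ", path)
  }
  tn_genome(ss[[i]], id = nm[i], topology = topology)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [tn_genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse-complement a genome
#'
#' @param genome A [tn_genome()] object.
#' @return A [tn_genome()] of the reverse-complement strand.
#' @export
reverse_complement_genome <- function(genome) {
  tn_genome(Biostrings::reverseComplement(genome$seq),
            id = genome$id, topology = genome$topology)
}

#' Find all TA dinucleotide sites
#'
#' Returns the 1-based coordinate of the T of every `TA` occurrence
#' (overlapping occurrences allowed; `TATA` holds sites at 1 and 3).
#' Because `TA` is its own reverse complement the index is strand-symmetric:
#' computing it on the reverse-complement strand and reflecting coordinates
#' gives the identical set. Positions containing `N` never form sites.
#'
#' @param genome A [tn_genome()] object.
#' @return A strictly increasing integer vector of TA-site positions.
#' @export
#' @examples
#' find_ta_sites(tn_genome("TATATA"))
find_ta_sites <- function(genome) {
  stopifnot(inherits(genome, "tn_genome"))
  m <- Biostrings::matchPattern("TA", genome$seq, fixed = TRUE)
  sort(BiocGenerics::start(m))
}

#' TA sites contained in a gene
#'
#' A TA site belongs to a gene only when both of its bases lie within the
#' gene's `[start, end]` interval (1-based, inclusive); a site straddling a
#' boundary is excluded. Strand-independent.
#'
#' @param sites Integer vector of TA-site positions (from [find_ta_sites()]).
#' @param start,end 1-based inclusive gene coordinates.
#' @param genome_length Optional; when supplied, genes outside `[1, genome_length]`
#'   raise an error.
#' @return The subset of `sites` inside the gene.
#' @export
sites_in_gene <- function(sites, start, end, genome_length = NULL) {
  stopifnot(length(start) == 1, length(end) == 1)
  if (start > end) tn_stop("gene start > end")
  if (start < 1 || (!is.null(genome_length) && end > genome_length)) {
    tn_stop("gene [", start, ",", end, "] outside genome bounds")
  }
  sites[sites >= start & (sites + 1) <= end]
}

#' Assign TA sites to genes
#'
#' Overlap join between a TA-site index and a gene-annotation table, keeping a
#' site-gene pair only when both TA bases fall within the gene body.
#'
#' @param sites Integer vector of TA-site positions.
#' @param annotations Annotation tibble (see [read_annotations_gff3()]), with
#'   columns `gene`, `start`, `end`.
#' @return A tibble with columns `position` and `gene` (one row per
#'   site-gene containment pair; genes may overlap).
#' @export
assign_sites_to_genes <- function(sites, annotations) {
  if (nrow(annotations) == 0 || length(sites) == 0) {
    return(tibble(position = integer(), gene = character()))
  }
  q <- IRanges::IRanges(start = sites, width = 2L)
  s <- IRanges::IRanges(start = annotations$start, end = annotations$end)
  hits <- IRanges::findOverlaps(q, s, type = "within")
  tibble(
    position = sites[S4Vectors::queryHits(hits)],
    gene = annotations$gene[S4Vectors::subjectHits(hits)]
  ) |>
    arrange(.data$position)
}
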