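#' Build a gene-annotation table
#'
#' @param gene Gene names.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param locus_tag Optional locus tags (default: the gene names).
#' @param is_essential Optional logical flag per gene.
#' @param genome_length Optional bound check.
#' @return A tibble with columns `gene`, `locus_tag`, `start`, `end`,
#'   `strand`, `is_essential`.
#' @export
gene_annotations <- function(gene, start, end, strand = "+",
                             locus_tag = gene, is_essential = FALSE,
                             genome_length = NULL) {
  ann <- tibble(
    gene = as.character(gene),
    locus_tag = as.character(locus_tag),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(strand, length(gene)),
    is_essential = rep_len(is_essential, length(gene))
  )
  if (any(ann$start > ann$end)) tn_stop("annotation with start > end")
  if (!all(ann$strand %in% c("+", "-"))) tn_stop("strand must be '+' or '-'")
  if (!is.null(genome_length) &&
      (any(ann$start < 1) || any(ann$end > genome_length))) {
    tn_stop("annotation coordinates outside genome bounds")
  }
  ann
}

#' Read gene annotations from a GFF3 file
#'
#' Keeps features of type `gene` or `CDS` (genes preferred when both are
#' present for the same locus) and extracts the `gene` and `locus_tag`
#' attributes; features lacking a `gene` attribute fall back to `locus_tag`,
#' then `ID`.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep.
#' @return An annotation tibble (see [gene_annotations()]).
#' @export
read_annotations_gff3 <- function(path, feature_types = c("gene", "CDS")) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if ("gene" %in% as.character(gr$type)) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  if (length(gr) == 0) {
    return(gene_annotations(character(), integer(), integer()))
  }
  mc <- S4Vectors::mcols(gr)
  pick <- function(key) if (key %in% names(mc)) as.character(mc[[key]]) else rep(NA_character_, length(gr))
  name <- dplyr::coalesce(pick("gene"), pick("Name"), pick("locus_tag"), pick("ID"))
  lt <- dplyr::coalesce(pick("locus_tag"), name)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  gene_annotations(
    gene = name,
    locus_tag = lt,
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

#' Write gene annotations to a GFF3 file
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @param genome_id Seqname to use.
#' @return `path`, invisibly.
#' @export
write_annotations_gff3 <- function(annotations, path, genome_id = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = genome_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand
  )
  gr$type <- "gene"
  gr$gene <- annotations$gene
  gr$locus_tag <- annotations$locus_tag
  gr$ID <- annotations$locus_tag
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
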