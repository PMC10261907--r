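#' Load gene models from a GTF annotation
#'
#' Reads exon features for the requested genes from a GTF file and returns one
#' `GeneModel` per gene. GTF coordinates (1-based inclusive) are converted to
#' the internal 0-based half-open convention at this boundary; exons are always
#' stored in ascending genome coordinates regardless of strand.
#'
#' @param gtf_path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon features.
#' @param fasta_path Optional path to the matching genome FASTA. When given,
#'   each gene's chromosome is checked against the FASTA record names.
#' @param gene_ids Character vector of gene identifiers to load.
#' @return Named list of `GeneModel` objects, one per requested gene. Each has
#'   `gene_id`, `chrom`, `strand`, `exons` (merged exon union, `data.frame`
#'   with 0-based half-open `start`/`end`, sorted) and `transcripts` (named
#'   list of per-transcript exon data frames).
#' @export
load_gene_models <- function(gtf_path, fasta_path = NULL, gene_ids) {
  stopifnot(length(gene_ids) >= 1)
  gene_ids <- unique(as.character(gene_ids))
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type == "exon" & md$gene_id %in% gene_ids
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  missing <- setdiff(gene_ids, unique(md$gene_id))
  if (length(missing) > 0) {
    stop("unknown gene: ", paste(missing, collapse = ", "))
  }
  chrom_names <- NULL
  if (!is.null(fasta_path)) {
    chrom_names <- names(Biostrings::fasta.seqlengths(fasta_path))
    # FASTA headers may carry descriptions after whitespace
    chrom_names <- sub("\\s.*$", "", chrom_names)
  }
  models <- lapply(gene_ids, function(gid) {
    sel <- md$gene_id == gid
    g <- gr[sel]
    chrom <- unique(as.character(GenomicRanges::seqnames(g)))
    if (length(chrom) != 1) {
      stop("ambiguous locus for gene ", gid, ": exons on multiple chromosomes")
    }
    strand <- unique(as.character(GenomicRanges::strand(g)))
    if (length(strand) != 1 || !strand %in% c("+", "-")) {
      stop("ambiguous locus for gene ", gid, ": inconsistent or missing strand")
    }
    if (!is.null(chrom_names) && !chrom %in% chrom_names) {
      stop("chromosome ", chrom, " for gene ", gid, " not present in FASTA")
    }
    tx_ids <- as.character(S4Vectors::mcols(g)$transcript_id)
    exon_df <- data.frame(
      start = GenomicRanges::start(g) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(g),
      transcript = tx_ids,
      stringsAsFactors = FALSE
    )
    transcripts <- lapply(split(exon_df[, c("start", "end")], exon_df$transcript),
                          function(d) d[order(d$start), , drop = FALSE])
    merged <- IRanges::reduce(IRanges::IRanges(start = exon_df$start + 1L,
                                               end = exon_df$end))
    exons <- data.frame(start = IRanges::start(merged) - 1L,
                        end = IRanges::end(merged))
    new_gene_model(gene_id = gid, chrom = chrom, strand = strand,
                   exons = exons, transcripts = transcripts)
  })
  names(models) <- gene_ids
  models
}

new_gene_model <- function(gene_id, chrom, strand, exons, transcripts) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) stop("exon with non-positive length in ", gene_id)
  obj <- structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, transcripts = transcripts),
    class = "GeneModel"
  )
  obj
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s%s) %d merged exons, %d transcripts, span %d..%d\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              length(x$transcripts), gene_span(x)[1], gene_span(x)[2]))
  invisible(x)
}

# 0-based half-open span across the merged exon union
gene_span <- function(gene) {
  c(min(gene$exons$start), max(gene$exons$end))
}

#' Read a genome FASTA into a named DNAStringSet
#'
#' @param fasta_path Path to an (optionally gzipped) FASTA file.
#' @return `Biostrings::DNAStringSet` keyed by the first word of each header.
#' @export
read_genome <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
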