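#' Shrink long introns of a gene, keeping an invertible coordinate map
#'
#' Every intron longer than `max_intron` is replaced by its first
#' `ceiling(max_intron/2)` and last `floor(max_intron/2)` bases, removing the
#' central region. Exon sequence is untouched, and because at least
#' `max_intron/2` bases flank every exon the donor/acceptor dinucleotides of
#' all splice sites are always retained.
#'
#' @param gene A `GeneModel`.
#' @param seq Character (or `DNAString`) genomic sequence of the gene span
#'   (merged-exon min start to max end, genome forward strand).
#' @param max_intron Maximum retained intron length (default 1000).
#' @return List with `seq` (shrunk sequence, genome forward strand) and `map`
#'   (a `CoordinateMap` from absolute 0-based genome positions to 0-based
#'   positions in the shrunk sequence, plus orientation).
#' @export
shrink_introns <- function(gene, seq, max_intron = 1000L) {
  stopifnot(inherits(gene, "GeneModel"), max_intron >= 2)
  seq <- as.character(seq)
  span <- gene_span(gene)
  if (nchar(seq) != span[2] - span[1]) {
    stop("sequence length ", nchar(seq), " does not match gene span ",
         span[2] - span[1])
  }
  ex <- gene$exons
  keep_s <- ex$start[1]
  keep_e <- ex$end[1]
  if (nrow(ex) > 1) {
    for (i in 2:nrow(ex)) {
      s <- ex$end[i - 1]; e <- ex$start[i]   # intron [s, e)
      ilen <- e - s
      if (ilen <= max_intron) {
        keep_e[length(keep_e)] <- ex$end[i]  # contiguous with previous block
      } else {
        head_len <- ceiling(max_intron / 2)
        tail_len <- floor(max_intron / 2)
        keep_e[length(keep_e)] <- s + head_len
        keep_s <- c(keep_s, e - tail_len)
        keep_e <- c(keep_e, ex$end[i])
      }
    }
  }
  widths <- keep_e - keep_s
  cstart <- cumsum(c(0L, widths[-length(widths)]))
  pieces <- substring(seq, keep_s - span[1] + 1L, keep_e - span[1])
  shrunk <- paste(pieces, collapse = "")
  map <- new_coordinate_map(
    data.frame(gstart = keep_s, gend = keep_e, cstart = as.integer(cstart)),
    strand = "+", length = sum(widths), gene_id = gene$gene_id
  )
  list(seq = shrunk, map = map)
}

#' Build a fusion contig from a 5' and a 3' partner gene
#'
#' Concatenates the intron-shrunk sequences of geneA (5' partner) and geneB
#' (3' partner) into one contig in collinear transcribed orientation:
#' minus-strand genes are reverse-complemented so both genes read 5'->3' left
#' to right. Exon annotations are remapped into contig coordinates and the
#' genome<->contig coordinate maps are kept invertible.
#'
#' @param geneA,geneB `GeneModel`s; `geneA` is the 5' partner.
#' @param genome Named `DNAStringSet` (see [read_genome()]).
#' @param max_intron Intron shrinking threshold, see [shrink_introns()].
#' @return A `FusionContig`: `name` ("geneA--geneB"), `seq`, `geneB_offset`
#'   (0-based contig position where the geneB segment starts), `maps` (one
#'   `CoordinateMap` per gene), `annotations` (per-transcript remapped exons)
#'   and `exons` (merged exon unions per gene, contig coordinates).
#' @export
build_fusion_contig <- function(geneA, geneB, genome, max_intron = 1000L) {
  stopifnot(inherits(geneA, "GeneModel"), inherits(geneB, "GeneModel"))
  if (geneA$gene_id == geneB$gene_id) {
    stop("self-fusion unsupported: ", geneA$gene_id)
  }
  prep <- function(gene, offset) {
    span <- gene_span(gene)
    chrom_seq <- genome[[gene$chrom]]
    if (is.null(chrom_seq)) stop("chromosome ", gene$chrom, " absent from genome")
    seq <- as.character(Biostrings::subseq(chrom_seq, start = span[1] + 1L,
                                           width = span[2] - span[1]))
    sh <- shrink_introns(gene, seq, max_intron)
    if (gene$strand == "-") {
      sh$seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sh$seq)))
      sh$map$strand <- "-"
    }
    sh$map$offset <- as.integer(offset)
    sh
  }
  a <- prep(geneA, 0L)
  b <- prep(geneB, nchar(a$seq))
  maps <- list(a$map, b$map)
  names(maps) <- c(geneA$gene_id, geneB$gene_id)

  remap_tx <- function(gene, map) {
    rows <- lapply(names(gene$transcripts), function(tx) {
      exd <- gene$transcripts[[tx]]
      cm <- t(vapply(seq_len(nrow(exd)), function(i) {
        map_interval_to_contig(map, exd$start[i], exd$end[i])
      }, integer(2)))
      data.frame(gene = gene$gene_id, transcript = tx,
                 cstart = cm[, 1], cend = cm[, 2],
                 gstart = exd$start, gend = exd$end,
                 chrom = gene$chrom, strand = gene$strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  ann <- rbind(remap_tx(geneA, maps[[1]]), remap_tx(geneB, maps[[2]]))
  merged_exons <- function(gene, map) {
    cm <- t(vapply(seq_len(nrow(gene$exons)), function(i) {
      map_interval_to_contig(map, gene$exons$start[i], gene$exons$end[i])
    }, integer(2)))
    d <- data.frame(cstart = cm[, 1], cend = cm[, 2])
    d[order(d$cstart), , drop = FALSE]
  }
  exons <- list(merged_exons(geneA, maps[[1]]), merged_exons(geneB, maps[[2]]))
  names(exons) <- c(geneA$gene_id, geneB$gene_id)

  structure(
    list(name = paste0(geneA$gene_id, "--", geneB$gene_id),
         gene_a = geneA$gene_id, gene_b = geneB$gene_id,
         seq = paste0(a$seq, b$seq),
         geneB_offset = nchar(a$seq),
         length = nchar(a$seq) + nchar(b$seq),
         maps = maps, annotations = ann, exons = exons),
    class = "FusionContig"
  )
}

#' @export
print.FusionContig <- function(x, ...) {
  cat(sprintf("FusionContig %s: %d bp (geneB segment starts at %d), %d remapped exons\n",
              x$name, x$length, x$geneB_offset, nrow(x$annotations)))
  invisible(x)
}

#' Write fusion contigs to FASTA and GTF
#'
#' One FASTA record per contig named "geneA--geneB", and a GTF of the remapped
#' exon features in 1-based inclusive coordinates (contig strand is always
#' "+": both genes read in transcribed orientation on the contig).
#'
#' @param contigs List of `FusionContig`s (non-empty, unique names).
#' @param out_fasta,out_gtf Output paths.
#' @export
write_contigs <- function(contigs, out_fasta, out_gtf) {
  if (length(contigs) == 0) stop("no contigs to write")
  nms <- vapply(contigs, function(x) x$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate contig names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(contigs, function(x) x$seq, character(1)))
  names(seqs) <- nms
  Biostrings::writeXStringSet(seqs, out_fasta)
  lines <- unlist(lapply(contigs, function(ct) {
    a <- ct$annotations
    sprintf("%s\tfuseval\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            ct$name, a$cstart + 1L, a$cend, a$gene, a$transcript)
  }))
  writeLines(lines, out_gtf)
  invisible(NULL)
}
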