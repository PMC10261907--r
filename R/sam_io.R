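#' Read alignments to fusion contigs from a SAM/BAM file
#'
#' Parses a coordinate- or name-sorted SAM/BAM file into a per-alignment
#' table (unmapped records are dropped but counted). Edit distances come from
#' the `NM` tag; if absent they fall back to 0 with a warning.
#'
#' @param path SAM or BAM file.
#' @return List with `alignments` (data.frame: `qname`, `flag`, `contig`,
#'   `pos0` 0-based leftmost aligned position, `cigar`, `seq`, `nm`,
#'   `is_first`, `is_reverse`) and `n_fragments` (distinct read names in the
#'   file, mapped or not — the default FFPM denominator source).
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_fragments <- length(unique(res$qname))
  mapped <- !bitwAnd(res$flag, 4L)
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  if (any(is.na(nm[mapped]))) {
    warning("NM tag missing for some alignments; edit distance assumed 0")
    nm[is.na(nm)] <- 0L
  }
  aln <- data.frame(
    qname = res$qname[mapped],
    flag = res$flag[mapped],
    contig = as.character(res$rname)[mapped],
    pos0 = res$pos[mapped] - 1L,
    cigar = res$cigar[mapped],
    seq = as.character(res$seq)[mapped],
    nm = as.integer(nm[mapped]),
    stringsAsFactors = FALSE
  )
  aln$is_first <- bitwAnd(aln$flag, 64L) > 0
  aln$is_reverse <- bitwAnd(aln$flag, 16L) > 0
  list(alignments = aln, n_fragments = n_fragments)
}

# Decompose one CIGAR + leftmost position into N-separated aligned blocks.
# Returns a data.frame with 0-based half-open ref and read coordinates per
# block plus the soft/hard clip lengths at each end. D consumes ref only,
# I/S consume read only, H consumes neither.
cigar_blocks <- function(cigar, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_at <- pos0
  read_at <- 0L
  blocks <- list()
  cur <- NULL  # c(ref_s, read_s)
  cur_ref <- cur_read <- NA_integer_
  open_block <- function() {
    if (is.null(cur)) cur <<- c(ref_at, read_at)
  }
  close_block <- function() {
    if (!is.null(cur)) {
      blocks[[length(blocks) + 1L]] <<- c(cur[1], ref_at, cur[2], read_at)
      cur <<- NULL
    }
  }
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      open_block()
      ref_at <- ref_at + len; read_at <- read_at + len
    } else if (op == "D") {
      open_block()
      ref_at <- ref_at + len
    } else if (op == "I") {
      open_block()
      read_at <- read_at + len
    } else if (op == "N") {
      close_block()
      ref_at <- ref_at + len
    } else if (op == "S") {
      read_at <- read_at + len
    }  # H, P: no consumption tracked
  }
  close_block()
  b <- do.call(rbind, blocks)
  data.frame(ref_start = b[, 1], ref_end = b[, 2],
             read_start = b[, 3], read_end = b[, 4])
}

#' Terminal clipping of an alignment
#'
#' Sum of soft- and hard-clipped bases at each end of the CIGAR.
#'
#' @param cigar A CIGAR string.
#' @return Integer vector `c(left, right)`.
#' @export
end_clipping <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  left <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("S", "H")) left <- left + lens[i] else break
  }
  right <- 0L
  for (i in rev(seq_along(ops))) {
    if (ops[i] %in% c("S", "H")) right <- right + lens[i] else break
  }
  c(left = as.integer(left), right = as.integer(right))
}

# Number of reference-aligned read bases (M/=/X ops).
aligned_length <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  sum(lens[ops %in% c("M", "=", "X")])
}

#' Write SAM records to a file
#'
#' Used by the simulator to emit truth alignments without an aligner.
#'
#' @param records data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `nm`.
#' @param contig_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output SAM path.
#' @export
write_sam <- function(records, contig_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$rnext, records$pnext,
                  records$tlen, records$seq, records$qual, records$nm)
  writeLines(c(header, body), path)
  invisible(path)
}
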