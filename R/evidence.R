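#' Per-read QC thresholds for fusion evidence
#'
#' Defaults are the method's stated settings: 10-base anchors, anchor/read
#' entropy >= 1.2 bits, >= 98% identity, at most 10 clipped bases per read
#' end, and 10-base overlap on each side of a breakpoint for counter reads.
#'
#' @param min_anchor Minimum aligned bases on each side of a split-read
#'   junction.
#' @param min_entropy Minimum Shannon entropy (bits) of anchor/read sequence.
#' @param min_identity Minimum alignment identity fraction.
#' @param max_end_clip Maximum soft+hard clipped bases per read end.
#' @param counter_overlap Minimum aligned bases on each side of a partner
#'   breakpoint for counter-evidence.
#' @return List of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(min_anchor = 10L, min_entropy = 1.2,
                          min_identity = 0.98, max_end_clip = 10L,
                          counter_overlap = 10L) {
  structure(list(min_anchor = min_anchor, min_entropy = min_entropy,
                 min_identity = min_identity, max_end_clip = max_end_clip,
                 counter_overlap = counter_overlap),
            class = "qc_thresholds")
}

#' Shannon sequence entropy
#'
#' Base-2 entropy over the observed A/C/G/T frequencies; `N` bases are
#' excluded from the counts.
#'
#' @param seq Nucleotide string.
#' @return Entropy in bits (0 for a single-symbol sequence, 2 for uniform).
#' @export
sequence_entropy <- function(seq) {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0) {
    stop("empty sequence")
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  if (n == 0) stop("sequence contains no A/C/G/T bases")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Alignment percent identity
#'
#' `(aligned length - edit distance) / aligned length`, where aligned length
#' counts M/=/X bases; indel bases in the edit distance count as errors.
#'
#' @param cigar CIGAR string of the alignment.
#' @param nm Edit distance (NM tag).
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(cigar, nm) {
  alen <- aligned_length(cigar)
  if (alen == 0) stop("alignment has no aligned bases")
  (alen - nm) / alen
}

FRAGMENT_CLASSES <- c("SPLIT", "SPANNING", "COUNTER_5P", "COUNTER_3P",
                      "BACKGROUND", "DISCARD")

read_qc_pass <- function(read, thresholds) {
  clips <- end_clipping(read$cigar)
  ident <- percent_identity(read$cigar, read$nm)
  ident >= thresholds$min_identity && all(clips <= thresholds$max_end_clip)
}

# Locate the junction of a read whose alignment crosses the geneA/geneB
# boundary through an N gap. Returns NULL or a list with the breakpoint and
# anchor statistics (aligned bases and read-base entropy on each side).
find_junction <- function(read, geneB_offset) {
  blocks <- cigar_blocks(read$cigar, read$pos0)
  if (nrow(blocks) < 2) return(NULL)
  for (i in seq_len(nrow(blocks) - 1)) {
    left_last <- blocks$ref_end[i] - 1L
    right_first <- blocks$ref_start[i + 1]
    if (left_last < geneB_offset && right_first >= geneB_offset) {
      anchor_left <- sum(pmin(blocks$read_end[seq_len(i)], .Machine$integer.max) -
                           blocks$read_start[seq_len(i)])
      right_idx <- (i + 1):nrow(blocks)
      anchor_right <- sum(blocks$read_end[right_idx] - blocks$read_start[right_idx])
      left_seq <- substr(read$seq, blocks$read_start[1] + 1L, blocks$read_end[i])
      right_seq <- substr(read$seq, blocks$read_start[i + 1] + 1L,
                          blocks$read_end[nrow(blocks)])
      return(list(left_break = left_last, right_break = right_first,
                  anchor_left = anchor_left, anchor_right = anchor_right,
                  left_seq = left_seq, right_seq = right_seq))
    }
  }
  NULL
}

# Count aligned reference bases of a read at positions <= / > a cut point.
overlap_each_side <- function(blocks, cut) {
  left <- sum(pmax(0L, pmin(blocks$ref_end, cut + 1L) - blocks$ref_start))
  right <- sum(pmax(0L, blocks$ref_end - pmax(blocks$ref_start, cut + 1L)))
  c(left, right)
}

#' Classify one read pair against a fusion contig
#'
#' Applies the per-read QC rules and the split / spanning / counter /
#' background partition. A fragment is `SPLIT` when a mate's alignment
#' crosses the geneA/geneB boundary through a junction gap with adequate
#' anchors; `SPANNING` when the mates align concordantly on opposite sides of
#' the boundary; `COUNTER_5P`/`COUNTER_3P` when an alignment lies wholly
#' within one gene segment and overlaps a candidate partner breakpoint by at
#' least `counter_overlap` aligned bases on each side (candidate breakpoints
#' must be supplied, usually from a first pass over the split reads);
#' `BACKGROUND` otherwise; `DISCARD` when the geometry matches but QC fails.
#'
#' @param pair List of one or two alignment rows (single-row data.frames from
#'   [read_alignments()]); orphan mates are treated as single-end and can
#'   never be `SPANNING`.
#' @param contig A `FusionContig`.
#' @param thresholds A [qc_thresholds()] list.
#' @param breakpoints Optional list of candidate breakpoints, each
#'   `c(left_break, right_break)` in 0-based contig coordinates.
#' @return A `FragmentEvidence` list: `fragment_id`, `class`, `breakpoint`,
#'   `anchor_left`, `anchor_right`, `counter_matches`, `qc`.
#' @export
classify_fragment <- function(pair, contig, thresholds = qc_thresholds(),
                              breakpoints = NULL) {
  reads <- if (is.data.frame(pair)) split(pair, seq_len(nrow(pair))) else pair
  contigs <- unique(vapply(reads, function(r) r$contig, character(1)))
  if (length(contigs) != 1) stop("cross-contig pair: ", paste(contigs, collapse = ","))
  off <- contig$geneB_offset
  fid <- reads[[1]]$qname
  qc_ok <- vapply(reads, read_qc_pass, logical(1), thresholds = thresholds)
  ev <- function(class, breakpoint = NULL, anchor_left = NA_integer_,
                 anchor_right = NA_integer_, counter_matches = list()) {
    structure(list(fragment_id = fid, class = class, breakpoint = breakpoint,
                   anchor_left = anchor_left, anchor_right = anchor_right,
                   counter_matches = counter_matches,
                   qc = list(pass = qc_ok)),
              class = "FragmentEvidence")
  }

  # SPLIT: a junction-crossing mate defines the breakpoint
  for (i in seq_along(reads)) {
    jx <- find_junction(reads[[i]], off)
    if (!is.null(jx)) {
      if (!qc_ok[i]) return(ev("DISCARD"))
      anchors_ok <- jx$anchor_left >= thresholds$min_anchor &&
        jx$anchor_right >= thresholds$min_anchor
      entropy_ok <- sequence_entropy(jx$left_seq) >= thresholds$min_entropy &&
        sequence_entropy(jx$right_seq) >= thresholds$min_entropy
      if (anchors_ok && entropy_ok) {
        return(ev("SPLIT", breakpoint = c(jx$left_break, jx$right_break),
                  anchor_left = jx$anchor_left, anchor_right = jx$anchor_right))
      }
      return(ev("DISCARD"))
    }
  }

  blocks <- lapply(reads, function(r) cigar_blocks(r$cigar, r$pos0))
  lo <- vapply(blocks, function(b) min(b$ref_start), numeric(1))
  hi <- vapply(blocks, function(b) max(b$ref_end), numeric(1)) - 1

  # SPANNING: two mates wholly on opposite sides, FR orientation
  if (length(reads) == 2) {
    side <- ifelse(hi < off, "A", ifelse(lo >= off, "B", NA))
    if (!anyNA(side) && side[1] != side[2]) {
      rev_flags <- vapply(reads, function(r) r$is_reverse, logical(1))
      concordant <- sum(rev_flags) == 1
      if (concordant) {
        if (!all(qc_ok)) return(ev("DISCARD"))
        ent_ok <- all(vapply(reads, function(r) {
          sequence_entropy(r$seq) >= thresholds$min_entropy
        }, logical(1)))
        if (ent_ok) return(ev("SPANNING")) else return(ev("DISCARD"))
      }
    }
  }

  # COUNTER: wholly within one gene, straddling a candidate partner breakpoint
  if (length(breakpoints) > 0) {
    for (i in seq_along(reads)) {
      b <- blocks[[i]]
      if (hi[i] < off) {            # geneA side: test the 5' breakpoints
        hits <- Filter(function(bp) {
          all(overlap_each_side(b, bp[1]) >= thresholds$counter_overlap)
        }, breakpoints)
        if (length(hits) > 0) {
          if (!qc_ok[i]) return(ev("DISCARD"))
          return(ev("COUNTER_5P", counter_matches = hits))
        }
      } else if (lo[i] >= off) {    # geneB side: test the 3' breakpoints
        hits <- Filter(function(bp) {
          all(overlap_each_side(b, bp[2] - 1L) >= thresholds$counter_overlap)
        }, breakpoints)
        if (length(hits) > 0) {
          if (!qc_ok[i]) return(ev("DISCARD"))
          return(ev("COUNTER_3P", counter_matches = hits))
        }
      }
    }
  }

  if (all(qc_ok)) ev("BACKGROUND") else ev("DISCARD")
}

#' Classify all alignments on one fusion contig
#'
#' Two-pass driver: fragments are first partitioned into split / spanning /
#' background, candidate breakpoints are taken from the split reads, and
#' non-supporting fragments are then re-examined for counter-evidence against
#' those breakpoints.
#'
#' @param aln Alignment data.frame from [read_alignments()], restricted to
#'   one contig.
#' @param contig A `FusionContig`.
#' @param thresholds A [qc_thresholds()] list.
#' @return Named list of `FragmentEvidence`, one per fragment.
#' @export
classify_alignments <- function(aln, contig, thresholds = qc_thresholds()) {
  stopifnot(all(aln$contig == contig$name))
  pairs <- split(aln, aln$qname)
  pass1 <- lapply(pairs, classify_fragment, contig = contig,
                  thresholds = thresholds, breakpoints = NULL)
  bps <- unique(lapply(Filter(function(e) e$class == "SPLIT", pass1),
                       function(e) e$breakpoint))
  if (length(bps) == 0) return(pass1)
  redo <- vapply(pass1, function(e) e$class == "BACKGROUND", logical(1))
  pass2 <- lapply(pairs[redo], classify_fragment, contig = contig,
                  thresholds = thresholds, breakpoints = bps)
  pass1[redo] <- pass2
  pass1
}

#' Collect breakpoint candidates from classified fragments
#'
#' One candidate per distinct (left_break, right_break) seen in a split read.
#' Spanning fragments are assigned to the compatible set of every breakpoint
#' their insert could bridge (the geneA-side mate lies entirely at or before
#' `left_break` and the geneB-side mate at or after `right_break`); counter
#' reads are tallied per side. Spanning-only evidence never creates a
#' candidate.
#'
#' @param fragments List of `FragmentEvidence` from one contig.
#' @param aln The alignment data.frame the fragments were classified from
#'   (needed to place spanning mates relative to each breakpoint).
#' @param contig A `FusionContig`.
#' @return List of `BreakpointCandidate`: `contig`, `left_break`,
#'   `right_break`, `split_read_ids`, `spanning_compatible_ids`,
#'   `counter_5p_count`, `counter_3p_count`.
#' @export
collect_breakpoints <- function(fragments, aln, contig) {
  splits <- Filter(function(e) e$class == "SPLIT", fragments)
  if (length(splits) == 0) return(list())
  keys <- vapply(splits, function(e) paste(e$breakpoint, collapse = ":"), character(1))
  groups <- split(splits, keys)

  spanning <- Filter(function(e) e$class == "SPANNING", fragments)
  span_extents <- lapply(spanning, function(e) {
    rows <- aln[aln$qname == e$fragment_id, , drop = FALSE]
    ext <- lapply(seq_len(nrow(rows)), function(i) {
      b <- cigar_blocks(rows$cigar[i], rows$pos0[i])
      c(min(b$ref_start), max(b$ref_end) - 1L)
    })
    lo <- vapply(ext, `[`, numeric(1), 2)   # per-mate last base
    side_a <- which(lo < contig$geneB_offset)
    list(a_end = max(vapply(ext[side_a], `[`, numeric(1), 2)),
         b_start = min(vapply(ext[-side_a], `[`, numeric(1), 1)))
  })
  names(span_extents) <- vapply(spanning, function(e) e$fragment_id, character(1))

  counters <- Filter(function(e) e$class %in% c("COUNTER_5P", "COUNTER_3P"), fragments)

  out <- lapply(groups, function(g) {
    bp <- g[[1]]$breakpoint
    compat <- names(Filter(function(se) {
      se$a_end <= bp[1] && se$b_start >= bp[2]
    }, span_extents))
    c5 <- sum(vapply(counters, function(e) {
      e$class == "COUNTER_5P" &&
        any(vapply(e$counter_matches, function(m) m[1] == bp[1], logical(1)))
    }, logical(1)))
    c3 <- sum(vapply(counters, function(e) {
      e$class == "COUNTER_3P" &&
        any(vapply(e$counter_matches, function(m) m[2] == bp[2], logical(1)))
    }, logical(1)))
    structure(
      list(contig = contig$name, left_break = bp[1], right_break = bp[2],
           split_read_ids = vapply(g, function(e) e$fragment_id, character(1)),
           spanning_compatible_ids = compat,
           counter_5p_count = c5, counter_3p_count = c3),
      class = "BreakpointCandidate"
    )
  })
  ord <- order(vapply(out, function(b) b$left_break, numeric(1)),
               vapply(out, function(b) b$right_break, numeric(1)))
  unname(out[ord])
}
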