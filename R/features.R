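#' Attribute order of the 9-feature fusion variant vector
#' @export
FEATURE_NAMES <- c("ffpm", "far_5p", "far_3p", "counter_ffpm_5p",
                   "counter_ffpm_3p", "consensus_indicator",
                   "ref_agree_indicator", "n_microhomologies",
                   "microhomology_distance")

#' Find exact k-mer microhomologies between the two genes of a fusion contig
#'
#' Enumerates every pair of positions `(posA, posB)` such that the `k`-mer
#' starting at `posA` in the geneA segment equals the `k`-mer starting at
#' `posB` in the geneB segment (0-based contig coordinates; k-mers containing
#' `N` are excluded). Matches are reported as all start pairs, not merged
#' into maximal exact matches.
#'
#' @param contig A `FusionContig` (length at least `2k`).
#' @param k Microhomology k-mer length (default 10; must be >= 4).
#' @return A `MicrohomologyMap`: list with `k` and `matches` (data.frame
#'   `posA`, `posB` sorted by `posA`, `posB`).
#' @export
find_microhomologies <- function(contig, k = 10L) {
  if (k < 4) stop("k must be at least 4")
  off <- contig$geneB_offset
  if (contig$length < 2 * k) stop("contig shorter than 2k")
  seq_a <- substr(contig$seq, 1L, off)
  seq_b <- substr(contig$seq, off + 1L, contig$length)
  kmer_table <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(NULL)
    km <- substring(s, 1:n, k:(k + n - 1L))
    keep <- !grepl("N", km, fixed = TRUE)
    split(which(keep) - 1L, km[keep])   # 0-based local starts per k-mer
  }
  ta <- kmer_table(seq_a)
  tb <- kmer_table(seq_b)
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0) {
    matches <- data.frame(posA = integer(0), posB = integer(0))
  } else {
    pairs <- lapply(shared, function(km) {
      expand.grid(posA = ta[[km]], posB = tb[[km]] + off,
                  KEEP.OUT.ATTRS = FALSE)
    })
    matches <- do.call(rbind, pairs)
    matches <- matches[order(matches$posA, matches$posB), , drop = FALSE]
    rownames(matches) <- NULL
  }
  structure(list(k = as.integer(k), matches = matches,
                 contig = contig$name, geneB_offset = off),
            class = "MicrohomologyMap")
}

#' Splice dinucleotides flanking a fusion breakpoint
#'
#' The donor is the two contig bases immediately after the last 5'-segment
#' base (`left_break`); the acceptor is the two bases immediately before the
#' first 3'-segment base (`right_break`). The pair is consensus when it is in
#' `consensus_set` (default the canonical GT-AG; GC-AG / AT-AC can be
#' enabled).
#'
#' @param contig A `FusionContig`.
#' @param bp A `BreakpointCandidate` or `c(left_break, right_break)`.
#' @param consensus_set Character vector of accepted donor+acceptor 4-mers.
#' @return List `donor`, `acceptor`, `consensus`.
#' @export
breakpoint_dinucleotides <- function(contig, bp, consensus_set = "GTAG") {
  pos <- breakpoint_pair(bp)
  left <- pos[1]; right <- pos[2]
  if (left < 2L || left + 3L > contig$length ||
      right < 2L || right + 2L > contig$length) {
    stop("edge breakpoint")
  }
  donor <- substr(contig$seq, left + 2L, left + 3L)      # 0-based left+1..left+2
  acceptor <- substr(contig$seq, right - 1L, right)      # 0-based right-2..right-1
  list(donor = donor, acceptor = acceptor,
       consensus = paste0(donor, acceptor) %in% consensus_set)
}

breakpoint_pair <- function(bp) {
  if (inherits(bp, "BreakpointCandidate")) c(bp$left_break, bp$right_break)
  else as.integer(bp[1:2])
}

#' Agreement of a breakpoint with reference exon boundaries
#'
#' The left side agrees when `left_break` equals an annotated exon 3' end of
#' geneA in transcribed orientation (exon union view); the right side agrees
#' when `right_break` equals an annotated exon 5' start of geneB. The splice
#' type is `ONLY_REF_SPLICE` (consensus dinucleotides and both sides agree),
#' `INCL_NON_REF_SPLICE` (consensus but at least one novel boundary) or
#' `NON_CANONICAL` (non-consensus dinucleotides, regardless of boundaries).
#'
#' @inheritParams breakpoint_dinucleotides
#' @return List `left_ref_agree`, `right_ref_agree`, `consensus`,
#'   `splice_type`.
#' @export
reference_agreement <- function(bp, contig, consensus_set = "GTAG") {
  pos <- breakpoint_pair(bp)
  exA <- contig$exons[[contig$gene_a]]
  exB <- contig$exons[[contig$gene_b]]
  left_agree <- any(exA$cend - 1L == pos[1])
  right_agree <- any(exB$cstart == pos[2])
  din <- breakpoint_dinucleotides(contig, pos, consensus_set)
  splice_type <- if (!din$consensus) {
    "NON_CANONICAL"
  } else if (left_agree && right_agree) {
    "ONLY_REF_SPLICE"
  } else {
    "INCL_NON_REF_SPLICE"
  }
  list(left_ref_agree = left_agree, right_ref_agree = right_agree,
       consensus = din$consensus, splice_type = splice_type)
}

#' Euclidean distance from a breakpoint to the nearest microhomology
#'
#' Distance in the fusion-contig coordinate plane between the breakpoint
#' `(left_break, right_break)` and the nearest exact k-mer match
#' `(posA, posB)`. With no microhomologies at all the contig diagonal
#' `sqrt(len_A^2 + len_B^2)` is returned as a finite "maximally distant"
#' sentinel, keeping the feature usable for scaling.
#'
#' @param bp A `BreakpointCandidate` or `c(left_break, right_break)`.
#' @param mh A `MicrohomologyMap` from [find_microhomologies()].
#' @param contig The `FusionContig` (needed for the sentinel).
#' @return Non-negative distance.
#' @export
microhomology_distance <- function(bp, mh, contig) {
  pos <- breakpoint_pair(bp)
  m <- mh$matches
  if (nrow(m) == 0) {
    len_a <- contig$geneB_offset
    len_b <- contig$length - contig$geneB_offset
    return(sqrt(len_a^2 + len_b^2))
  }
  min(sqrt((pos[1] - m$posA)^2 + (pos[2] - m$posB)^2))
}

#' Assemble the 9-attribute feature vector of a fusion variant
#'
#' Fixed-order numeric vector used for clustering and classification:
#' expression (FFPM), 5'/3' fusion allelic ratios, 5'/3' counter FFPM,
#' consensus-splice and reference-boundary indicators (1/0), microhomology
#' count and breakpoint-to-microhomology distance.
#'
#' @param ffpm Fusion expression, fragments per million.
#' @param far_5p,far_3p Fusion allelic ratios.
#' @param counter_ffpm_5p,counter_ffpm_3p Unfused partner expression proxies.
#' @param consensus Logical: consensus splice dinucleotides at the breakpoint.
#' @param ref_agree Logical: both breakpoint sides match reference exon
#'   boundaries.
#' @param n_microhomologies Exact k-mer match count between the partners.
#' @param microhomology_distance Distance to the nearest microhomology.
#' @return Named numeric vector in `FEATURE_NAMES` order.
#' @export
assemble_feature_vector <- function(ffpm, far_5p, far_3p, counter_ffpm_5p,
                                    counter_ffpm_3p, consensus, ref_agree,
                                    n_microhomologies, microhomology_distance) {
  ind <- function(x) if (length(x) != 1 || is.na(x)) NA_real_ else as.numeric(as.logical(x))
  v <- c(ffpm = as.numeric(ffpm),
         far_5p = as.numeric(far_5p),
         far_3p = as.numeric(far_3p),
         counter_ffpm_5p = as.numeric(counter_ffpm_5p),
         counter_ffpm_3p = as.numeric(counter_ffpm_3p),
         consensus_indicator = ind(consensus),
         ref_agree_indicator = ind(ref_agree),
         n_microhomologies = as.numeric(n_microhomologies),
         microhomology_distance = as.numeric(microhomology_distance))
  if (anyNA(v)) {
    stop("missing attribute(s): ", paste(names(v)[is.na(v)], collapse = ", "))
  }
  stopifnot(identical(names(v), FEATURE_NAMES))
  v
}
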