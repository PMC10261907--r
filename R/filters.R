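FILTER_RULES <- c("MIN_SPLIT", "NON_CONSENSUS_SPLIT", "LDAS", "PROMISCUITY",
                  "PARALOG")

new_filter_decision <- function(id, failed) {
  structure(list(id = id, passed = length(failed) == 0,
                 failed_rules = failed),
            class = "FilterDecision")
}

#' Minimum split-read evidence filter
#'
#' A variant needs at least one split read defining its junction; if the
#' breakpoint has non-consensus dinucleotide splice sites, at least three
#' split reads are required.
#'
#' @param bp A `BreakpointCandidate`.
#' @param consensus Logical: consensus splice dinucleotides at this
#'   breakpoint (from [breakpoint_dinucleotides()]).
#' @return A `FilterDecision` (`id`, `passed`, `failed_rules`).
#' @export
min_evidence_filter <- function(bp, consensus) {
  n_split <- length(bp$split_read_ids)
  failed <- character(0)
  if (n_split < 1) failed <- c(failed, "MIN_SPLIT")
  if (!consensus && n_split < 3) failed <- c(failed, "NON_CONSENSUS_SPLIT")
  new_filter_decision(breakpoint_id(bp), failed)
}

breakpoint_id <- function(bp) {
  paste0(bp$contig, ":", bp$left_break, "-", bp$right_break)
}

#' Long double anchor support (LDAS) filter
#'
#' Passes when at least one single split read aligns `min_anchor` (default
#' 25) bases on both sides of the breakpoint. An aggregate mode (best left
#' anchor and best right anchor may come from different reads) is available
#' but off by default.
#'
#' @param bp A `BreakpointCandidate`.
#' @param split_evidence List of `FragmentEvidence` of class `SPLIT` at this
#'   breakpoint.
#' @param min_anchor Required anchor length per side.
#' @param aggregate Use the aggregate (per-side maxima) reading instead of
#'   the per-read one.
#' @return A `FilterDecision`.
#' @export
ldas_filter <- function(bp, split_evidence, min_anchor = 25L,
                        aggregate = FALSE) {
  al <- vapply(split_evidence, function(e) e$anchor_left, numeric(1))
  ar <- vapply(split_evidence, function(e) e$anchor_right, numeric(1))
  ok <- if (length(al) == 0) {
    FALSE
  } else if (aggregate) {
    max(al) >= min_anchor && max(ar) >= min_anchor
  } else {
    any(al >= min_anchor & ar >= min_anchor)
  }
  new_filter_decision(breakpoint_id(bp), if (ok) character(0) else "LDAS")
}

#' Promiscuous fusion partner filter
#'
#' Within one sample, any gene that appears as a partner in more than
#' `max_partners` distinct fusions marks all of its fusions failed.
#'
#' @param fusions data.frame with columns `gene_a`, `gene_b` (and optionally
#'   `support`), one row per fusion in the sample.
#' @param max_partners Promiscuity cap (default 10: keep genes with at most
#'   10 distinct partners).
#' @return List of `FilterDecision`, one per input row (order preserved).
#' @export
promiscuity_filter <- function(fusions, max_partners = 10L) {
  partner_count <- function(gene, fus) {
    length(unique(c(fus$gene_b[fus$gene_a == gene],
                    fus$gene_a[fus$gene_b == gene])))
  }
  genes <- unique(c(fusions$gene_a, fusions$gene_b))
  promiscuous <- genes[vapply(genes, partner_count, integer(1),
                              fus = fusions) > max_partners]
  lapply(seq_len(nrow(fusions)), function(i) {
    bad <- fusions$gene_a[i] %in% promiscuous ||
      fusions$gene_b[i] %in% promiscuous
    new_filter_decision(paste0(fusions$gene_a[i], "--", fusions$gene_b[i]),
                        if (bad) "PROMISCUITY" else character(0))
  })
}

#' Read a two-column paralog pair file
#'
#' @param path TSV with two gene-id columns (unordered pairs, no header).
#' @return data.frame with columns `g1`, `g2`.
#' @export
read_paralog_pairs <- function(path) {
  d <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                error = function(e) stop("malformed paralog file: ",
                                         conditionMessage(e)))
  if (ncol(d) < 2) stop("malformed paralog file: expected two columns")
  data.frame(g1 = as.character(d[[1]]), g2 = as.character(d[[2]]),
             stringsAsFactors = FALSE)
}

#' Paralog shadow filter
#'
#' A fusion fails when another fusion in the same sample has strictly more
#' supporting fragments and its partners are, position by position, either
#' the same gene or a listed paralog.
#'
#' @param fusions data.frame with columns `gene_a`, `gene_b`, `support`.
#' @param paralog_pairs data.frame of unordered paralog pairs (`g1`, `g2`),
#'   e.g. from [read_paralog_pairs()]; may be empty.
#' @return List of `FilterDecision`, one per input row (order preserved).
#' @export
paralog_filter <- function(fusions, paralog_pairs = NULL) {
  related <- function(x, y) {
    if (x == y) return(TRUE)
    if (is.null(paralog_pairs) || nrow(paralog_pairs) == 0) return(FALSE)
    any((paralog_pairs$g1 == x & paralog_pairs$g2 == y) |
          (paralog_pairs$g1 == y & paralog_pairs$g2 == x))
  }
  n <- nrow(fusions)
  lapply(seq_len(n), function(i) {
    shadowed <- any(vapply(seq_len(n), function(j) {
      j != i && fusions$support[j] > fusions$support[i] &&
        related(fusions$gene_a[i], fusions$gene_a[j]) &&
        related(fusions$gene_b[i], fusions$gene_b[j])
    }, logical(1)))
    new_filter_decision(paste0(fusions$gene_a[i], "--", fusions$gene_b[i]),
                        if (shadowed) "PARALOG" else character(0))
  })
}

# Merge several FilterDecision objects for the same id.
combine_decisions <- function(...) {
  ds <- list(...)
  new_filter_decision(ds[[1]]$id,
                      unique(unlist(lapply(ds, function(d) d$failed_rules))))
}
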