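#' EM fractional assignment of spanning fragments to fusion variants
#'
#' Split reads are unique to the breakpoint they define, but spanning
#' fragments are often compatible with several variants of the same fusion.
#' Starting from uniform abundances, the E-step assigns each ambiguous
#' spanning fragment across its compatible variants proportionally to the
#' current abundance estimates, and the M-step resets each abundance to its
#' unique split count plus its fractional spanning mass, iterating to a fixed
#' point.
#'
#' @param variants List of `BreakpointCandidate` (each with at least one
#'   split read and known spanning compatibility sets).
#' @param tol Convergence tolerance on the largest abundance change.
#' @param max_iter Iteration cap.
#' @param trace Keep the per-iteration abundance estimates (attribute
#'   `"trace"`, an iterations x variants matrix) for diagnostics.
#' @return data.frame with one row per variant: `left_break`, `right_break`,
#'   `unique_split_count`, `est_spanning`, `est_total_fragments`.
#' @export
em_assign <- function(variants, tol = 1e-6, max_iter = 1000L, trace = FALSE) {
  if (length(variants) == 0) {
    return(data.frame(left_break = integer(0), right_break = integer(0),
                      unique_split_count = integer(0),
                      est_spanning = numeric(0),
                      est_total_fragments = numeric(0)))
  }
  n <- length(variants)
  u <- vapply(variants, function(v) length(v$split_read_ids), integer(1))
  if (any(u < 1)) stop("every variant must have at least one split read")
  frag_ids <- unique(unlist(lapply(variants, function(v) v$spanning_compatible_ids)))
  compat <- matrix(FALSE, nrow = length(frag_ids), ncol = n,
                   dimnames = list(frag_ids, NULL))
  for (j in seq_len(n)) compat[variants[[j]]$spanning_compatible_ids, j] <- TRUE

  theta <- rep(1 / n, n)
  frac <- rep(0, n)
  hist <- if (trace) list() else NULL
  for (iter in seq_len(max_iter)) {
    frac_new <- rep(0, n)
    if (nrow(compat) > 0) {
      w <- sweep(compat * 1, 2, theta, `*`)
      rs <- rowSums(w)
      w <- w / rs
      frac_new <- colSums(w)
    }
    a_new <- u + frac_new
    theta_new <- a_new / sum(a_new)
    if (trace) hist[[iter]] <- a_new
    converged <- max(abs(a_new - (u + frac))) < tol
    frac <- frac_new
    theta <- theta_new
    if (converged) break
  }
  res <- data.frame(
    left_break = vapply(variants, function(v) v$left_break, numeric(1)),
    right_break = vapply(variants, function(v) v$right_break, numeric(1)),
    unique_split_count = u,
    est_spanning = frac,
    est_total_fragments = u + frac
  )
  if (trace) attr(res, "trace") <- do.call(rbind, hist)
  res
}

#' Fusion fragments per million (FFPM)
#'
#' @param fragments Supporting fragment count (may be EM-estimated, so
#'   fractional).
#' @param total_fragments Total sequenced fragments in the sample.
#' @return `fragments * 1e6 / total_fragments`.
#' @export
ffpm <- function(fragments, total_fragments) {
  if (length(total_fragments) != 1 || is.na(total_fragments) ||
      total_fragments <= 0) {
    stop("total_fragments must be a positive count")
  }
  fragments * 1e6 / total_fragments
}

#' Fusion allelic ratio (FAR)
#'
#' Ratio of mutually exclusive fusion-supporting fragments to
#' counter-evidence fragments for one unfused partner, with +1 pseudocounts
#' on both sides so the ratio stays finite when counter-evidence is absent
#' (the common case for strong fusions).
#'
#' @param fusion_fragments Fusion-supporting fragments (EM-estimated total).
#' @param counter_fragments Counter-evidence read count at the corresponding
#'   partner breakpoint.
#' @return `(fusion_fragments + 1) / (counter_fragments + 1)`.
#' @export
fusion_allelic_ratio <- function(fusion_fragments, counter_fragments) {
  stopifnot(all(is.finite(fusion_fragments)), all(is.finite(counter_fragments)),
            all(fusion_fragments >= 0), all(counter_fragments >= 0))
  (fusion_fragments + 1) / (counter_fragments + 1)
}

#' Tumor-enrichment score of a fusion across cohorts
#'
#' `((n_tumor_with + 1) / n_tumor) / ((n_normal_with + 1) / n_normal)`.
#'
#' @param n_tumor_with,n_normal_with Samples carrying the fusion.
#' @param n_tumor,n_normal Total samples per cohort (must be positive).
#' @return Positive real enrichment score.
#' @export
tumor_enrichment <- function(n_tumor_with, n_tumor, n_normal_with, n_normal) {
  if (any(c(n_tumor, n_normal) <= 0)) stop("cohort totals must be positive")
  ((n_tumor_with + 1) / n_tumor) / ((n_normal_with + 1) / n_normal)
}
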