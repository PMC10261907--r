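# Shared fixtures and independent oracles. Everything is generated in code;
# no binary or stored test data.

# --- tiny hand-written reference (GTF parsing / error cases) ---------------

write_toy_reference <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  set.seed(20240101)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  chr2 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", chr1, ">chr2", chr2), fasta)
  gtf <- file.path(dir, "toy.gtf")
  writeLines(c(
    'chr1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1";',
    'chr1\ttoy\texon\t301\t400\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1";',
    'chr1\ttoy\texon\t501\t600\t.\t-\t.\tgene_id "GB"; transcript_id "GB.t1";',
    'chr1\ttoy\texon\t701\t800\t.\t-\t.\tgene_id "GB"; transcript_id "GB.t1";',
    'chr1\ttoy\texon\t101\t160\t.\t+\t.\tgene_id "GSPLIT"; transcript_id "GS.t1";',
    'chr2\ttoy\texon\t101\t160\t.\t+\t.\tgene_id "GSPLIT"; transcript_id "GS.t1";'
  ), gtf)
  list(fasta = fasta, gtf = gtf, chr1 = chr1, chr2 = chr2)
}

# --- synthetic FusionContig without genome plumbing ------------------------
# (for evidence / feature unit tests where only the contig contract matters)

fake_contig <- function(seq_a, seq_b, exons_a = NULL, exons_b = NULL,
                        gene_a = "GA", gene_b = "GB") {
  if (is.null(exons_a)) exons_a <- data.frame(cstart = 0L, cend = nchar(seq_a))
  if (is.null(exons_b)) exons_b <- data.frame(cstart = nchar(seq_a),
                                              cend = nchar(seq_a) + nchar(seq_b))
  exons <- list(exons_a, exons_b)
  names(exons) <- c(gene_a, gene_b)
  structure(
    list(name = paste0(gene_a, "--", gene_b), gene_a = gene_a, gene_b = gene_b,
         seq = paste0(seq_a, seq_b), geneB_offset = nchar(seq_a),
         length = nchar(seq_a) + nchar(seq_b), maps = list(),
         annotations = NULL, exons = exons),
    class = "FusionContig")
}

make_read <- function(qname, contig, pos0, cigar, seq, nm = 0L, flag = 99L) {
  data.frame(qname = qname, flag = flag, contig = contig, pos0 = pos0,
             cigar = cigar, seq = seq, nm = nm,
             is_first = bitwAnd(flag, 64L) > 0,
             is_reverse = bitwAnd(flag, 16L) > 0,
             stringsAsFactors = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

fake_breakpoint <- function(left, right, contig = "GA--GB",
                            split_ids = character(0), span_ids = character(0),
                            c5 = 0L, c3 = 0L) {
  structure(list(contig = contig, left_break = left, right_break = right,
                 split_read_ids = split_ids, spanning_compatible_ids = span_ids,
                 counter_5p_count = c5, counter_3p_count = c3),
            class = "BreakpointCandidate")
}

fake_split_evidence <- function(id, left, right, anchor_left, anchor_right) {
  structure(list(fragment_id = id, class = "SPLIT",
                 breakpoint = c(left, right), anchor_left = anchor_left,
                 anchor_right = anchor_right, counter_matches = list(),
                 qc = list(pass = TRUE)),
            class = "FragmentEvidence")
}

unname_df <- function(df, new_names) {
  out <- df
  names(out) <- new_names
  rownames(out) <- NULL
  out
}

# --- independent oracles ---------------------------------------------------

# brute-force scan of every geneA k-mer against the geneB segment, via
# Biostrings Aho-Corasick matching (independent of the package's hash join)
oracle_microhomologies <- function(seq_a, seq_b, k) {
  n <- nchar(seq_a) - k + 1L
  av <- Biostrings::DNAStringSet(Biostrings::DNAString(seq_a),
                                 start = 1:n, width = k)
  hits <- Biostrings::matchPDict(Biostrings::PDict(av),
                                 Biostrings::DNAString(seq_b))
  starts <- Biostrings::startIndex(hits)
  res <- lapply(seq_len(n), function(i) {
    sb <- starts[[i]]
    if (length(sb) == 0) return(NULL)
    data.frame(posA = i - 1L, posB = sb - 1L + nchar(seq_a))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(posA = integer(0), posB = integer(0)))
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive hypergeometric upper-tail by direct density summation
oracle_fisher_tail <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  xs <- a:min(K, n)
  sum(stats::dhyper(xs, K, N - K, n))
}

# closed-form EM fixed point for two variants sharing all spanning mass
oracle_em_two_variants <- function(u1, u2, s) {
  tot <- u1 + u2 + s
  c(u1 * tot / (u1 + u2), u2 * tot / (u1 + u2))
}

# default scenario wrapper used by several test files
run_scenario <- function(cfg, fusions, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sc <- simulate_scenario(cfg, fusions, file.path(dir, "sim"))
  rc <- run_config(fusions = sc$fusions, fasta = sc$fasta, gtf = sc$gtf,
                   sam = sc$sam, seed = cfg$seed)
  res <- suppressMessages(run_inspect(rc))
  list(sc = sc, res = res)
}
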