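# Read simulation against fusion contigs: emits truth SAM records (no
# aligner involved) for split, spanning, counter and background fragments.

sam_record <- function(qname, flag, rname, pos0, cigar, seq, nm,
                       mate_pos0, tlen) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos0 + 1L,
             mapq = 60L, cigar = cigar, rnext = "=", pnext = mate_pos0 + 1L,
             tlen = tlen, seq = seq, qual = strrep("I", nchar(seq)),
             nm = nm, stringsAsFactors = FALSE)
}

apply_errors <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n = 0L))
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(list(seq = seq, n = 0L))
  chars <- strsplit(seq, "")[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n = length(hit))
}

exon_row_containing <- function(exdf, pos) {
  i <- which(exdf$cstart <= pos & pos < exdf$cend)
  if (length(i) == 0) stop("position ", pos, " not inside an annotated exon")
  i[1]
}

#' Simulate reads for one fusion contig
#'
#' Emits the requested numbers of split, spanning, counter and background
#' fragments as SAM records with correct CIGAR and NM against the fusion
#' contig, plus a truth table listing every fragment exactly once. Split
#' reads carry an `aM<gap>NbM` junction alignment across the planted
#' breakpoint; spanning mates sit wholly in the breakpoint-adjacent exons on
#' opposite sides; counter reads are contiguous alignments straddling one
#' partner's breakpoint within that gene's segment (unfused pre-mRNA-style
#' support); background pairs live in the first exon of each gene, away from
#' all breakpoints.
#'
#' @param contig A `FusionContig`.
#' @param variants List of planted variants, each
#'   `list(name, mode, left, right)` with 0-based contig breakpoints (empty
#'   for a background-only contig).
#' @param cfg A [sim_config()].
#' @return List with `records` (SAM record data.frame) and `truth`
#'   (data.frame: `fragment_id`, `contig`, `fusion`, `class`, `left_break`,
#'   `right_break`).
#' @export
simulate_reads <- function(contig, variants, cfg) {
  rl <- cfg$read_length
  if (cfg$frag_mean < rl) stop("fragment length below read length")
  off <- contig$geneB_offset
  exA <- contig$exons[[contig$gene_a]]
  exB <- contig$exons[[contig$gene_b]]
  recs <- list()
  truth <- list()
  sub <- function(s, e) substr(contig$seq, s + 1L, e)  # 0-based [s, e)
  emit_pair <- function(fid, class, bp, r1, r2) {
    # r_: list(pos0, cigar, seq)
    e1 <- apply_errors(r1$seq, cfg$error_rate)
    e2 <- apply_errors(r2$seq, cfg$error_rate)
    tl <- max(r1$pos0, r2$pos0) + rl - min(r1$pos0, r2$pos0)
    recs[[length(recs) + 1L]] <<- rbind(
      sam_record(fid, 99L, contig$name, r1$pos0, r1$cigar, e1$seq, e1$n,
                 r2$pos0, tl),
      sam_record(fid, 147L, contig$name, r2$pos0, r2$cigar, e2$seq, e2$n,
                 r1$pos0, -tl)
    )
    truth[[length(truth) + 1L]] <<- data.frame(
      fragment_id = fid, contig = contig$name,
      fusion = contig$name,
      class = class,
      left_break = if (is.null(bp)) NA_integer_ else bp[1],
      right_break = if (is.null(bp)) NA_integer_ else bp[2],
      stringsAsFactors = FALSE)
  }

  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    lb <- v$left; rb <- v$right
    ia <- exon_row_containing(exA, lb)
    ib <- exon_row_containing(exB, rb)
    donor_start <- exA$cstart[ia]
    acceptor_end <- exB$cend[ib]
    gap <- rb - lb - 1L
    for (i in seq_len(cfg$n_split)) {
      aL <- sample(cfg$split_anchor_range[1]:cfg$split_anchor_range[2], 1)
      aR <- rl - aL
      pos <- lb - aL + 1L
      stopifnot(pos >= donor_start, rb + aR <= acceptor_end)
      seq <- paste0(sub(pos, lb + 1L), sub(rb, rb + aR))
      cigar <- sprintf("%dM%dN%dM", aL, gap, aR)
      mate_pos <- sample(donor_start:(lb - rl + 1L), 1)
      emit_pair(sprintf("%s.v%d.split.%03d", contig$name, vi, i),
                "SPLIT", c(lb, rb),
                r1 = list(pos0 = mate_pos, cigar = sprintf("%dM", rl),
                          seq = sub(mate_pos, mate_pos + rl)),
                r2 = list(pos0 = pos, cigar = cigar, seq = seq))
    }
    for (i in seq_len(cfg$n_spanning)) {
      p1 <- sample(donor_start:(lb - rl + 1L), 1)
      p2 <- sample(rb:(acceptor_end - rl), 1)
      emit_pair(sprintf("%s.v%d.span.%03d", contig$name, vi, i),
                "SPANNING", c(lb, rb),
                r1 = list(pos0 = p1, cigar = sprintf("%dM", rl),
                          seq = sub(p1, p1 + rl)),
                r2 = list(pos0 = p2, cigar = sprintf("%dM", rl),
                          seq = sub(p2, p2 + rl)))
    }
    for (i in seq_len(cfg$n_counter_5p)) {
      o1 <- sample(20:(rl - 20L), 1)
      pos <- lb - o1 + 1L
      stopifnot(pos >= 0L, pos + rl <= off)
      mate_pos <- max(0L, pos - 180L)
      emit_pair(sprintf("%s.v%d.c5p.%03d", contig$name, vi, i),
                "COUNTER_5P", c(lb, rb),
                r1 = list(pos0 = mate_pos, cigar = sprintf("%dM", rl),
                          seq = sub(mate_pos, mate_pos + rl)),
                r2 = list(pos0 = pos, cigar = sprintf("%dM", rl),
                          seq = sub(pos, pos + rl)))
    }
    for (i in seq_len(cfg$n_counter_3p)) {
      o1 <- sample(20:(rl - 20L), 1)
      pos <- rb - o1
      stopifnot(pos >= off, pos + rl <= contig$length)
      mate_pos <- min(contig$length - rl, pos + 180L)
      emit_pair(sprintf("%s.v%d.c3p.%03d", contig$name, vi, i),
                "COUNTER_3P", c(lb, rb),
                r1 = list(pos0 = pos, cigar = sprintf("%dM", rl),
                          seq = sub(pos, pos + rl)),
                r2 = list(pos0 = mate_pos, cigar = sprintf("%dM", rl),
                          seq = sub(mate_pos, mate_pos + rl)))
    }
  }

  bg_windows <- list(c(exA$cstart[1], exA$cend[1]),
                     c(exB$cstart[1] , exB$cend[1]))
  for (i in seq_len(cfg$n_background)) {
    w <- bg_windows[[1L + (i %% 2L)]]
    if (w[2] - w[1] < rl) w <- bg_windows[[1]]
    p1 <- sample(w[1]:(w[2] - rl), 1)
    p2 <- sample(w[1]:(w[2] - rl), 1)
    emit_pair(sprintf("%s.bg.%03d", contig$name, i), "BACKGROUND", NULL,
              r1 = list(pos0 = min(p1, p2), cigar = sprintf("%dM", rl),
                        seq = sub(min(p1, p2), min(p1, p2) + rl)),
              r2 = list(pos0 = max(p1, p2), cigar = sprintf("%dM", rl),
                        seq = sub(max(p1, p2), max(p1, p2) + rl)))
  }

  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

#' Simulate a complete fusion screening scenario
#'
#' Builds a genome, plants the requested fusions, constructs the fusion
#' contigs, simulates reads and writes everything a pipeline run needs:
#' `genome.fa`, `genes.gtf`, `fusions.txt`, `reads.sam`, `truth.tsv` and a
#' `manifest.json` with the effective configuration.
#'
#' @param cfg A [sim_config()].
#' @param fusions List of scenario entries
#'   `list(gene_a, gene_b, modes, donor_exons, acceptor_exons)`; `modes` is
#'   a character vector (one planted variant per element, empty for a
#'   background-only candidate), `donor_exons`/`acceptor_exons` optional
#'   parallel integer vectors.
#' @param out_dir Output directory (created).
#' @return List: `dir`, file paths, `cfg`, `sim`, `contigs`, `variants`
#'   (per-contig planted breakpoints) and the combined `truth` table.
#' @export
simulate_scenario <- function(cfg, fusions, out_dir) {
  sim <- simulate_genome_and_genes(cfg)
  for (fu in fusions) {
    modes <- fu$modes
    for (mi in seq_along(modes)) {
      donor <- if (!is.null(fu$donor_exons)) fu$donor_exons[mi] else {
        nrow(tx_exons(sim$genes[[fu$gene_a]])) - mi
      }
      acceptor <- if (!is.null(fu$acceptor_exons)) fu$acceptor_exons[mi] else 2L
      sim <- plant_fusion(sim, fu$gene_a, fu$gene_b, mode = modes[mi],
                          donor_exon = donor, acceptor_exon = acceptor)
    }
  }
  sim <- write_simulation_reference(sim, out_dir)

  genome <- Biostrings::DNAStringSet(unlist(sim$chrom_seqs))
  contigs <- list()
  variants <- list()
  all_records <- list()
  all_truth <- list()
  for (fu in fusions) {
    models <- list(sim_gene_model(sim, fu$gene_a), sim_gene_model(sim, fu$gene_b))
    ct <- build_fusion_contig(models[[1]], models[[2]], genome)
    vts <- list()
    for (tr in sim$truths) {
      if (tr$gene_a == fu$gene_a && tr$gene_b == fu$gene_b) {
        bp <- planted_contig_breakpoint(ct, sim, tr)
        vts[[length(vts) + 1L]] <- list(name = ct$name, mode = tr$mode,
                                        left = bp[1], right = bp[2])
      }
    }
    rd <- simulate_reads(ct, vts, cfg)
    contigs[[ct$name]] <- ct
    variants[[ct$name]] <- vts
    all_records[[ct$name]] <- rd$records
    all_truth[[ct$name]] <- rd$truth
  }
  records <- do.call(rbind, all_records)
  truth <- do.call(rbind, all_truth)
  rownames(truth) <- NULL

  sam <- file.path(out_dir, "reads.sam")
  lens <- vapply(contigs, function(ct) ct$length, integer(1))
  write_sam(records, lens, sam)
  fus_file <- file.path(out_dir, "fusions.txt")
  writeLines(vapply(fusions, function(fu) paste0(fu$gene_a, "::", fu$gene_b),
                    character(1)), fus_file)
  truth_file <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  total_fragments <- if (!is.null(cfg$total_fragments)) cfg$total_fragments else {
    length(unique(records$qname))
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(seed = cfg$seed, read_length = cfg$read_length,
         total_fragments = total_fragments,
         contigs = names(contigs),
         n_fragments = length(unique(records$qname))),
    manifest, auto_unbox = TRUE, pretty = TRUE)

  list(dir = out_dir, fasta = sim$fasta, gtf = sim$gtf, sam = sam,
       fusions = fus_file, truth_file = truth_file, manifest = manifest,
       cfg = cfg, sim = sim, contigs = contigs, variants = variants,
       truth = truth, total_fragments = total_fragments)
}

#' Write simulated reads as a gzipped FASTQ pair
#'
#' Optional output for external-aligner integration; reverse-strand mates
#' are reverse-complemented back to sequencing orientation. Base qualities
#' are constant.
#'
#' @param records SAM record data.frame from [simulate_reads()].
#' @param prefix Output path prefix (`<prefix>_1.fastq.gz`,
#'   `<prefix>_2.fastq.gz`).
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pair <- function(records, prefix) {
  paths <- paste0(prefix, c("_1.fastq.gz", "_2.fastq.gz"))
  for (mate in 1:2) {
    sel <- if (mate == 1) bitwAnd(records$flag, 64L) > 0 else
      bitwAnd(records$flag, 128L) > 0
    r <- records[sel, , drop = FALSE]
    r <- r[order(r$qname), , drop = FALSE]
    seqs <- ifelse(bitwAnd(r$flag, 16L) > 0,
                   vapply(r$seq, revcomp_chr, character(1), USE.NAMES = FALSE),
                   r$seq)
    con <- gzfile(paths[mate], "wb")
    writeLines(paste0("@", r$qname, "/", mate, "\n", seqs, "\n+\n", r$qual),
               con)
    close(con)
  }
  invisible(paths)
}
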