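#' Simulation configuration
#'
#' Defaults describe a small but realistic short-read RNA-seq experiment:
#' multi-exon genes (3-6 exons of 150-300 bp separated by 300-3000 bp
#' introns, so some introns exceed the 1 kb shrinking threshold) on both
#' strands, 100-base paired-end reads with ~300 bp fragments, 10 split and
#' 10 spanning fragments per planted variant, 5 counter reads per partner
#' side, 20 background pairs per contig and error-free base calls.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of simulated genes (one per chromosome).
#' @param exons_per_gene,exon_len,intron_len Ranges `c(min, max)`.
#' @param intergenic Pad (bases) around each gene on its chromosome.
#' @param read_length Read length in bases.
#' @param frag_mean,frag_sd Fragment length distribution (loosely enforced).
#' @param n_split,n_spanning Per-variant fusion-supporting fragment depths.
#' @param n_counter_5p,n_counter_3p Counter-read depth per partner side.
#' @param n_background Background read pairs per contig.
#' @param error_rate Per-base substitution rate (no indel errors).
#' @param split_anchor_range Range of split-read left-anchor lengths.
#' @param total_fragments Library size used as FFPM denominator when writing
#'   scenario manifests (defaults to the number of simulated fragments).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 6L, exons_per_gene = c(3L, 6L),
                       exon_len = c(150L, 300L), intron_len = c(300L, 3000L),
                       intergenic = 500L, read_length = 100L,
                       frag_mean = 300, frag_sd = 30,
                       n_split = 10L, n_spanning = 10L,
                       n_counter_5p = 5L, n_counter_3p = 5L,
                       n_background = 20L, error_rate = 0,
                       split_anchor_range = c(30L, 70L),
                       total_fragments = NULL) {
  stopifnot(read_length >= 2 * 10L, frag_mean >= read_length,
            split_anchor_range[1] >= 10L,
            split_anchor_range[2] <= read_length - 10L,
            exon_len[1] >= 130L)
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  paste(rev(REVCOMP[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# --- transcribed-coordinate helpers (t = 0-based offset along the gene span
# in transcribed orientation; genome coordinates are absolute 0-based) -------

tx_len <- function(gene) gene$span_end - gene$span_start

tx2g <- function(gene, t) {
  if (gene$strand == "+") gene$span_start + t else gene$span_end - 1L - t
}

# transcribed-order exon table with transcribed-span offsets
tx_exons <- function(gene) {
  ex <- gene$exons
  if (gene$strand == "+") {
    d <- data.frame(tstart = ex$start - gene$span_start,
                    tend = ex$end - gene$span_start)
    d[order(d$tstart), , drop = FALSE]
  } else {
    d <- data.frame(tstart = gene$span_end - ex$end,
                    tend = gene$span_end - ex$start)
    d[order(d$tstart), , drop = FALSE]
  }
}

tx_get <- function(sim, gene, t, len) {
  chrom <- sim$chrom_seqs[[gene$chrom]]
  if (gene$strand == "+") {
    g <- tx2g(gene, t)
    substr(chrom, g + 1L, g + len)
  } else {
    g_last <- tx2g(gene, t + len - 1L)
    revcomp_chr(substr(chrom, g_last + 1L, g_last + len))
  }
}

tx_set <- function(sim, gene, t, bases) {
  chrom <- sim$chrom_seqs[[gene$chrom]]
  len <- nchar(bases)
  if (gene$strand == "+") {
    g <- tx2g(gene, t)
    substr(chrom, g + 1L, g + len) <- bases
  } else {
    g_last <- tx2g(gene, t + len - 1L)
    substr(chrom, g_last + 1L, g_last + len) <- revcomp_chr(bases)
  }
  sim$chrom_seqs[[gene$chrom]] <- chrom
  sim
}

#' Simulate a genome with multi-exon genes on both strands
#'
#' Generates one gene per chromosome with GT-AG introns by construction on
#' the transcribed strand, and (optionally) writes the genome FASTA and a
#' single-transcript-per-gene GTF.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory for `genome.fa` / `genes.gtf`.
#' @return A `fusion_sim` object: `cfg`, `genes` (named list with genome
#'   0-based exon tables, strand, span), `chrom_seqs` (named character), and
#'   file paths when written.
#' @export
simulate_genome_and_genes <- function(cfg, out_dir = NULL) {
  set.seed(cfg$seed)
  if (cfg$intron_len[1] < 4L) stop("introns must be at least 4 bases")
  genes <- list()
  chrom_seqs <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- paste0("G", i)
    chrom <- paste0("chr", i)
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1)
    ex_len <- sample(cfg$exon_len[1]:cfg$exon_len[2], n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) {
      sample(cfg$intron_len[1]:cfg$intron_len[2], n_ex - 1, replace = TRUE)
    } else integer(0)
    span_len <- sum(ex_len) + sum(in_len)
    span_start <- cfg$intergenic
    seq <- rand_dna(span_len + 2L * cfg$intergenic)
    # exon coordinates (genome ascending, 0-based half-open)
    starts <- span_start + cumsum(c(0L, (ex_len + c(in_len, 0L))[-n_ex]))
    ends <- starts + ex_len
    gene <- list(gene_id = gid, chrom = chrom, strand = strand,
                 exons = data.frame(start = starts, end = ends),
                 span_start = span_start, span_end = span_start + span_len)
    chrom_seqs[[chrom]] <- seq
    genes[[gid]] <- gene
  }
  sim <- structure(list(cfg = cfg, genes = genes, chrom_seqs = chrom_seqs,
                        truths = list()),
                   class = "fusion_sim")
  # force GT..AG intron ends on the transcribed strand
  for (gid in names(genes)) {
    gene <- sim$genes[[gid]]
    tex <- tx_exons(gene)
    if (nrow(tex) > 1) {
      for (k in seq_len(nrow(tex) - 1)) {
        sim <- tx_set(sim, gene, tex$tend[k], "GT")
        sim <- tx_set(sim, gene, tex$tstart[k + 1] - 2L, "AG")
      }
    }
  }
  if (!is.null(out_dir)) sim <- write_simulation_reference(sim, out_dir)
  sim
}

write_simulation_reference <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(out_dir, "genome.fa")
  gtf <- file.path(out_dir, "genes.gtf")
  seqs <- Biostrings::DNAStringSet(unlist(sim$chrom_seqs))
  Biostrings::writeXStringSet(seqs, fasta)
  lines <- unlist(lapply(sim$genes, function(g) {
    sprintf("%s\tfuseval_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            g$chrom, g$exons$start + 1L, g$exons$end, g$strand,
            g$gene_id, g$gene_id)
  }))
  writeLines(lines, gtf)
  sim$fasta <- fasta
  sim$gtf <- gtf
  sim
}

# GeneModel view of a simulated gene (single transcript = merged exons)
sim_gene_model <- function(sim, gid) {
  g <- sim$genes[[gid]]
  new_gene_model(gene_id = gid, chrom = g$chrom, strand = g$strand,
                 exons = g$exons,
                 transcripts = setNames(list(g$exons), paste0(gid, ".t1")))
}

#' Plant a fusion breakpoint between two simulated genes
#'
#' Supported modes mirror the contrast between clean splice-defined fusions
#' and microhomology-driven chimeric artifacts: `REF_SPLICE` places the
#' junction at annotated exon boundaries (consensus GT-AG by construction),
#' `NON_REF_CONSENSUS` mid-exon with edited GT-AG flanks,
#' `NON_CANONICAL` mid-exon without consensus dinucleotides, and
#' `MICROHOMOLOGY_ARTIFACT` first plants a shared 10-mer in both genes and
#' sets the junction exactly at it.
#'
#' @param sim A `fusion_sim`.
#' @param gene_a,gene_b Gene ids (5' and 3' partner; must differ).
#' @param mode One of the four modes above.
#' @param donor_exon,acceptor_exon 1-based exon index in transcribed order
#'   (donor defaults to the next-to-last exon of geneA, acceptor to exon 2
#'   of geneB; the donor may not be geneA's last exon).
#' @param k Shared k-mer length for `MICROHOMOLOGY_ARTIFACT`.
#' @return The updated `fusion_sim`; the planted truth (gene pair, mode,
#'   transcribed-offset breakpoints) is appended to `sim$truths`.
#' @export
plant_fusion <- function(sim, gene_a, gene_b,
                         mode = c("REF_SPLICE", "NON_REF_CONSENSUS",
                                  "NON_CANONICAL", "MICROHOMOLOGY_ARTIFACT"),
                         donor_exon = NULL, acceptor_exon = 2L, k = 10L) {
  mode <- match.arg(mode)
  if (gene_a == gene_b) stop("self-fusion unsupported")
  ga <- sim$genes[[gene_a]]
  gb <- sim$genes[[gene_b]]
  if (is.null(ga) || is.null(gb)) stop("unknown gene in fusion")
  texa <- tx_exons(ga)
  texb <- tx_exons(gb)
  if (nrow(texa) < 2) stop("mode incompatible with gene structure: geneA needs >= 2 exons")
  if (is.null(donor_exon)) donor_exon <- nrow(texa) - 1L
  if (donor_exon >= nrow(texa) || donor_exon < 1) {
    stop("donor exon must be an internal/first exon of geneA")
  }
  if (acceptor_exon > nrow(texb) || acceptor_exon < 1) {
    stop("mode incompatible with gene structure: acceptor exon out of range")
  }
  rl <- sim$cfg$read_length
  mid_offset_a <- texa$tend[donor_exon] - texa$tstart[donor_exon] - 30L
  mid_offset_b <- 30L
  if (mode == "REF_SPLICE") {
    t_a <- texa$tend[donor_exon] - 1L   # last transcribed base of donor exon
    t_b <- texb$tstart[acceptor_exon]   # first transcribed base of acceptor
  } else {
    t_a <- texa$tstart[donor_exon] + mid_offset_a - 1L
    t_b <- texb$tstart[acceptor_exon] + mid_offset_b
    if (mode == "NON_REF_CONSENSUS") {
      sim <- tx_set(sim, ga, t_a + 1L, "GT")
      sim <- tx_set(sim, gb, t_b - 2L, "AG")
    } else if (mode == "NON_CANONICAL") {
      sim <- tx_set(sim, ga, t_a + 1L, "CC")
      sim <- tx_set(sim, gb, t_b - 2L, "TT")
    } else {  # MICROHOMOLOGY_ARTIFACT: junction inside a planted shared k-mer
      kmer <- tx_get(sim, ga, t_a, k)
      sim <- tx_set(sim, gb, t_b, kmer)
      din <- breakpoint_like_dinucs(sim, ga, gb, t_a, t_b)
      if (din == "GTAG") sim <- tx_set(sim, gb, t_b - 2L, "TT")
    }
  }
  truth <- list(gene_a = gene_a, gene_b = gene_b, mode = mode,
                t_a = t_a, t_b = t_b,
                name = paste0(gene_a, "--", gene_b))
  sim$truths[[length(sim$truths) + 1L]] <- truth
  sim
}

breakpoint_like_dinucs <- function(sim, ga, gb, t_a, t_b) {
  paste0(tx_get(sim, ga, t_a + 1L, 2L), tx_get(sim, gb, t_b - 2L, 2L))
}

#' Simulate fusion feature vectors from annotated archetypes
#'
#' Draws raw 9-attribute feature vectors from three generating archetypes
#' mirroring the annotated fusion classes: "COSMIC-like" (high expression,
#' 3' allelic ratio exceeding the 5', consensus reference splicing, few and
#' distal microhomologies), "artifact-like" (non-consensus novel
#' breakpoints coinciding with abundant microhomology, moderate partner
#' expression) and "high-counter" (lowly expressed fusion against highly
#' expressed unfused partners, allelic ratios near 1). Used to exercise the
#' clustering / classification stack without cohort data.
#'
#' @param n Total variants (split evenly across the three archetypes).
#' @param seed Integer RNG seed.
#' @return List with `features` (n x 9 matrix, `FEATURE_NAMES` columns) and
#'   `archetype` (factor of generating class labels).
#' @export
simulate_feature_archetypes <- function(n = 3000L, seed = 1L) {
  set.seed(seed)
  n_each <- c(rep(n %/% 3L, 2L), n - 2L * (n %/% 3L))
  gen <- list(
    cosmic_like = function(m) cbind(
      ffpm = rlnorm(m, log(5), 0.5),
      far_5p = rlnorm(m, log(8), 0.4),
      far_3p = rlnorm(m, log(40), 0.4),
      counter_ffpm_5p = rlnorm(m, log(0.3), 0.5),
      counter_ffpm_3p = rlnorm(m, log(0.1), 0.5),
      consensus_indicator = rep(1, m),
      ref_agree_indicator = rep(1, m),
      n_microhomologies = rpois(m, 2),
      microhomology_distance = runif(m, 2000, 6000)),
    artifact_like = function(m) cbind(
      ffpm = rlnorm(m, log(0.4), 0.5),
      far_5p = rlnorm(m, log(1.5), 0.4),
      far_3p = rlnorm(m, log(1.5), 0.4),
      counter_ffpm_5p = rlnorm(m, log(3), 0.6),
      counter_ffpm_3p = rlnorm(m, log(3), 0.6),
      consensus_indicator = rep(0, m),
      ref_agree_indicator = rep(0, m),
      n_microhomologies = rpois(m, 40),
      microhomology_distance = abs(rnorm(m, 0, 15))),
    high_counter = function(m) cbind(
      ffpm = rlnorm(m, log(0.3), 0.4),
      far_5p = rlnorm(m, log(1.05), 0.15),
      far_3p = rlnorm(m, log(1.05), 0.15),
      counter_ffpm_5p = rlnorm(m, log(25), 0.5),
      counter_ffpm_3p = rlnorm(m, log(25), 0.5),
      consensus_indicator = rep(1, m),
      ref_agree_indicator = rep(1, m),
      n_microhomologies = rpois(m, 2),
      microhomology_distance = runif(m, 2000, 6000))
  )
  features <- do.call(rbind, Map(function(f, m) f(m), gen, n_each))
  archetype <- factor(rep(names(gen), n_each), levels = names(gen))
  ord <- sample(nrow(features))
  list(features = features[ord, , drop = FALSE], archetype = archetype[ord])
}

#' Contig coordinates of a planted breakpoint
#'
#' @param contig `FusionContig` built from the (post-planting) simulated
#'   genome.
#' @param sim The `fusion_sim`.
#' @param truth One element of `sim$truths`.
#' @return `c(left_break, right_break)` in 0-based contig coordinates.
#' @export
planted_contig_breakpoint <- function(contig, sim, truth) {
  ga <- sim$genes[[truth$gene_a]]
  gb <- sim$genes[[truth$gene_b]]
  left <- map_genome_to_contig(contig$maps[[truth$gene_a]], tx2g(ga, truth$t_a))
  right <- map_genome_to_contig(contig$maps[[truth$gene_b]], tx2g(gb, truth$t_b))
  c(left, right)
}
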