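test_that("load_gene_models parses GTF with strand-independent exon storage", {
  toy <- write_toy_reference()
  models <- load_gene_models(toy$gtf, toy$fasta, c("GA", "GB"))
  ga <- models$GA
  expect_s3_class(ga, "GeneModel")
  expect_equal(ga$strand, "+")
  # 1-based inclusive -> 0-based half-open
  expect_equal(ga$exons, data.frame(start = c(100L, 300L), end = c(200L, 400L)))
  gb <- models$GB
  expect_equal(gb$strand, "-")
  # minus-strand exons still ascend in genome coordinates
  expect_true(all(diff(gb$exons$start) > 0))
})

test_that("load_gene_models errors name the offending gene", {
  toy <- write_toy_reference()
  expect_error(load_gene_models(toy$gtf, gene_ids = c("GA", "MISSING")),
               "unknown gene.*MISSING")
  expect_error(load_gene_models(toy$gtf, gene_ids = "GSPLIT"),
               "ambiguous locus.*GSPLIT")
})

test_that("shrink_introns keeps flanking halves of long introns only", {
  # 2 exons of 100 around a 5000-base intron, then a short 800-base intron
  gene <- fuseval:::new_gene_model(
    "GX", "chr1", "+",
    exons = data.frame(start = c(0L, 5100L, 6000L),
                       end = c(100L, 5200L, 6100L)),
    transcripts = list(GX.t1 = data.frame(start = c(0L, 5100L, 6000L),
                                          end = c(100L, 5200L, 6100L))))
  set.seed(1)
  seq <- rand_seq(6100)
  sh <- shrink_introns(gene, seq, max_intron = 1000L)
  # 5000-base intron -> 500 + 500 retained; 800-base intron unchanged
  expect_equal(nchar(sh$seq), 100 + 1000 + 100 + 800 + 100)
  expect_equal(sh$map$length, nchar(sh$seq))
  # exon sequence unchanged
  expect_equal(substr(sh$seq, 1, 100), substr(seq, 1, 100))
  expect_equal(substr(sh$seq, 1101, 1200), substr(seq, 5101, 5200))
  # removed central region maps to no contig position
  expect_true(is.na(map_genome_to_contig(sh$map, 2500L)))
})

test_that("coordinate maps round-trip on all retained bases (property)", {
  set.seed(42)
  for (rep in 1:6) {
    n_ex <- sample(2:5, 1)
    starts <- cumsum(sample(200:4000, n_ex)) + sample(0:50, 1)
    ends <- starts + sample(80:300, n_ex, replace = TRUE)
    # keep exons disjoint and ordered
    for (i in seq_len(n_ex - 1)) {
      if (ends[i] >= starts[i + 1]) starts[i + 1] <- ends[i] + 100L
      ends[i + 1] <- starts[i + 1] + sample(80:300, 1)
    }
    ex <- data.frame(start = as.integer(starts), end = as.integer(ends))
    gene <- fuseval:::new_gene_model("GR", "chr1", sample(c("+", "-"), 1),
                                     exons = ex, transcripts = list(t1 = ex))
    span <- ex$end[n_ex] - ex$start[1]
    seq <- rand_seq(span)
    sh <- shrink_introns(gene, seq, max_intron = 1000L)
    if (gene$strand == "-") sh$map$strand <- "-"
    retained_g <- unlist(Map(seq.int, sh$map$segments$gstart,
                             sh$map$segments$gend - 1L))
    gpos <- sample(retained_g, min(170, length(retained_g)))
    cpos <- map_genome_to_contig(sh$map, gpos)
    expect_false(anyNA(cpos))
    expect_equal(map_contig_to_genome(sh$map, cpos), as.integer(gpos))
    # conservation: retained length = exons + capped introns
    introns <- ex$start[-1] - ex$end[-n_ex]
    expect_equal(sh$map$length,
                 sum(ex$end - ex$start) + sum(pmin(introns, 1000L)))
  }
})

test_that("build_fusion_contig orients both genes 5'->3' left to right", {
  toy <- write_toy_reference()
  models <- load_gene_models(toy$gtf, gene_ids = c("GA", "GB"))
  genome <- read_genome(toy$fasta)
  ct <- build_fusion_contig(models$GA, models$GB, genome)
  expect_equal(ct$name, "GA--GB")
  expect_equal(ct$geneB_offset, 300L)   # 100 + 100 exon + 100 intron
  expect_equal(ct$length, ct$geneB_offset + 300L)
  # geneB is minus strand: its first transcribed exon (genome 701-800) must
  # map to the smallest contig coordinates of the geneB segment
  first_tx_exon <- ct$annotations[ct$annotations$gene == "GB" &
                                    ct$annotations$gstart == 700L, ]
  expect_equal(first_tx_exon$cstart, ct$geneB_offset)
  # contig sequence of that exon equals the reverse complement of the genome
  contig_exon <- substr(ct$seq, first_tx_exon$cstart + 1, first_tx_exon$cend)
  genome_exon <- substr(toy$chr1, 701, 800)
  expect_equal(contig_exon,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(genome_exon))))
  # remapped exon -> genome round trip
  for (i in seq_len(nrow(ct$annotations))) {
    a <- ct$annotations[i, ]
    mp <- ct$maps[[a$gene]]
    g <- sort(map_contig_to_genome(mp, c(a$cstart, a$cend - 1L)))
    expect_equal(g, c(a$gstart, a$gend - 1L))
  }
  expect_error(build_fusion_contig(models$GA, models$GA, genome),
               "self-fusion unsupported")
})

test_that("write_contigs round-trips through FASTA/GTF", {
  toy <- write_toy_reference()
  models <- load_gene_models(toy$gtf, gene_ids = c("GA", "GB"))
  genome <- read_genome(toy$fasta)
  ct <- build_fusion_contig(models$GA, models$GB, genome)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "contigs.fa")
  gtf <- file.path(dir, "contigs.gtf")
  write_contigs(list(ct), fa, gtf)
  seqs <- read_genome(fa)
  expect_equal(names(seqs), "GA--GB")
  expect_equal(unname(Biostrings::width(seqs)), ct$length)
  back <- load_gene_models(gtf, gene_ids = c("GA", "GB"))
  expect_equal(back$GA$exons,
               unname_df(ct$exons$GA, c("start", "end")))
  expect_equal(back$GB$exons,
               unname_df(ct$exons$GB, c("start", "end")))
  expect_error(write_contigs(list(), fa, gtf), "no contigs")
  expect_error(write_contigs(list(ct, ct), fa, gtf), "duplicate contig names")
})
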