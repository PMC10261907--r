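test_that("genome simulation is deterministic and structurally sound", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 4, n_genes = 4)
  s1 <- simulate_genome_and_genes(cfg, d1)
  s2 <- simulate_genome_and_genes(cfg, d2)
  expect_identical(readLines(s1$fasta), readLines(s2$fasta))
  expect_identical(readLines(s1$gtf), readLines(s2$gtf))
  for (g in s1$genes) {
    n_ex <- nrow(g$exons)
    expect_gte(n_ex, cfg$exons_per_gene[1])
    expect_lte(n_ex, cfg$exons_per_gene[2])
    # every intron starts GT and ends AG on the transcribed strand
    tex <- fuseval:::tx_exons(g)
    for (k in seq_len(n_ex - 1)) {
      expect_equal(fuseval:::tx_get(s1, g, tex$tend[k], 2L), "GT")
      expect_equal(fuseval:::tx_get(s1, g, tex$tstart[k + 1] - 2L, 2L), "AG")
    }
  }
})

test_that("plant_fusion modes produce the promised breakpoint context", {
  cfg <- sim_config(seed = 21)
  modes <- c("REF_SPLICE", "NON_REF_CONSENSUS", "NON_CANONICAL",
             "MICROHOMOLOGY_ARTIFACT")
  sc <- simulate_scenario(cfg, list(
    list(gene_a = "G1", gene_b = "G2", modes = modes[1]),
    list(gene_a = "G3", gene_b = "G4", modes = modes[2]),
    list(gene_a = "G5", gene_b = "G6", modes = modes[3]),
    list(gene_a = "G1", gene_b = "G4", modes = modes[4])),
    withr::local_tempdir())
  get_ct <- function(i) sc$contigs[[i]]
  for (i in seq_along(modes)) {
    ct <- get_ct(i)
    v <- sc$variants[[ct$name]][[1]]
    ra <- reference_agreement(c(v$left, v$right), ct)
    if (modes[i] == "REF_SPLICE") {
      expect_equal(ra$splice_type, "ONLY_REF_SPLICE")
    } else if (modes[i] == "NON_REF_CONSENSUS") {
      expect_equal(ra$splice_type, "INCL_NON_REF_SPLICE")
    } else {
      expect_equal(ra$splice_type, "NON_CANONICAL")
    }
    if (modes[i] == "MICROHOMOLOGY_ARTIFACT") {
      mh <- find_microhomologies(ct)
      expect_equal(microhomology_distance(c(v$left, v$right), mh, ct), 0)
    }
  }
  expect_error(plant_fusion(sc$sim, "G1", "G1"), "self-fusion")
})

test_that("simulate_reads emits exact depths, valid CIGARs and clean reads", {
  cfg <- sim_config(seed = 13, n_genes = 2)
  sc <- simulate_scenario(cfg, list(list(gene_a = "G1", gene_b = "G2",
                                         modes = "REF_SPLICE")),
                          withr::local_tempdir())
  truth <- sc$truth
  expect_equal(sum(truth$class == "SPLIT"), cfg$n_split)
  expect_equal(sum(truth$class == "SPANNING"), cfg$n_spanning)
  expect_equal(sum(truth$class %in% c("SPLIT", "SPANNING")),
               cfg$n_split + cfg$n_spanning)
  expect_equal(anyDuplicated(truth$fragment_id), 0L)
  aln <- read_alignments(sc$sam)$alignments
  # zero error rate: every read passes the identity rule with margin
  expect_true(all(aln$nm == 0))
  expect_true(all(vapply(seq_len(nrow(aln)), function(i) {
    percent_identity(aln$cigar[i], aln$nm[i]) >= 0.98
  }, logical(1))))
  # read sequences match the contig at their aligned positions
  ct <- sc$contigs[[1]]
  ok <- vapply(seq_len(nrow(aln)), function(i) {
    blocks <- fuseval:::cigar_blocks(aln$cigar[i], aln$pos0[i])
    ref <- paste(substring(ct$seq, blocks$ref_start + 1, blocks$ref_end),
                 collapse = "")
    read_aln <- paste(substring(aln$seq[i], blocks$read_start + 1,
                                blocks$read_end), collapse = "")
    identical(ref, read_aln)
  }, logical(1))
  expect_true(all(ok))
})

test_that("scenario output is byte-stable for a fixed seed", {
  cfg <- sim_config(seed = 99, n_genes = 2)
  spec <- list(list(gene_a = "G1", gene_b = "G2", modes = "REF_SPLICE"))
  s1 <- simulate_scenario(cfg, spec, withr::local_tempdir())
  s2 <- simulate_scenario(cfg, spec, withr::local_tempdir())
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_identical(readLines(s1$truth_file), readLines(s2$truth_file))
})

test_that("FASTQ export round-trips read sequences", {
  cfg <- sim_config(seed = 55, n_genes = 2, n_background = 4L,
                    n_split = 2L, n_spanning = 2L,
                    n_counter_5p = 0L, n_counter_3p = 0L)
  sc <- simulate_scenario(cfg, list(list(gene_a = "G1", gene_b = "G2",
                                         modes = "REF_SPLICE")),
                          withr::local_tempdir())
  aln <- read_alignments(sc$sam)$alignments
  prefix <- file.path(withr::local_tempdir(), "reads")
  paths <- write_fastq_pair(
    cbind(aln[, c("qname", "flag", "seq")],
          qual = strrep("I", cfg$read_length)), prefix)
  fq1 <- readLines(paths[1])
  expect_equal(length(fq1) / 4, length(unique(aln$qname)))
  # a reverse-flagged mate is reverse-complemented in FASTQ space
  rev_row <- aln[bitwAnd(aln$flag, 16L) > 0, ][1, ]
  fq2 <- readLines(paths[2])
  idx <- which(fq2 == paste0("@", rev_row$qname, "/2"))
  expect_equal(fq2[idx + 1], fuseval:::revcomp_chr(rev_row$seq))
})
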