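test_that("sequence_entropy matches the Shannon formula", {
  expect_equal(sequence_entropy("AAAAAAAAAA"), 0)
  expect_equal(sequence_entropy("ACGTACGTACGT"), 2)
  # 6 A, 4 C: -(0.6 log2 0.6 + 0.4 log2 0.4) = 0.97095
  expect_equal(sequence_entropy("AAACCAAACC"), 0.9709506, tolerance = 1e-6)
  # N excluded from counts
  expect_equal(sequence_entropy("AANNAA"), 0)
  expect_error(sequence_entropy(""), "empty sequence")
  expect_error(sequence_entropy("NNN"), "no A/C/G/T")
})

test_that("percent_identity and end_clipping implement the stated QC rules", {
  expect_equal(percent_identity("100M", 2L), 0.98)
  expect_equal(percent_identity("100M", 3L), 0.97)
  expect_equal(percent_identity("50M", 0L), 1.0)
  expect_error(percent_identity("10S", 0L), "no aligned bases")
  expect_equal(end_clipping("10S90M"), c(left = 10L, right = 0L))
  expect_equal(end_clipping("11S89M"), c(left = 11L, right = 0L))
  expect_equal(end_clipping("90M10H"), c(left = 0L, right = 10L))
  expect_equal(end_clipping("5H5S90M3S"), c(left = 10L, right = 3L))
})

# A contig fixture with a junction at 60/140: geneA = 60 exonic bases plus a
# retained intron tail, geneB starts at offset 140.
evidence_contig <- function() {
  set.seed(99)
  fake_contig(rand_seq(140), rand_seq(160),
              exons_a = data.frame(cstart = 0L, cend = 60L),
              exons_b = data.frame(cstart = 180L, cend = 280L))
}

test_that("classify_fragment identifies split reads with anchors and QC", {
  ct <- evidence_contig()
  lb <- 59L; rb <- 180L                       # exon end / exon start junction
  gap <- rb - lb - 1L
  seq <- paste0(substr(ct$seq, lb - 39L, lb + 1L), substr(ct$seq, rb + 1L, rb + 60L))
  split <- make_read("f1", ct$name, lb - 40L + 1L, sprintf("40M%dN60M", gap), seq)
  mate <- make_read("f1", ct$name, 0L, "40M", substr(ct$seq, 1, 40), flag = 147L)
  ev <- classify_fragment(rbind(mate, split), ct)
  expect_equal(ev$class, "SPLIT")
  expect_equal(ev$breakpoint, c(lb, rb))
  expect_equal(ev$anchor_left, 40L)
  expect_equal(ev$anchor_right, 60L)

  # identity below 98% discards the fragment
  bad <- split; bad$nm <- 3L
  expect_equal(classify_fragment(rbind(mate, bad), ct)$class, "DISCARD")
  # clipped beyond 10 bases discards
  clipped <- make_read("f2", ct$name, lb - 29L + 1L,
                       sprintf("11S29M%dN60M", gap),
                       paste0(strrep("A", 11), substr(seq, 12, 100)))
  expect_equal(classify_fragment(list(clipped), ct)$class, "DISCARD")
  # anchor below 10 aligned bases discards
  tiny <- make_read("f3", ct$name, lb - 8L + 1L, sprintf("8M%dN60M", gap),
                    paste0(substr(ct$seq, lb - 7L, lb + 1L),
                           substr(ct$seq, rb + 1L, rb + 60L)))
  expect_equal(classify_fragment(list(tiny), ct)$class, "DISCARD")
  # low-complexity anchor discards: poly-A left anchor
  ct2 <- ct
  ct2$seq <- paste0(strrep("A", 60), substr(ct$seq, 61, ct$length))
  lowc <- make_read("f4", ct2$name, lb - 39L + 1L, sprintf("40M%dN60M", gap),
                    paste0(strrep("A", 40), substr(ct2$seq, rb + 1L, rb + 60L)))
  expect_equal(classify_fragment(list(lowc), ct2)$class, "DISCARD")
})

test_that("classify_fragment identifies spanning, counter and background", {
  ct <- evidence_contig()
  r1 <- make_read("s1", ct$name, 0L, "50M", substr(ct$seq, 1, 50), flag = 99L)
  r2 <- make_read("s1", ct$name, 200L, "50M", substr(ct$seq, 201, 250),
                  flag = 147L)
  expect_equal(classify_fragment(rbind(r1, r2), ct)$class, "SPANNING")
  # same-strand mates are not concordant spanning evidence
  r2_fwd <- r2; r2_fwd$flag <- 163L; r2_fwd$is_reverse <- FALSE
  expect_equal(classify_fragment(rbind(r1, r2_fwd), ct)$class, "BACKGROUND")

  bp <- c(40L, 200L)
  c5 <- make_read("c1", ct$name, 21L, "40M", substr(ct$seq, 22, 61))
  ev <- classify_fragment(list(c5), ct, breakpoints = list(bp))
  expect_equal(ev$class, "COUNTER_5P")
  c3 <- make_read("c2", ct$name, 185L, "40M", substr(ct$seq, 186, 225))
  expect_equal(classify_fragment(list(c3), ct, breakpoints = list(bp))$class,
               "COUNTER_3P")
  # 9-base overlap on one side is not enough
  c5short <- make_read("c3", ct$name, 32L, "40M", substr(ct$seq, 33, 72))
  expect_equal(
    classify_fragment(list(c5short), ct, breakpoints = list(bp))$class,
    "BACKGROUND")
  # without candidate breakpoints the same read is background
  expect_equal(classify_fragment(list(c5), ct)$class, "BACKGROUND")

  other <- make_read("x1", "OTHER--CTG", 0L, "50M", substr(ct$seq, 1, 50))
  expect_error(classify_fragment(rbind(r1, other), ct), "cross-contig pair")
})

test_that("classification is a partition and tightening QC is monotone", {
  cfg <- sim_config(seed = 11, n_genes = 2, error_rate = 0.002)
  sc <- simulate_scenario(cfg, list(list(gene_a = "G1", gene_b = "G2",
                                         modes = "REF_SPLICE")),
                          withr::local_tempdir())
  aln <- read_alignments(sc$sam)$alignments
  ct <- sc$contigs[[1]]
  frags <- classify_alignments(aln, ct)
  expect_setequal(names(frags), unique(aln$qname))
  classes <- vapply(frags, function(e) e$class, character(1))
  expect_true(all(classes %in% fuseval:::FRAGMENT_CLASSES))
  support <- sum(classes %in% c("SPLIT", "SPANNING"))
  # tightened thresholds can only lose support
  tight <- qc_thresholds(min_anchor = 20L, min_identity = 0.999,
                         max_end_clip = 0L, min_entropy = 1.5)
  frags_tight <- classify_alignments(aln, ct, tight)
  classes_tight <- vapply(frags_tight, function(e) e$class, character(1))
  expect_lte(sum(classes_tight %in% c("SPLIT", "SPANNING")), support)
})

test_that("collect_breakpoints groups splits and assigns compatible spanning", {
  cfg <- sim_config(seed = 5, n_genes = 2, exons_per_gene = c(4L, 6L))
  sc <- simulate_scenario(cfg, list(list(gene_a = "G1", gene_b = "G2",
                                         modes = c("REF_SPLICE", "REF_SPLICE"))),
                          withr::local_tempdir())
  ct <- sc$contigs[[1]]
  aln <- read_alignments(sc$sam)$alignments
  frags <- classify_alignments(aln, ct)
  bps <- collect_breakpoints(frags, aln, ct)
  planted <- lapply(sc$variants[[1]], function(v) c(v$left, v$right))
  expect_equal(length(bps), 2L)
  expect_setequal(lapply(bps, function(b) c(b$left_break, b$right_break)),
                  planted)
  # split sets are disjoint and exact
  ids <- lapply(bps, function(b) b$split_read_ids)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_true(all(lengths(ids) == cfg$n_split))
  # the outer variant's spanning reads bracket the inner breakpoint too
  inner <- which.max(vapply(bps, function(b) b$left_break, numeric(1)))
  expect_gte(length(bps[[inner]]$spanning_compatible_ids), cfg$n_spanning)
  # counter reads are tallied per side
  expect_true(all(vapply(bps, function(b) b$counter_5p_count, numeric(1)) ==
                    cfg$n_counter_5p))

  # spanning-only evidence never creates a candidate
  no_split <- Filter(function(e) e$class != "SPLIT", frags)
  expect_length(collect_breakpoints(no_split, aln, ct), 0)
})
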