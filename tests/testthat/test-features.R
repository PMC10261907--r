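test_that("find_microhomologies enumerates exact k-mer start pairs", {
  set.seed(7)
  # disjoint alphabets guarantee the segments share no 10-mer by themselves
  seq_a <- paste(sample(c("A", "C"), 1200, replace = TRUE), collapse = "")
  seq_b <- paste(sample(c("G", "T"), 1200, replace = TRUE), collapse = "")
  ct <- fake_contig(seq_a, seq_b)
  expect_equal(nrow(find_microhomologies(ct)$matches), 0)

  km <- "TATGCGCATG"   # mixed alphabet: can only match where planted
  seq_a2 <- seq_a; substr(seq_a2, 901, 910) <- km
  seq_b2 <- seq_b; substr(seq_b2, 701, 710) <- km
  ct2 <- fake_contig(seq_a2, seq_b2)
  mh <- find_microhomologies(ct2)
  expect_equal(mh$matches, data.frame(posA = 900L, posB = 1200L + 700L))

  # a shared 12-mer yields 3 overlapping 10-mer pairs
  km12 <- "TATGCGCATGAC"
  seq_a3 <- seq_a; substr(seq_a3, 901, 912) <- km12
  seq_b3 <- seq_b; substr(seq_b3, 701, 712) <- km12
  mh3 <- find_microhomologies(fake_contig(seq_a3, seq_b3))
  expect_equal(mh3$matches,
               data.frame(posA = 900:902, posB = 1900:1902))
  expect_error(find_microhomologies(ct, k = 3L), "at least 4")
})

test_that("microhomology maps match the pattern-matching oracle (property)", {
  set.seed(123)
  for (rep in 1:15) {
    la <- sample(200:800, 1); lb <- sample(200:800, 1)
    seq_a <- rand_seq(la); seq_b <- rand_seq(lb)
    if (rep %% 2 == 0) {  # plant shared k-mers in half the cases
      km <- rand_seq(sample(10:14, 1))
      pa <- sample(seq_len(la - nchar(km)), 1)
      pb <- sample(seq_len(lb - nchar(km)), 1)
      substr(seq_a, pa, pa + nchar(km) - 1) <- km
      substr(seq_b, pb, pb + nchar(km) - 1) <- km
    }
    ct <- fake_contig(seq_a, seq_b)
    got <- find_microhomologies(ct, k = 10L)$matches
    expect_equal(got, oracle_microhomologies(seq_a, seq_b, 10L))
    # symmetry: swapping the gene segments transposes the match set
    swapped <- find_microhomologies(fake_contig(seq_b, seq_a), k = 10L)$matches
    expect_equal(nrow(swapped), nrow(got))
    if (nrow(got) > 0) {
      expect_setequal(paste(got$posA, got$posB - nchar(seq_a)),
                      paste(swapped$posB - nchar(seq_b), swapped$posA))
    }
  }
})

test_that("breakpoint_dinucleotides reads donor/acceptor off the contig", {
  seq_a <- paste0(rand_seq(58), "AG", "GT", rand_seq(38))  # break at pos 59
  seq_b <- paste0(rand_seq(58), "AG", rand_seq(42))
  ct <- fake_contig(seq_a, seq_b)
  din <- breakpoint_dinucleotides(ct, c(59L, 160L))
  expect_equal(din$donor, "GT")
  expect_equal(din$acceptor, "AG")
  expect_true(din$consensus)
  ct2 <- ct
  substr(ct2$seq, 61, 62) <- "CT"
  substr(ct2$seq, 159, 160) <- "AC"
  din2 <- breakpoint_dinucleotides(ct2, c(59L, 160L))
  expect_equal(din2$donor, "CT")
  expect_equal(din2$acceptor, "AC")
  expect_false(din2$consensus)
  # extended consensus set is configurable
  substr(ct2$seq, 61, 62) <- "GC"
  substr(ct2$seq, 159, 160) <- "AG"
  expect_true(breakpoint_dinucleotides(ct2, c(59L, 160L),
                                       consensus_set = c("GTAG", "GCAG"))$consensus)
  expect_error(breakpoint_dinucleotides(ct, c(1L, ct$length - 1L)),
               "edge breakpoint")
})

test_that("reference_agreement distinguishes the three splice types", {
  set.seed(31)
  seq_a <- rand_seq(200); seq_b <- rand_seq(200)
  ct <- fake_contig(seq_a, seq_b,
                    exons_a = data.frame(cstart = 0L, cend = 100L),
                    exons_b = data.frame(cstart = 250L, cend = 350L))
  substr(ct$seq, 101, 102) <- "GT"   # donor after exon end (break 99)
  substr(ct$seq, 249, 250) <- "AG"   # acceptor before exon start (break 250)
  ra <- reference_agreement(c(99L, 250L), ct)
  expect_true(ra$left_ref_agree && ra$right_ref_agree)
  expect_equal(ra$splice_type, "ONLY_REF_SPLICE")
  # consensus junction 7 bases inside the exon: novel but spliced
  substr(ct$seq, 94, 95) <- "GT"
  ra2 <- reference_agreement(c(92L, 250L), ct)
  expect_false(ra2$left_ref_agree)
  expect_equal(ra2$splice_type, "INCL_NON_REF_SPLICE")
  # non-consensus flanks dominate regardless of boundary agreement
  substr(ct$seq, 101, 102) <- "CA"
  ra3 <- reference_agreement(c(99L, 250L), ct)
  expect_equal(ra3$splice_type, "NON_CANONICAL")
})

test_that("microhomology_distance minimizes over matches with a sentinel", {
  ct <- fake_contig(rand_seq(3000), rand_seq(4000))
  mh <- structure(list(k = 10L, matches = data.frame(posA = 900L, posB = 4900L)),
                  class = "MicrohomologyMap")
  expect_equal(microhomology_distance(c(1000L, 5000L), mh, ct),
               sqrt(100^2 + 100^2))
  expect_equal(microhomology_distance(c(900L, 4900L), mh, ct), 0)
  empty <- structure(list(k = 10L,
                          matches = data.frame(posA = integer(0),
                                               posB = integer(0))),
                     class = "MicrohomologyMap")
  expect_equal(microhomology_distance(c(1000L, 5000L), empty, ct), 5000)
  # adding a match can only decrease the distance (property)
  set.seed(4)
  for (rep in 1:25) {
    bp <- c(sample(0:2999, 1), sample(3000:6999, 1))
    m1 <- data.frame(posA = sample(0:2999, 5), posB = sample(3000:6999, 5))
    m2 <- rbind(m1, data.frame(posA = sample(0:2999, 1),
                               posB = sample(3000:6999, 1)))
    d1 <- microhomology_distance(bp, structure(list(matches = m1),
                                               class = "MicrohomologyMap"), ct)
    d2 <- microhomology_distance(bp, structure(list(matches = m2),
                                               class = "MicrohomologyMap"), ct)
    expect_lte(d2, d1)
  }
})

test_that("assemble_feature_vector has fixed order and strict completeness", {
  v <- assemble_feature_vector(ffpm = 1.5, far_5p = 3, far_3p = 12,
                               counter_ffpm_5p = 0.2, counter_ffpm_3p = 0.1,
                               consensus = TRUE, ref_agree = TRUE,
                               n_microhomologies = 4,
                               microhomology_distance = 812.3)
  expect_identical(names(v), FEATURE_NAMES)
  expect_equal(unname(v[c("consensus_indicator", "ref_agree_indicator")]),
               c(1, 0) + c(0, 1))
  expect_error(
    assemble_feature_vector(ffpm = 1, far_5p = 1, far_3p = 1,
                            counter_ffpm_5p = 0, counter_ffpm_3p = 0,
                            consensus = NA, ref_agree = TRUE,
                            n_microhomologies = 0,
                            microhomology_distance = 1),
    "missing attribute")
})
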