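test_that("fragment walking reproduces the hand-counted single-locus geometry", {
  # NotI cut 7, BamHI cut 21, MspI cut 31 on a 40 bp chromosome
  fr <- enumerate_fragments(tiny_hap(), "MspI")
  plus <- fr[fr$direction == "+", ]
  expect_equal(plus$len_1d, 24L)
  expect_equal(plus$end_1d_kind, "second_enzyme")
  expect_equal(plus$len_2d, 14L)
  expect_equal(plus$end_2d_kind, "BamHI")
  minus <- fr[fr$direction == "-", ]
  expect_equal(minus$len_1d, 7L)
  expect_equal(minus$end_1d_kind, "sequence_end")

  # outer_C blocks both isoschizomers: the walk passes the M site and
  # runs to the chromosome end
  fr <- enumerate_fragments(tiny_hap("outer_C"), "MspI")
  plus <- fr[fr$direction == "+", ]
  expect_equal(plus$end_1d_kind, "sequence_end")
  expect_equal(plus$len_1d, 33L)
  expect_equal(plus$len_2d, 14L)

  # internal_C: MspI still cuts, HpaII does not
  fr_m <- enumerate_fragments(tiny_hap("internal_C"), "MspI")
  fr_h <- enumerate_fragments(tiny_hap("internal_C"), "HpaII")
  expect_equal(fr_m$len_1d[fr_m$direction == "+"], 24L)
  expect_equal(fr_h$end_1d_kind[fr_h$direction == "+"], "sequence_end")

  # BamHI site removed from the sequence: 2D length collapses onto 1D
  fr <- enumerate_fragments(tiny_hap(drop_bamHI = TRUE), "MspI")
  plus <- fr[fr$direction == "+", ]
  expect_equal(plus$len_2d, plus$len_1d)
  expect_equal(plus$len_1d, 24L)
  expect_equal(plus$end_2d_kind, "same_as_1d")

  # fragment invariants
  all_fr <- rbind(fr, fr_m, fr_h)
  expect_true(all(all_fr$len_2d <= all_fr$len_1d))
  expect_true(all(all_fr$len_1d > 0))
})

test_that("empty genomes and landmark-free genomes give empty results", {
  hap <- haplotype("h", c(chr1 = "ACGTACGTACGT"))
  expect_equal(nrow(enumerate_fragments(hap, "MspI")), 0L)
  expect_equal(nrow(haplotype_pattern(hap, "MspI", open_gel())$spots), 0L)
})

test_that("mobility is the normalised log-linear map", {
  g <- gel_model(c(100, 10000), c(100, 10000))
  expect_equal(mobility(100, 1, g), 1.0)
  expect_equal(mobility(10000, 1, g), 0.0)
  expect_equal(mobility(1000, 1, g), 0.5)
  expect_equal(mobility(1000, 2, g), 0.5)
  # strictly decreasing in length
  lens <- c(150, 500, 2000, 9000)
  expect_true(all(diff(mobility(lens, 1, g)) < 0))
  expect_error(mobility(50, 1, g), "detection window")
  expect_error(mobility(20000, 2, g), "detection window")
})

test_that("haplotype patterns carry the 0.5 intensity quantum and merge co-migrants", {
  gel <- open_gel()
  pat <- haplotype_pattern(tiny_hap(), "MspI", gel)
  # sequence_end '-' fragment excluded by default: one spot at 0.5
  expect_equal(nrow(pat$spots), 1L)
  expect_equal(pat$spots$intensity, 0.5)
  expect_equal(pat$spots$len_1d, 24L)
  expect_equal(pat$spots$len_2d, 14L)

  # sequence_end fragments can be opted in
  pat2 <- haplotype_pattern(tiny_hap(), "MspI", gel,
                            include_sequence_end = TRUE)
  expect_equal(nrow(pat2$spots), 2L)

  # two loci engineered to identical lengths merge into one 1.0 spot
  two <- haplotype("two", c(chrA = tiny_locus_seq(), chrB = tiny_locus_seq()))
  pat3 <- haplotype_pattern(two, "MspI", gel)
  expect_equal(nrow(pat3$spots), 1L)
  expect_equal(pat3$spots$intensity, 1.0)
  expect_equal(pat3$spots$n_loci, 2L)
  expect_match(pat3$spots$loci, "chrA.*;.*chrB")
})

test_that("diploid patterns sum allele contributions", {
  gel <- open_gel()
  # both alleles produce the fragment: full intensity
  hom <- diploid(tiny_hap(id = "a1"), tiny_hap(id = "a2"), "hom")
  pat <- diploid_pattern(hom, "MspI", gel)
  expect_equal(pat$spots$intensity[pat$spots$len_1d == 24], 1.0)

  # one allele outer_C-blocked: the landmark spot halves
  het <- diploid(tiny_hap(id = "a1"), tiny_hap("outer_C", id = "a2"), "het")
  pat <- diploid_pattern(het, "MspI", gel)
  expect_equal(spot_intensity_at(pat, 24, 14), 0.5)

  # one allele lacks the BamHI site, the other is blocked: spot absent
  mix <- diploid(tiny_hap(drop_bamHI = TRUE, id = "a1"),
                 tiny_hap("outer_C", id = "a2"), "mix")
  pat <- diploid_pattern(mix, "MspI", gel)
  expect_equal(spot_intensity_at(pat, 24, 14), 0)
})

test_that("fragment enumeration agrees with the brute-force digestion oracle", {
  for (seed in 1:30) {
    hap <- random_test_hap(seed)
    for (second in c("MspI", "HpaII")) {
      got <- enumerate_fragments(hap, second)
      want <- oracle_fragments(hap, second)
      expect_equal(got, want, info = sprintf("seed %d %s", seed, second))
    }
  }
})

test_that("removing the overlay makes [MspI] and [HpaII] patterns identical", {
  gel <- open_gel()
  for (seed in c(3, 17)) {
    hap <- random_test_hap(seed, overlay_frac = 0)
    pm <- haplotype_pattern(hap, "MspI", gel)
    ph <- haplotype_pattern(hap, "HpaII", gel)
    expect_equal(pm$spots, ph$spots)
  }
})

test_that("blocking one allele's M site never increases any spot intensity", {
  gel <- open_gel()
  base_hap <- tiny_hap(id = "a2")
  ind0 <- diploid(tiny_hap(id = "a1"), base_hap, "d0")
  ind1 <- diploid(tiny_hap(id = "a1"), tiny_hap("outer_C", id = "a2"), "d1")
  p0 <- diploid_pattern(ind0, "MspI", gel)
  p1 <- diploid_pattern(ind1, "MspI", gel)
  for (r in seq_len(nrow(p0$spots))) {
    before <- p0$spots$intensity[r]
    after <- spot_intensity_at(p1, p0$spots$len_1d[r], p0$spots$len_2d[r])
    expect_true(after <= before)
    expect_true(after == before || before - after == 0.5)
  }
})

test_that("total diploid intensity doubles the haploid in-window fragment count", {
  gel <- gel_model()
  for (seed in c(5, 21)) {
    hap <- random_test_hap(seed, length = 8000, overlay_frac = 0)
    hap2 <- hap; hap2$id <- paste0(hap$id, "b")
    ind <- diploid(hap, hap2, "ident")
    pat_hap <- haplotype_pattern(hap, "MspI", gel)
    pat_dip <- diploid_pattern(ind, "MspI", gel)
    n_frag <- sum(pat_hap$spots$n_loci)
    expect_equal(sum(pat_dip$spots$intensity), 2 * n_frag * 0.5)
  }
})
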