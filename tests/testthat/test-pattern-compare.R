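make_pattern <- function(len_1d, len_2d, intensity, ids = seq_along(len_1d),
                         gel = open_gel(), sample_id = "s", combo = "MspI") {
  spots <- data.frame(
    x1 = mobility(len_1d, 1, gel), x2 = mobility(len_2d, 2, gel),
    len_1d = as.integer(len_1d), len_2d = as.integer(len_2d),
    intensity = intensity,
    loci = sprintf("chr1:%d:+:h%d", as.integer(len_1d), ids),
    n_loci = 1L, stringsAsFactors = FALSE)
  spot_pattern(sample_id, combo, spots, gel)
}

test_that("match_spots self-match, orphans and intensity ratios", {
  a <- make_pattern(c(2400, 1200, 800), c(1400, 900, 700), c(1, 1, 0.5))
  m <- match_spots(a, a)
  expect_true(all(m$status == "both"))
  expect_true(all(m$intensity_ratio == 1))

  b <- make_pattern(c(2400, 1200), c(1400, 900), c(1, 0.5))
  m <- match_spots(a, b)
  expect_equal(m$status[m$len_1d_a == 800 & !is.na(m$len_1d_a)], "a_only")
  expect_equal(m$intensity_ratio[m$len_1d_a == 1200 & !is.na(m$len_1d_a)], 0.5)

  # differing gel models are rejected
  b2 <- make_pattern(2400, 1400, 1, gel = gel_model())
  expect_error(match_spots(a, b2), "gel models")
})

test_that("match_spots is symmetric up to status labels", {
  set.seed(4)
  l1 <- sort(sample(500:20000, 12))
  a <- make_pattern(l1, pmax(100L, l1 %/% 2L), sample(c(0.5, 1), 12, TRUE))
  l2 <- l1[-c(2, 5)]
  b <- make_pattern(c(l2, 4321), c(pmax(100L, l2 %/% 2L), 2100),
                    c(sample(c(0.5, 1), 10, TRUE), 1))
  ab <- match_spots(a, b)
  ba <- match_spots(b, a)
  expect_equal(sum(ab$status == "both"), sum(ba$status == "both"))
  expect_equal(sum(ab$status == "a_only"), sum(ba$status == "b_only"))
  expect_equal(sum(ab$status == "b_only"), sum(ba$status == "a_only"))
  both_ab <- ab[ab$status == "both", ]
  both_ba <- ba[ba$status == "both", ]
  expect_equal(sort(both_ab$intensity_ratio), sort(1 / both_ba$intensity_ratio))
})

test_that("intensity classification bands sit around 1 and 1/2", {
  expect_equal(classify_intensity(0.5, 1.0), "half")
  expect_equal(classify_intensity(1.0, 1.0), "full")
  expect_equal(classify_intensity(0.77, 1.0, tol = 0.1), "other")
  expect_equal(classify_intensity(0, 1.0), "absent")
  expect_equal(classify_intensity(c(1.05, 0.52, 0.3, 0), 1.0),
               c("full", "half", "other", "absent"))
  expect_error(classify_intensity(0.5, 0), "baseline")
})

test_that("modal intensity acts as the surrounding-spot baseline", {
  pat <- make_pattern(c(2400, 1200, 800, 600), c(1400, 900, 700, 500),
                      c(0.5, 1, 1, 1))
  expect_equal(modal_intensity(pat), 1)
  # tie broken towards the larger intensity
  pat2 <- make_pattern(c(2400, 1200), c(1400, 900), c(0.5, 1))
  expect_equal(modal_intensity(pat2), 1)
})

test_that("msp_hpa_diff calls internal-C methylation from combo differences", {
  # spot present in [MspI], absent in [HpaII]: homozygous internal_C
  pm <- make_pattern(c(2400, 1200), c(1400, 900), c(1, 1))
  ph <- make_pattern(1200, 900, 1, ids = 2)
  calls <- msp_hpa_diff(pm, ph)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$call, "internal_C_methylated")
  expect_equal(calls$zygosity, "homozygous")

  # identical patterns: zero calls
  expect_equal(nrow(msp_hpa_diff(pm, pm)), 0L)

  # [MspI] full, [HpaII] half: heterozygous internal_C
  ph2 <- make_pattern(c(2400, 1200), c(1400, 900), c(0.5, 1))
  calls <- msp_hpa_diff(pm, ph2)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$call, "internal_C_methylated")
  expect_equal(calls$zygosity, "heterozygous")
})

test_that("msp_hpa_diff on a real heterozygous internal_C diploid", {
  gel <- open_gel()
  het <- diploid(tiny_hap(id = "a1"), tiny_hap("internal_C", id = "a2"), "het")
  pm <- diploid_pattern(het, "MspI", gel)
  ph <- diploid_pattern(het, "HpaII", gel)
  expect_equal(spot_intensity_at(pm, 24, 14), 1.0)
  expect_equal(spot_intensity_at(ph, 24, 14), 0.5)
  calls <- msp_hpa_diff(pm, ph)
  focal <- calls[calls$len_1d == 24, ]
  expect_equal(focal$call, "internal_C_methylated")
  expect_equal(focal$zygosity, "heterozygous")
  # brute-force digestion of both alleles confirms the halving
  o1 <- oracle_fragments(tiny_hap(id = "a1"), "HpaII")
  o2 <- oracle_fragments(tiny_hap("internal_C", id = "a2"), "HpaII")
  in_1d <- function(o) o[o$end_1d_kind != "sequence_end" & o$len_1d == 24, ]
  expect_equal(nrow(in_1d(o1)), 1L)
  expect_equal(nrow(in_1d(o2)), 0L)
})

test_that("a reference pattern turns joint absence into blocked_or_absent", {
  ref <- make_pattern(c(2400, 1200), c(1400, 900), c(1, 1))
  pm <- make_pattern(1200, 900, 1, ids = 2)
  ph <- make_pattern(1200, 900, 1, ids = 2)
  calls <- msp_hpa_diff(pm, ph, reference = ref)
  expect_equal(calls$call, "blocked_or_absent")
  expect_equal(calls$len_1d, 2400)
})

test_that("methylation-call recovery is exact on planted synthetic diploids", {
  gel <- gel_model()
  for (seed in c(2, 9)) {
    for (zyg in c("hom", "het")) {
      h1 <- build_locus(locus_spec(), background_length = 6000, seed = seed,
                        m_state = "internal_C", id = "a1")
      h2 <- build_locus(locus_spec(), background_length = 6000, seed = seed,
                        m_state = if (zyg == "hom") "internal_C"
                                  else "unmethylated", id = "a2")
      ind <- diploid(h1, h2, "ind")
      calls <- msp_hpa_diff(diploid_pattern(ind, "MspI", gel),
                            diploid_pattern(ind, "HpaII", gel))
      hits <- calls[calls$call == "internal_C_methylated", ]
      expect_equal(nrow(hits), 1L, info = paste(seed, zyg))
      expect_equal(hits$len_1d, 2400L)
      expect_equal(hits$zygosity,
                   if (zyg == "hom") "homozygous" else "heterozygous")
    }
    # unmethylated genome: no calls at all
    h1 <- build_locus(locus_spec(), background_length = 6000, seed = seed,
                      id = "a1")
    h2 <- build_locus(locus_spec(), background_length = 6000, seed = seed,
                      id = "a2")
    ind <- diploid(h1, h2, "ind")
    calls <- msp_hpa_diff(diploid_pattern(ind, "MspI", gel),
                          diploid_pattern(ind, "HpaII", gel))
    expect_equal(nrow(calls), 0L)
  }
})
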