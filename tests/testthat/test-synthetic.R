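test_that("build_locus plants the declared cut geometry exactly", {
  hap <- build_locus(locus_spec(spacing_nb = 1400, spacing_bm = 1000),
                     background_length = 6000, seed = 1)
  fr <- enumerate_fragments(hap, "MspI")
  plus <- fr[fr$direction == "+" & fr$landmark_cut == hap$focal$n_cut, ]
  expect_equal(plus$len_1d, 2400L)
  expect_equal(plus$len_2d, 1400L)
  expect_equal(plus$end_1d_kind, "second_enzyme")
  expect_equal(plus$end_2d_kind, "BamHI")

  # B-absent variant: the fragment runs to the M cut in both dimensions
  hap <- build_locus(locus_spec(b_present = FALSE),
                     background_length = 6000, seed = 1)
  fr <- enumerate_fragments(hap, "MspI")
  plus <- fr[fr$direction == "+" & fr$landmark_cut == hap$focal$n_cut, ]
  expect_equal(plus$len_2d, 2400L)
  expect_equal(plus$len_2d, plus$len_1d)

  # overlapping plantings are rejected
  expect_error(locus_spec(spacing_nb = 3), "overlap")
  expect_error(locus_spec(spacing_bm = 2), "overlap")
  expect_error(locus_spec(next_notI = 1403), "overlap")
})

test_that("a planted second NotI closer than M truncates the 1D walk", {
  hap <- build_locus(locus_spec(spacing_nb = 1400, spacing_bm = 1000,
                                next_notI = 1800),
                     background_length = 7000, seed = 2)
  fr <- enumerate_fragments(hap, "MspI")
  plus <- fr[fr$direction == "+" & fr$landmark_cut == hap$focal$n_cut, ]
  expect_equal(plus$len_1d, 1800L)
  expect_equal(plus$end_1d_kind, "NotI")
  expect_equal(plus$len_2d, 1400L)
})

test_that("generation is byte-identical under a fixed seed", {
  a <- build_locus(locus_spec(), background_length = 5000, seed = 7)
  b <- build_locus(locus_spec(), background_length = 5000, seed = 7)
  expect_identical(a, b)
  c <- build_locus(locus_spec(), background_length = 5000, seed = 8)
  expect_false(identical(a$sequences, c$sequences))

  fx1 <- nipponbare_kasalath_fixture(seed = 3)
  fx2 <- nipponbare_kasalath_fixture(seed = 3)
  expect_identical(fx1, fx2)

  p1 <- simulate_cross(fx1$parent_N, fx1$parent_K, 5, "mendelian", seed = 9)
  p2 <- simulate_cross(fx2$parent_N, fx2$parent_K, 5, "mendelian", seed = 9)
  expect_identical(p1, p2)
})

test_that("the fixture parents reproduce the half-intensity / absent spots", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  for (combo in c("MspI", "HpaII")) {
    pN <- diploid_pattern(fx$parent_N, combo)
    pK <- diploid_pattern(fx$parent_K, combo)
    expect_equal(spot_intensity_at(pN, f$len_1d, f$len_2d), 0.5, info = combo)
    expect_equal(spot_intensity_at(pK, f$len_1d, f$len_2d), 0, info = combo)
  }
})

test_that("only focal-locus spots differ between the fixture parents", {
  fx <- nipponbare_kasalath_fixture(seed = 2)
  pN <- diploid_pattern(fx$parent_N, "MspI")
  pK <- diploid_pattern(fx$parent_K, "MspI")
  m <- match_spots(pN, pK)
  diffs <- m[m$status != "both" |
               (m$status == "both" & m$intensity_ratio != 1), ]
  # every differing spot originates at the focal landmark cut
  focal_key <- sprintf("%s:%d:", fx$focal$chrom, fx$focal$n_cut)
  expect_gt(nrow(diffs), 0)
  expect_true(all(grepl(focal_key, diffs$locus, fixed = TRUE)))
  # and the shared background spots all match at equal intensity
  shared <- m[m$status == "both" & !grepl(focal_key, m$locus, fixed = TRUE), ]
  expect_gt(nrow(shared), 0)
  expect_true(all(shared$intensity_ratio == 1))
})

test_that("maintenance selfing reproduces the all-half signature", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  panel <- fx$panels$selfed_N   # maintain_heterozygous, n = 9
  cls <- panel_spot_classes(panel, f$len_1d, f$len_2d)
  expect_equal(cls$class, rep("half", 9))
  expect_equal(cls$intensity, rep(0.5, 9))
})

test_that("Mendelian transmission segregates alleles 1:1", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  panel <- simulate_cross(fx$parent_N, fx$parent_K, 400, "mendelian",
                          seed = 11)
  cls <- panel_spot_classes(panel, f$len_1d, f$len_2d)
  expect_true(all(cls$class %in% c("half", "absent")))
  frac <- mean(cls$class == "half")
  # 3 binomial standard errors at n = 400
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))

  # empty panel
  empty <- simulate_cross(fx$parent_N, fx$parent_K, 0, "mendelian", seed = 1)
  expect_equal(length(empty$individuals), 0L)
  expect_equal(nrow(panel_spot_classes(empty, f$len_1d, f$len_2d)), 0L)
  expect_error(simulate_cross(fx$parent_N, fx$parent_K, -1), "non-negative")
})

test_that("demethylation model erases the focal epiallele in progeny", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  panel <- simulate_cross(fx$parent_N, fx$parent_N, 8,
                          "demethylate_progeny", seed = 13)
  cls <- panel_spot_classes(panel, f$len_1d, f$len_2d)
  expect_equal(cls$class, rep("full", 8))
})

test_that("maintenance probability below 1 mixes the two behaviours", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  model <- transmission_model("maintain_heterozygous", maintenance_prob = 0)
  panel <- simulate_cross(fx$parent_N, fx$parent_N, 30, model, seed = 17)
  cls <- panel_spot_classes(panel, f$len_1d, f$len_2d)
  # prob 0 degenerates to Mendelian: all three classes should appear at n=30
  expect_true(all(c("absent", "half", "full") %in% cls$class))
  expect_error(transmission_model("maintain_heterozygous", 1.5))
})

test_that("F1 spot genotypes follow the transmitted epiallele", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  f <- fx$focal
  panel <- fx$panels$NKF1
  cls <- panel_spot_classes(panel, f$len_1d, f$len_2d)
  for (k in seq_along(panel$individuals)) {
    geno <- spot_genotype(panel$individuals[[k]])
    expect_equal(cls$class[k] == "half", sum(geno) == 1L)
    expect_equal(cls$class[k] == "absent", sum(geno) == 0L)
  }
})

test_that("parental spot genotypes expose the fixture design", {
  fx <- nipponbare_kasalath_fixture(seed = 1)
  expect_equal(spot_genotype(fx$parent_N), c(TRUE, FALSE))
  expect_equal(spot_genotype(fx$parent_K), c(FALSE, FALSE))
  # outer_C blocks HpaII too
  expect_equal(spot_genotype(fx$parent_N, combo = "HpaII"), c(TRUE, FALSE))
})
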