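test_that("find_extrema handles the toy, monotone and triangle profiles", {
  ex <- find_extrema(c(1, 3, 2, 4, 2, 5, 1), min_separation = 1)
  expect_equal(ex$value[ex$kind == "peak"], c(3, 4, 5))
  expect_equal(ex$position[ex$kind == "peak"], c(2, 4, 6))
  expect_equal(ex$value[ex$kind == "valley"], c(2, 2))

  expect_equal(nrow(find_extrema(1:10, min_separation = 1)), 0L)
  expect_equal(nrow(find_extrema(10:1, min_separation = 1)), 0L)

  tri <- find_extrema(c(1, 2, 3, 4, 3, 2, 1), min_separation = 1)
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$position, 4L)
  expect_equal(tri$kind, "peak")

  expect_error(find_extrema(c(1, 2)), "at least 3")
})

test_that("plateaus reduce to their central point, ties toward smaller index", {
  ex <- find_extrema(c(0, 5, 5, 5, 0), min_separation = 1)
  expect_equal(ex$position, 3L)
  ex2 <- find_extrema(c(0, 5, 5, 0), min_separation = 1)   # even run
  expect_equal(ex2$position, 2L)
  # plateau valley
  ex3 <- find_extrema(c(3, 1, 1, 1, 3), min_separation = 1)
  expect_equal(ex3$kind, "valley")
  expect_equal(ex3$position, 3L)
  # boundary plateaus are not interior
  expect_equal(nrow(find_extrema(c(5, 5, 1, 5, 5), min_separation = 1)), 1L)
})

test_that("min_separation keeps the higher of close peaks, highest first", {
  # peaks at 2 (v=10), 5 (v=8), 12 (v=9); sep 5 drops the 8 next to the 10,
  # keeps the 9 which is >= 5 away from position 2... then drops nothing else
  v <- c(0, 10, 0, 0, 8, 0, 0, 0, 0, 0, 0, 9, 0)
  ex <- find_extrema(v, min_separation = 5)
  pk <- ex[ex$kind == "peak", ]
  expect_equal(pk$position, c(2L, 12L))
  expect_equal(pk$value, c(10, 9))
  # with sep 1 all three survive
  ex1 <- find_extrema(v, min_separation = 1)
  expect_equal(sum(ex1$kind == "peak"), 3L)
  # valleys are thinned lowest-first, independently of peaks
  v2 <- c(5, -10, 5, -8, 5, 0, 5, -9, 5)
  ex2 <- find_extrema(v2, min_separation = 3)
  vl <- ex2[ex2$kind == "valley", ]
  expect_equal(vl$value, c(-10, -9))
})

test_that("top_k_peaks selects by value with position tie-breaks and flags short sets", {
  prof <- planted_profile(c(7, 3, 9, 5, 8, 2, 6))
  ex <- find_extrema(prof, min_separation = 1)
  ps <- top_k_peaks(ex, k = 5)
  expect_equal(ps$peaks$value, c(9, 8, 7, 6, 5))
  expect_false(ps$short)

  short <- top_k_peaks(find_extrema(planted_profile(c(4, 2, 6)),
                                    min_separation = 1), k = 5)
  expect_true(short$short)
  expect_equal(nrow(short$peaks), 3L)

  # tie at the cutoff: equal 5th values at positions 100 < 200 keep the earlier
  heights <- c(10, 9, 8, 7, 5, 5)
  prof2 <- numeric(220)
  pos <- c(20, 40, 60, 80, 100, 200)
  prof2[pos] <- heights
  ex2 <- find_extrema(prof2, min_separation = 1)
  ps2 <- top_k_peaks(ex2, k = 5)
  expect_equal(sort(ps2$peaks$position), c(20, 40, 60, 80, 100))

  expect_error(top_k_peaks(find_extrema(1:5, min_separation = 1)),
               "empty level set")
  expect_error(top_k_peaks(ex, k = 1), "at least 2")
})

test_that("level_deviation computes mad and sd with the documented edge cases", {
  ps <- top_k_peaks(find_extrema(planted_profile(c(1, 2, 3, 4, 5)),
                                 min_separation = 1), k = 5)
  expect_equal(level_deviation(ps, "mad")$deviation, 1.2)
  expect_equal(level_deviation(ps, "sd")$deviation, sd(1:5), tolerance = 1e-12)
  expect_equal(level_deviation(ps)$mean_level, 3)

  level <- top_k_peaks(find_extrema(planted_profile(rep(4, 5)),
                                    min_separation = 1), k = 5)
  expect_equal(level_deviation(level, "mad")$deviation, 0)
  expect_equal(level_deviation(level, "sd")$deviation, 0)

  # mad never exceeds sd (checked over random sets)
  set.seed(7)
  for (i in 1:50) {
    vals <- rnorm(sample(2:8, 1), mean = 10, sd = 2)
    ps <- top_k_peaks(find_extrema(planted_profile(vals), min_separation = 1),
                      k = max(2, length(vals)))
    expect_lte(level_deviation(ps, "mad")$deviation,
               level_deviation(ps, "sd")$deviation + 1e-12)
  }
})

test_that("level_members finds the largest band exactly", {
  ps <- top_k_peaks(find_extrema(planted_profile(c(10, 10.1, 9.9, 5, 15)),
                                 min_separation = 1), k = 5)
  got <- level_members(ps, epsilon = 0.2)
  expect_equal(got$count, 3L)
  expect_setequal(got$members$value, c(10, 10.1, 9.9))
  expect_equal(level_members(ps, epsilon = Inf)$count, 5L)

  lev <- top_k_peaks(find_extrema(planted_profile(rep(2, 4)),
                                  min_separation = 1), k = 4)
  expect_equal(level_members(lev, epsilon = 0.01)$count, 4L)
  expect_error(level_members(ps, epsilon = 0), "positive")

  # agreement with the exhaustive subset oracle on random value sets
  set.seed(19)
  for (i in 1:40) {
    vals <- round(rnorm(sample(2:8, 1), mean = 10, sd = 2), 2)
    eps <- runif(1, 0.1, 2)
    ps <- top_k_peaks(find_extrema(planted_profile(vals), min_separation = 1),
                      k = max(2, length(vals)))
    expect_equal(level_members(ps, eps)$count,
                 oracle_level_members(ps$peaks$value, eps))
  }
})

test_that("match_peaks pairs by nearest position within max_shift", {
  g <- generate_sequence(synthetic_spec(seed = 55))
  p <- compute_profile(g$record, "KD", 9)
  self <- match_peaks(p, p, max_shift = 10)
  ok <- !is.na(self$position_a)
  expect_equal(self$position_a[ok], self$position_b[ok])

  # shifted copy: all pairs at the construction offset
  seqstr <- g$record$residues
  shifted <- seq_record("b", paste0(strrep("G", 3), seqstr))
  pb <- compute_profile(shifted, "KD", 9)
  mp <- match_peaks(p, pb, max_shift = 10)
  paired <- mp[!is.na(mp$position_a) & !is.na(mp$position_b), ]
  expect_true(nrow(paired) >= 5)
  expect_true(all(paired$position_b - paired$position_a == 3))

  # positions beyond max_shift match nothing
  mp2 <- match_peaks(p, pb, max_shift = 0)
  expect_true(all(is.na(mp2$position_b) | is.na(mp2$position_a)))

  expect_error(match_peaks(p, compute_profile(g$record, "KD", 7)),
               "share window")
  expect_error(match_peaks(p, compute_profile(g$record, "MZ", 9)),
               "share window")
})

test_that("compare_species ranks planted spreads correctly and survives failures", {
  tight <- generate_sequence(synthetic_spec(level_spread = 0.1, seed = 201))
  loose <- generate_sequence(synthetic_spec(level_spread = 1.0, seed = 202))
  flat <- seq_record("flat", strrep("A", 120), species = "flatfish")
  cmp <- compare_species(list(loose$record, tight$record, flat),
                         scale = "KD", window = 9, k = 5)
  expect_s3_class(cmp, "species_comparison")
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$id[1], tight$record$id)
  expect_equal(cmp$rank[1:2], 1:2)
  expect_true(is.na(cmp$deviation[3]))
  expect_match(cmp$note[3], "level set|peak")

  single <- compare_species(tight$record, scale = "KD")
  expect_equal(single$rank, 1L)
  expect_error(compare_species(list()), "no records")
})

test_that("valley polarity scores the hydrophilic minima with the same machinery", {
  g <- generate_sequence(synthetic_spec(seed = 77))
  f_peak <- levelfit(g$record, scale = "KD")
  f_valley <- levelfit(g$record, scale = "KD", polarity = "valleys")
  expect_true(all(f_valley$peaks$peaks$value <= f_peak$peaks$peaks$value))
  # inverting the scale swaps the roles: valley fit on -scale == peak fit
  inv <- rescale(load_scale("KD"), -1, 0)
  f_inv <- levelfit(g$record, scale = inv, polarity = "valleys")
  expect_equal(sort(f_inv$peaks$peaks$position),
               sort(f_peak$peaks$peaks$position))
  expect_equal(f_inv$stat$deviation, f_peak$stat$deviation, tolerance = 1e-12)
})
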