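enum_on <- function(depths) {
  tr <- make_track(depths)
  enumerate_candidates(tr, detect_landmarks(tr))
}

test_that("a single bump yields exactly one candidate triple", {
  cc <- enum_on(c(0, 5, 0))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$start_bin, 0L)
  expect_equal(cc$apex_bin, 1L)
  expect_equal(cc$end_bin, 2L)
  expect_equal(cc$baseline, 0)
  expect_equal(cc$max_excess, 5)
  expect_equal(cc$integrated_excess, 5)
})

test_that("no maxima means no candidates", {
  cc <- enum_on(c(3, 3, 3, 3))
  expect_equal(nrow(cc), 0L)
})

test_that("two flanking minima per side give all four combinations", {
  cc <- enum_on(c(1, 3, 0, 6, 0, 3, 1))
  central <- cc[cc$apex_bin == 3L, ]
  expect_equal(nrow(central), 4L)
  expect_setequal(
    paste(central$start_bin, central$end_bin),
    c("0 4", "0 6", "2 4", "2 6")
  )
})

test_that("enumeration equals the brute-force triple scan on random tracks", {
  for (seed in 1:20) {
    d0 <- random_track(seed, n_bins = 45L)
    tr <- smooth_track(make_track(d0), window_bins = 3)
    lm <- detect_landmarks(tr)
    got <- as.data.frame(enumerate_candidates(tr, lm))
    want <- oracle_enumerate(tr$depth, lm)
    got <- got[order(got$start_bin, got$end_bin, got$apex_bin), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_bin, want$start_bin)
    expect_equal(got$apex_bin, want$apex_bin)
    expect_equal(got$end_bin, want$end_bin)
    expect_equal(got$baseline, want$baseline, tolerance = 1e-9)
    expect_equal(got$max_excess, want$max_excess, tolerance = 1e-9)
    expect_equal(got$integrated_excess, want$integrated_excess, tolerance = 1e-9)
  }
})

test_that("threshold boundaries are strict and epsilon above passes", {
  cand <- tibble::tibble(
    chrom = "chr1",
    start_bin = c(0L, 0L, 0L, 0L), apex_bin = c(5L, 5L, 5L, 5L),
    end_bin = c(10L, 10L, 10L, 10L),
    baseline = 0,
    max_excess = c(2.5, 2.5 + 1e-9, 2.5 + 1e-9, 10),
    net_excess = c(10, 10, 5, 5),
    width_bins = 11L,
    integrated_excess = c(10, 10, 5, 5 + 1e-9)
  )
  kept <- filter_candidates(cand, peak_params(), dedup = FALSE)
  # row 1: max_excess exactly 2.5 -> rejected; row 3: area exactly 5 ->
  # rejected; rows 2 and 4 are epsilon above both thresholds
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$max_excess > 2.5 & kept$integrated_excess > 5))
})

test_that("excess arithmetic decides the documented bump cases", {
  kept <- filter_candidates(enum_on(c(0, 3, 6, 3, 0)), peak_params(), dedup = FALSE)
  expect_equal(nrow(kept), 1L) # max 6 > 2.5, area 12 > 5
  expect_equal(kept$max_excess, 6)
  expect_equal(kept$integrated_excess, 12)

  rejected <- filter_candidates(enum_on(c(0, 3, 0)), peak_params(), dedup = FALSE)
  expect_equal(nrow(rejected), 0L) # max 3 > 2.5 but area 3 < 5
})

test_that("raising either threshold never adds a peak", {
  for (seed in 1:10) {
    d0 <- random_track(seed, n_bins = 60L)
    tr <- smooth_track(make_track(d0), window_bins = 3)
    cc <- enumerate_candidates(tr, detect_landmarks(tr))
    key <- function(df) paste(df$start_bin, df$apex_bin, df$end_bin)
    base <- filter_candidates(cc, peak_params(), dedup = FALSE)
    higher1 <- filter_candidates(cc, peak_params(max_excess_min = 4), dedup = FALSE)
    higher2 <- filter_candidates(cc, peak_params(area_min = 12), dedup = FALSE)
    expect_true(all(key(higher1) %in% key(base)))
    expect_true(all(key(higher2) %in% key(base)))
  }
})

test_that("translating a track translates the surviving peaks", {
  bump <- 20 * exp(-(seq_len(60) - 20)^2 / 8)
  shift <- 7L
  bump_shifted <- 20 * exp(-(seq_len(60) - 27)^2 / 8)
  pk <- function(x) {
    tr <- smooth_track(make_track(x), window_bins = 3)
    filter_candidates(enumerate_candidates(tr, detect_landmarks(tr)), peak_params())
  }
  a <- pk(bump)
  b <- pk(bump_shifted)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$start_bin + shift, b$start_bin)
  expect_equal(a$apex_bin + shift, b$apex_bin)
  expect_equal(a$end_bin + shift, b$end_bin)
})

test_that("scaling depths scales both excess statistics linearly", {
  d0 <- random_track(4, n_bins = 50L)
  key <- function(df) paste(df$start_bin, df$apex_bin, df$end_bin)
  tr1 <- smooth_track(make_track(d0), window_bins = 3)
  tr3 <- smooth_track(make_track(3 * d0), window_bins = 3)
  c1 <- enumerate_candidates(tr1, detect_landmarks(tr1))
  c3 <- enumerate_candidates(tr3, detect_landmarks(tr3))
  c1 <- c1[order(key(c1)), ]
  c3 <- c3[order(key(c3)), ]
  expect_equal(key(c1), key(c3))
  expect_equal(3 * c1$max_excess, c3$max_excess, tolerance = 1e-9)
  expect_equal(3 * c1$integrated_excess, c3$integrated_excess, tolerance = 1e-9)
})
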