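test_that("occurrence counting follows the both-strand convention", {
  expect_equal(count_motif_occurrences("CCCCACCCCA", "CCCCACCCC"), 1L)
  # 2 forward; the reverse complement TTTTT never occurs on the forward
  # sequence, so no additional minus-strand hits
  expect_equal(count_motif_occurrences("AAAAAA", "AAAAA"), 2L)
  # a true minus-strand occurrence is counted
  expect_equal(count_motif_occurrences("GTTTTTG", "AAAAA"), 1L)
  expect_equal(count_motif_occurrences("ACA", "ANA"), 1L) # N matches C
  # N in the sequence matches nothing, not even motif N
  expect_equal(count_motif_occurrences("ANA", "AAA"), 0L)
  expect_equal(count_motif_occurrences("ANA", "ANA"), 0L)
  expect_error(count_motif_occurrences("ACGT", "AC-T"), class = "peakshift_config_error")
})

test_that("occurrence counting equals the brute-force scanner", {
  motifs <- c("AAAAA", "CCCCACCCC", "TAGAAATA", "ANGCW", "RYSWK")
  withr::with_seed(99, {
    for (i in 1:30) {
      n <- sample(50:1000, 1)
      seq <- paste(
        sample(c("A", "C", "G", "T", "N"), n,
          replace = TRUE, prob = c(rep(0.2425, 4), 0.03)
        ),
        collapse = ""
      )
      m <- sample(motifs, 1)
      expect_equal(
        count_motif_occurrences(seq, m),
        oracle_count_occurrences(seq, m),
        info = paste("seed case", i, "motif", m)
      )
    }
  })
})

test_that("counts are symmetric under reverse complement of the sequence", {
  withr::with_seed(7, {
    for (i in 1:10) {
      seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      for (m in c("CCCCACCCC", "TAGAAATA", "ANA")) {
        expect_equal(
          count_motif_occurrences(seq, m),
          count_motif_occurrences(revcomp(seq), m)
        )
      }
    }
  })
})

test_that("consolidation merges homologous motifs and reassigns ids", {
  m <- tibble::tibble(
    consensus = c("AAAAA", "AAAAA", "CCCCC"),
    source_class = c("PEAKS_2_0", "PEAKS_0_5", "PEAKS_2_0")
  )
  cat1 <- consolidate_motifs(m, 0.8)
  expect_equal(nrow(cat1), 2L)
  expect_equal(cat1$motif_id, c(0L, 1L))

  # offset-by-one overlap of 8/8 positions crosses the 0.8 threshold
  m2 <- tibble::tibble(
    consensus = c("CCCCACCCC", "CCCACCCC"),
    source_class = "PEAKS_2_0"
  )
  expect_equal(nrow(consolidate_motifs(m2, 0.8)), 1L)
  # representative is the longest member
  expect_equal(consolidate_motifs(m2, 0.8)$consensus, "CCCCACCCC")

  m3 <- tibble::tibble(
    consensus = c("AAAAA", "CCCCC"), source_class = "PEAKS_2_0"
  )
  expect_equal(nrow(consolidate_motifs(m3, 0.8)), 2L)
})

test_that("consolidation is idempotent", {
  m <- tibble::tibble(
    consensus = c("CCCCACCCC", "CCCACCCC", "TAGAAATA", "AGAAATAG", "GGGGG"),
    source_class = "PEAKS_2_0"
  )
  once <- consolidate_motifs(m, 0.8)
  twice <- consolidate_motifs(once, 0.8)
  expect_equal(once$consensus, twice$consensus)
  expect_equal(once$motif_id, twice$motif_id)
})

test_that("motif similarity is strand- and offset-aware", {
  expect_equal(motif_similarity("AAAAA", "AAAAA"), 1)
  expect_equal(motif_similarity("AAAAA", "TTTTT"), 1) # reverse complement
  expect_equal(motif_similarity("AAAAA", "CCCCC"), 0)
  expect_equal(motif_match_count("CCCCACCCC", "CCCACCCC"), 8L)
})

test_that("planted motifs are recovered from sequences vs background", {
  withr::with_seed(55, {
    rand_seq <- function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }
    fg <- vapply(1:50, function(i) {
      s <- rand_seq(200)
      pos <- sample(1:150, 1)
      paste0(substr(s, 1, pos), "CCCCACCCC", substr(s, pos + 10, 200))
    }, character(1))
    bg <- vapply(1:50, function(i) rand_seq(200), character(1))
  })
  found <- discover_motifs(fg, bg, source_class = "PEAKS_2_0", seed = 1)
  expect_gt(nrow(found), 0L)
  best <- max(vapply(found$consensus, motif_match_count, integer(1), b = "CCCCACCCC"))
  expect_gte(best, 8L)

  # sequences identical to background: nothing is enriched
  none <- discover_motifs(bg, bg, seed = 1)
  expect_equal(nrow(none), 0L)

  expect_error(discover_motifs(fg[1:5]), "at least 10")
})

test_that("frequency vectors are per-kb occurrence rates", {
  genome <- c(chr1 = paste0(
    strrep("G", 100), "CCCCACCCC", strrep("G", 891),
    strrep("T", 500)
  ))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2"), chrom = "chr1",
    start = c(0L, 0L), end = c(1000L, 500L),
    label = c("PEAKS_2_0", "PEAKS_0_5")
  )
  catalog <- consolidate_motifs(
    tibble::tibble(consensus = c("CCCCACCCC", "AAAAAAA"), source_class = "PEAKS_2_0")
  )
  fv <- build_frequency_vectors(peaks, genome, catalog)
  expect_equal(names(fv), c("peak_id", "origin", "motif_0", "motif_1"))
  expect_equal(fv$motif_0[fv$peak_id == "p1"], 1.0) # 1 occurrence / 1 kb
  expect_equal(fv$motif_1, c(0, 0))
  # halving the peak length doubles the rate of a contained occurrence
  genome2 <- c(chr1 = paste0(strrep("G", 100), "CCCCACCCC", strrep("G", 391)))
  peaks2 <- dplyr::mutate(peaks[1, ], end = 500L)
  fv2 <- build_frequency_vectors(peaks2, genome2, catalog)
  expect_equal(fv2$motif_0, 2.0)

  expect_error(
    build_frequency_vectors(peaks, genome, catalog[0, ]),
    "empty motif catalogue"
  )
  bad <- dplyr::mutate(peaks, end = 10000L)
  expect_error(build_frequency_vectors(bad, genome, catalog), "beyond")
})

test_that("unchanged peaks are excluded from vectorization by default", {
  genome <- c(chr1 = strrep("ACGT", 500))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2"), chrom = "chr1",
    start = c(0L, 100L), end = c(400L, 600L),
    label = c("PEAKS_2_0", "UNCHANGED")
  )
  catalog <- consolidate_motifs(
    tibble::tibble(consensus = "ACGTACGT", source_class = "PEAKS_2_0")
  )
  fv <- build_frequency_vectors(peaks, genome, catalog)
  expect_equal(fv$peak_id, "p1")
  fv_all <- build_frequency_vectors(peaks, genome, catalog, include_unchanged = TRUE)
  expect_equal(nrow(fv_all), 2L)
})
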