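fpkm_from_rows <- function(ctrl, m1, m2, m3) {
  genes <- sprintf("g%d", seq_along(ctrl))
  dplyr::bind_rows(
    tibble::tibble(gene_id = genes, sample = "c1", group = "control", fpkm = ctrl),
    tibble::tibble(gene_id = genes, sample = "m1", group = "mutant", fpkm = m1),
    tibble::tibble(gene_id = genes, sample = "m2", group = "mutant", fpkm = m2),
    tibble::tibble(gene_id = genes, sample = "m3", group = "mutant", fpkm = m3)
  )
}

test_that("direction rules follow the gate and all-line thresholds", {
  fp <- fpkm_from_rows(
    ctrl = c(20, 8, 5),
    m1 = c(5, 1, 10), m2 = c(4, 1, 15), m3 = c(6, 1, 12)
  )
  ch <- compute_fold_changes(fp, pseudocount = 0)
  expect_equal(ch$direction[ch$gene_id == "g1"], "DOWN") # ratios .25/.2/.3
  expect_equal(ch$direction[ch$gene_id == "g2"], "NONE") # control below gate
  expect_equal(ch$direction[ch$gene_id == "g3"], "UP") # ratios 2/3/2.4
})

test_that("boundary ratios are inclusive for both rules", {
  fp <- fpkm_from_rows(
    ctrl = c(20, 20),
    m1 = c(10, 40), m2 = c(10, 40), m3 = c(10, 40)
  )
  ch <- compute_fold_changes(fp, pseudocount = 0)
  expect_equal(ch$direction, c("DOWN", "UP")) # exactly 0.5 / exactly 2
})

test_that("the pseudocount guards zero control expression", {
  fp <- fpkm_from_rows(ctrl = 0, m1 = 5, m2 = 5, m3 = 5)
  ch <- compute_fold_changes(fp)
  expect_true(is.finite(ch$min_ratio))
  expect_equal(ch$direction, "UP") # 5.1 / 0.1 = 51 in every line
})

test_that("no gene is ever both UP and DOWN", {
  withr::with_seed(31, {
    fp <- fpkm_from_rows(
      ctrl = runif(200, 0, 100),
      m1 = runif(200, 0, 100), m2 = runif(200, 0, 100), m3 = runif(200, 0, 100)
    )
  })
  ch <- compute_fold_changes(fp)
  is_down <- ch$control_fpkm > 10 & ch$max_ratio <= 0.5
  is_up <- ch$min_ratio >= 2
  expect_false(any(is_down & is_up))
  expect_equal(ch$direction == "DOWN", is_down)
})

test_that("peak-gene links respect the inclusive 10 kb boundary", {
  peaks <- tibble::tibble(
    peak_id = "p1", chrom = "chr1", start = 1000, end = 2000
  )
  genes <- tibble::tibble(
    gene_id = c("in_range", "at_boundary", "beyond", "overlapping", "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(11500, 12000, 12001, 1500, 3000),
    end = c(12000, 12500, 13000, 2500, 4000)
  )
  links <- link_peaks_to_genes(peaks, genes, max_distance = 10000)
  expect_setequal(links$gene_id, c("in_range", "at_boundary", "overlapping"))
  expect_equal(links$distance[links$gene_id == "in_range"], 9500)
  expect_equal(links$distance[links$gene_id == "at_boundary"], 10000)
  expect_equal(links$distance[links$gene_id == "overlapping"], 0)
})

test_that("links equal the brute-force all-pairs scan", {
  withr::with_seed(41, {
    peaks <- tibble::tibble(
      peak_id = sprintf("p%02d", 1:40),
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = sample(0:200000, 40)
    )
    peaks$end <- peaks$start + sample(200:2000, 40, replace = TRUE)
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:40),
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = sample(0:200000, 40)
    )
    genes$end <- genes$start + sample(500:3000, 40, replace = TRUE)
  })
  got <- as.data.frame(link_peaks_to_genes(peaks, genes, 10000))
  want <- oracle_links(peaks, genes, 10000)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got$peak_id, want$peak_id)
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$distance, want$distance)
})

test_that("growing the link radius never removes a link", {
  withr::with_seed(43, {
    peaks <- tibble::tibble(
      peak_id = sprintf("p%02d", 1:20), chrom = "chr1",
      start = sample(0:100000, 20)
    )
    peaks$end <- peaks$start + 500
    genes <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
      start = sample(0:100000, 20)
    )
    genes$end <- genes$start + 1000
  })
  key <- function(l) paste(l$peak_id, l$gene_id)
  small <- link_peaks_to_genes(peaks, genes, 5000)
  large <- link_peaks_to_genes(peaks, genes, 20000)
  expect_true(all(key(small) %in% key(large)))
})

test_that("the cluster gene report composes cluster, link and direction", {
  model <- structure(
    list(
      assignments = tibble::tibble(
        peak_id = c("p1", "p2"), origin = c("PEAKS_2_0", "PEAKS_0_5"),
        cluster = c(1L, 2L)
      ),
      k = 2L
    ),
    class = "peak_kmeans"
  )
  selected <- tibble::tibble(
    cluster = 1L, dominant_origin = "PEAKS_2_0", purity = 1, n = 1L
  )
  diff_peaks <- tibble::tibble(
    peak_id = c("p1", "p2"), chrom = "chr1",
    start = c(1000, 50000), end = c(2000, 51000),
    label = c("PEAKS_2_0", "PEAKS_0_5")
  )
  links <- tibble::tibble(
    peak_id = c("p1", "p1", "p2"),
    gene_id = c("gDown", "gUp", "gDown2"),
    distance = c(5000, 100, 200)
  )
  changes <- tibble::tibble(
    gene_id = c("gDown", "gUp", "gDown2"),
    direction = c("DOWN", "UP", "DOWN")
  )
  rep1 <- build_cluster_gene_report(selected, model, diff_peaks, links, changes)
  expect_equal(nrow(rep1), 1L) # gUp filtered out; p2 not in a selected cluster
  expect_equal(rep1$gene_id, "gDown")
  expect_equal(rep1$cluster, 1L)
  expect_equal(rep1$distance, 5000)

  expect_warning(
    rep0 <- build_cluster_gene_report(selected[0, ], model, diff_peaks, links, changes),
    "empty"
  )
  expect_equal(nrow(rep0), 0L)
})
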