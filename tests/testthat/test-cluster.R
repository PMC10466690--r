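make_vectors <- function(x, origin = NULL) {
  colnames(x) <- paste0("motif_", seq_len(ncol(x)) - 1L)
  out <- dplyr::bind_cols(
    tibble::tibble(peak_id = sprintf("p%03d", seq_len(nrow(x)))),
    tibble::as_tibble(x)
  )
  if (!is.null(origin)) out <- dplyr::mutate(out, origin = origin, .after = "peak_id")
  out
}

two_clouds <- function(seed = 1, n = 20, sep = 10) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n * 3, 0, 0.5), ncol = 3)
    b <- matrix(rnorm(n * 3, sep, 0.5), ncol = 3)
  })
  rbind(a, b)
}

test_that("model invariants hold on every fit", {
  x <- two_clouds(5)
  v <- make_vectors(x)
  for (k in c(2, 4)) {
    fit <- fit_kmeans(v, k = k, seed = 3)
    xmat <- as.matrix(v[, -1])
    # centroid = mean of assigned vectors
    for (j in seq_len(k)) {
      idx <- fit$assignments$cluster == j
      if (any(idx)) {
        expect_equal(
          unname(fit$centroids[j, ]),
          unname(colMeans(xmat[idx, , drop = FALSE])),
          tolerance = 1e-9
        )
      }
    }
    # every vector assigned to its nearest centroid
    d2 <- as.matrix(dist(rbind(xmat, fit$centroids)))^2
    d2 <- d2[seq_len(nrow(xmat)), nrow(xmat) + seq_len(k), drop = FALSE]
    nearest <- apply(d2, 1, which.min)
    mine <- d2[cbind(seq_len(nrow(xmat)), fit$assignments$cluster)]
    best <- d2[cbind(seq_len(nrow(xmat)), nearest)]
    expect_equal(mine, best, tolerance = 1e-9)
    # WCSS trace never increases
    expect_true(all(diff(fit$wcss_trace) <= 1e-9))
  }
})

test_that("well-separated clouds recover the exact cloud means", {
  x <- two_clouds(7, n = 25)
  fit <- fit_kmeans(make_vectors(x), k = 2, seed = 1)
  cloud_means <- rbind(colMeans(x[1:25, ]), colMeans(x[26:50, ]))
  got <- fit$centroids[order(fit$centroids[, 1]), ]
  want <- cloud_means[order(cloud_means[, 1]), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
  # WCSS equals the summed within-cloud squared deviations
  wcss_want <- sum(scale(x[1:25, ], scale = FALSE)^2) +
    sum(scale(x[26:50, ], scale = FALSE)^2)
  expect_equal(fit$wcss, wcss_want, tolerance = 1e-9)
})

test_that("k equal to n gives singleton clusters and zero WCSS", {
  x <- two_clouds(9, n = 4)
  fit <- fit_kmeans(make_vectors(x), k = 8, seed = 2)
  expect_equal(fit$wcss, 0, tolerance = 1e-12)
  expect_equal(sort(fit$assignments$cluster), 1:8)
})

test_that("fits are deterministic in the seed and reject degenerate input", {
  v <- make_vectors(two_clouds(11))
  f1 <- fit_kmeans(v, k = 3, seed = 42)
  f2 <- fit_kmeans(v, k = 3, seed = 42)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$centroids, f2$centroids)

  expect_error(fit_kmeans(v[1:2, ], k = 3), "n < k")
  same <- make_vectors(matrix(1, nrow = 5, ncol = 3))
  expect_error(fit_kmeans(same, k = 2), "identical")
})

test_that("the fit matches the reference k-means objective", {
  x <- two_clouds(13, n = 30)
  fit <- fit_kmeans(make_vectors(x), k = 2, seed = 1)
  ref <- withr::with_seed(1, stats::kmeans(x, centers = 2, nstart = 10))
  expect_equal(fit$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("composition counts and proportions are exact", {
  x <- two_clouds(15, n = 10)
  origin <- c(rep("PEAKS_2_0", 10), rep("PEAKS_0_5", 10))
  fit <- fit_kmeans(make_vectors(x, origin), k = 2, seed = 4)
  comp <- cluster_composition(fit)
  expect_equal(nrow(comp), 2L)
  expect_equal(sum(comp$n), 20L)
  nonempty <- comp[comp$n > 0, ]
  expect_equal(nonempty$prop_peaks_2_0 + nonempty$prop_peaks_0_5, rep(1, nrow(nonempty)))
  # perfectly separated clouds with distinct origins: purity 1 each
  expect_setequal(round(nonempty$prop_peaks_2_0, 9), c(0, 1))

  # an empty cluster is reported with n = 0 and undefined proportions
  fit_k3 <- fit_kmeans(make_vectors(x, origin), k = 3, seed = 4)
  comp3 <- cluster_composition(fit_k3)
  expect_equal(nrow(comp3), 3L)
  if (any(comp3$n == 0)) {
    expect_true(all(is.na(comp3$prop_peaks_2_0[comp3$n == 0])))
  }
})

test_that("group-specific cluster selection ranks centroid motifs", {
  x <- two_clouds(17, n = 10)
  origin <- c(rep("PEAKS_2_0", 10), rep("PEAKS_0_5", 10))
  fit <- fit_kmeans(make_vectors(x, origin), k = 2, seed = 4)
  sel <- select_group_specific_clusters(fit, purity_min = 0.9, n_top_motifs = 2)
  expect_equal(nrow(sel), 2L)
  expect_true(all(sel$purity >= 0.9))
  expect_setequal(sel$dominant_origin, c("PEAKS_2_0", "PEAKS_0_5"))

  # hand-built centroid: argmax coordinate wins the top slot
  fit2 <- fit
  fit2$centroids <- matrix(c(0.1, 3.2, 0.0, 3.2, 0.1, 0.0),
    nrow = 2, byrow = TRUE
  )
  fit2$motif_cols <- c("motif_0", "motif_1", "motif_2")
  sel2 <- select_group_specific_clusters(fit2, purity_min = 0, n_top_motifs = 1)
  top <- sel2$top_motifs[[which(sel2$cluster == 1)]]
  expect_equal(top, 1L)

  # purity below the threshold excludes the cluster
  mixed <- fit
  mixed$assignments$origin <- rep(c("PEAKS_2_0", "PEAKS_0_5"), 10) # 50/50
  expect_equal(nrow(select_group_specific_clusters(mixed, purity_min = 0.9)), 0L)
})

test_that("planted motif-usage profiles are recovered at k = 4", {
  # MUT-origin vectors rich in motif A (column 1), CTRL-origin in motif B
  withr::with_seed(23, {
    mut <- cbind(rpois(30, 8), rpois(30, 1), rpois(30, 1))
    ctrl <- cbind(rpois(30, 1), rpois(30, 8), rpois(30, 1))
  })
  v <- make_vectors(
    rbind(mut, ctrl),
    c(rep("PEAKS_2_0", 30), rep("PEAKS_0_5", 30))
  )
  fit <- fit_kmeans(v, k = 4, seed = 6)
  sel <- select_group_specific_clusters(fit, purity_min = 0.9, n_top_motifs = 1)
  for (orig in c("PEAKS_2_0", "PEAKS_0_5")) {
    rows <- sel[sel$dominant_origin == orig, ]
    expect_gte(nrow(rows), 1L)
    planted <- if (orig == "PEAKS_2_0") 0L else 1L
    expect_true(any(vapply(rows$top_motifs, `[[`, integer(1), 1) == planted))
  }
})

test_that("the 2-D embedding satisfies its display contracts", {
  x <- two_clouds(19, n = 15)
  v <- make_vectors(x)
  e1 <- embed_2d(v, seed = 1, n_neighbors = 5)
  expect_equal(nrow(e1), 30L)
  expect_equal(names(e1), c("peak_id", "dim1", "dim2"))
  e2 <- embed_2d(v, seed = 1, n_neighbors = 5)
  expect_identical(e1, e2)

  # duplicated input vectors land on (near-)coincident points
  v_dup <- v
  v_dup[2, -1] <- v_dup[1, -1]
  e3 <- embed_2d(v_dup, seed = 1, n_neighbors = 5)
  diam <- max(dist(as.matrix(e3[, c("dim1", "dim2")])))
  d12 <- sqrt((e3$dim1[1] - e3$dim1[2])^2 + (e3$dim2[1] - e3$dim2[2])^2)
  expect_lt(d12, 1e-6 * diam)

  expect_error(embed_2d(v[1:5, ]), "at least 10")
  expect_warning(embed_2d(v[1:12, ], n_neighbors = 15), "shrink")
})
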