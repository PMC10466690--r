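# k-means clustering of motif-frequency vectors with deterministic
# farthest-point initialization and restarts, cluster-composition analysis
# by peak origin, selection of group-specific clusters, and a 2-D display
# embedding.

vector_matrix <- function(vectors) {
  cols <- grep("^motif_", names(vectors), value = TRUE)
  if (length(cols) == 0L) abort("no motif_ columns in vectors")
  m <- as.matrix(vectors[, cols])
  storage.mode(m) <- "double"
  rownames(m) <- vectors$peak_id
  m
}

# squared Euclidean distances of rows of x to rows of centers
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# deterministic greedy farthest-point seeding: random first centre, then
# repeatedly the point farthest from its nearest chosen centre (ties ->
# lowest index)
farthest_point_init <- function(x, k, seed) {
  n <- nrow(x)
  first <- withr::with_seed(seed, sample.int(n, 1L))
  chosen <- first
  d2 <- dist2_to_centers(x, x[first, , drop = FALSE])[, 1]
  while (length(chosen) < k) {
    nxt <- which.max(d2) # first index on ties
    chosen <- c(chosen, nxt)
    d2 <- pmin(d2, dist2_to_centers(x, x[nxt, , drop = FALSE])[, 1])
  }
  chosen
}

lloyd <- function(x, centers, max_iter = 100L) {
  n <- nrow(x)
  k <- nrow(centers)
  assign_prev <- integer(n)
  wcss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(x, centers)
    assign_cur <- max.col(-d2, ties.method = "first") # nearest, ties -> lowest
    wcss_trace <- c(wcss_trace, sum(d2[cbind(seq_len(n), assign_cur)]))
    # an empty cluster takes the point currently farthest from its centre
    for (j in seq_len(k)) {
      if (!any(assign_cur == j)) {
        far <- which.max(d2[cbind(seq_len(n), assign_cur)])
        assign_cur[far] <- j
      }
    }
    # at convergence the centres are already the means of this assignment
    # and every vector sits with its nearest centre: both invariants hold
    if (identical(assign_cur, assign_prev)) break
    assign_prev <- assign_cur
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(x[assign_cur == j, , drop = FALSE])
    }
  }
  wcss <- sum(dist2_to_centers(x, centers)[cbind(seq_len(n), assign_prev)])
  list(
    assignment = assign_prev, centers = centers, wcss = wcss,
    wcss_trace = wcss_trace, iterations = length(wcss_trace)
  )
}

#' Fit k-means on motif-frequency vectors
#'
#' Lloyd iterations from greedy farthest-point initialization, best of
#' `n_restarts` by within-cluster sum of squares; fully deterministic
#' given `seed`.  Every fit satisfies the centroid-mean and
#' nearest-centroid invariants by construction.
#'
#' @param vectors Frequency-vector tibble from
#'   [build_frequency_vectors()].
#' @param k Number of clusters (default 8).
#' @param seed Integer seed.
#' @param n_restarts Restarts (default 5).
#' @param max_iter Lloyd iteration cap per restart.
#' @param standardize Z-score columns before clustering (default `FALSE`:
#'   per-kb frequencies share units).
#' @return A `peak_kmeans` object: list with `assignments` (tibble:
#'   peak_id, origin, cluster 1..k), `centroids` (k x m matrix), `wcss`,
#'   `wcss_trace`, `k`, `seed`, `iterations`.
#' @export
fit_kmeans <- function(vectors, k = 8L, seed = 1L, n_restarts = 5L,
                       max_iter = 100L, standardize = FALSE) {
  x <- vector_matrix(vectors)
  n <- nrow(x)
  if (n < k) abort("fewer vectors than clusters (n < k)")
  if (all(apply(x, 2, function(col) length(unique(col)) == 1L))) {
    abort("degenerate input: all vectors identical")
  }
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
    x <- matrix(as.numeric(x), nrow = n, dimnames = dimnames(x))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- farthest_point_init(x, k, derive_seed(seed, 1000L + r))
    fit <- lloyd(x, x[init, , drop = FALSE], max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  structure(
    list(
      assignments = tibble(
        peak_id = vectors$peak_id,
        origin = if ("origin" %in% names(vectors)) vectors$origin else NA_character_,
        cluster = best$assignment
      ),
      centroids = best$centers,
      wcss = best$wcss,
      wcss_trace = best$wcss_trace,
      iterations = best$iterations,
      k = as.integer(k), seed = as.integer(seed),
      motif_cols = colnames(x),
      standardized = standardize
    ),
    class = "peak_kmeans"
  )
}

#' @method print peak_kmeans
#' @export
print.peak_kmeans <- function(x, ...) {
  cat("k-means fit on", nrow(x$assignments), "motif-frequency vectors\n")
  cat("  k =", x$k, " WCSS =", format(x$wcss, digits = 6),
    " iterations =", x$iterations, "\n")
  comp <- cluster_composition(x)
  print(comp, n = x$k)
  invisible(x)
}

#' Per-cluster composition by peak origin
#'
#' @param model A `peak_kmeans` fit.
#' @return Tibble with one row per cluster (including empty ones):
#'   `cluster`, `n`, `n_peaks_2_0`, `n_peaks_0_5`, `prop_peaks_2_0`,
#'   `prop_peaks_0_5` (proportions `NA` for empty clusters).
#' @export
cluster_composition <- function(model) {
  stopifnot(inherits(model, "peak_kmeans"))
  a <- model$assignments
  out <- tibble(cluster = seq_len(model$k)) |>
    left_join(
      a |>
        group_by(.data$cluster) |>
        summarise(
          n = dplyr::n(),
          n_peaks_2_0 = sum(.data$origin == "PEAKS_2_0"),
          n_peaks_0_5 = sum(.data$origin == "PEAKS_0_5"),
          .groups = "drop"
        ),
      by = "cluster"
    ) |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_peaks_2_0 = dplyr::coalesce(.data$n_peaks_2_0, 0L),
      n_peaks_0_5 = dplyr::coalesce(.data$n_peaks_0_5, 0L),
      prop_peaks_2_0 = ifelse(.data$n > 0, .data$n_peaks_2_0 / .data$n, NA_real_),
      prop_peaks_0_5 = ifelse(.data$n > 0, .data$n_peaks_0_5 / .data$n, NA_real_)
    )
  out
}

#' Select group-specific clusters and their top centroid motifs
#'
#' Clusters whose proportion of one origin reaches `purity_min` are
#' selected; per selected cluster the motifs are ranked by centroid
#' coordinate (descending, ties to the lower motif id).
#'
#' @param model A `peak_kmeans` fit.
#' @param composition Optional precomputed [cluster_composition()].
#' @param purity_min Minimum origin proportion (default 0.9; use 1 for
#'   strictly pure clusters).
#' @param n_top_motifs Number of top centroid motifs to report.
#' @return Tibble: `cluster`, `dominant_origin`, `purity`, `n`,
#'   `top_motifs` (list column of 0-based motif ids).
#' @export
select_group_specific_clusters <- function(model, composition = NULL,
                                           purity_min = 0.9, n_top_motifs = 3L) {
  stopifnot(inherits(model, "peak_kmeans"))
  comp <- composition %||% cluster_composition(model)
  comp <- filter(comp, .data$n > 0L)
  dominant <- ifelse(comp$prop_peaks_2_0 >= comp$prop_peaks_0_5,
    "PEAKS_2_0", "PEAKS_0_5"
  )
  purity <- pmax(comp$prop_peaks_2_0, comp$prop_peaks_0_5)
  sel <- which(purity >= purity_min)
  motif_ids <- as.integer(sub("^motif_", "", model$motif_cols))
  top <- lapply(sel, function(i) {
    ctr <- model$centroids[comp$cluster[i], ]
    ord <- order(-ctr, motif_ids)
    motif_ids[ord][seq_len(min(n_top_motifs, length(ord)))]
  })
  tibble(
    cluster = comp$cluster[sel],
    dominant_origin = dominant[sel],
    purity = purity[sel],
    n = comp$n[sel],
    top_motifs = top
  )
}

#' 2-D spectral display embedding of frequency vectors
#'
#' A Laplacian-eigenmap neighbor embedding: a Gaussian-weighted symmetric
#' k-nearest-neighbor graph is built on Euclidean distances with locally
#' scaled bandwidths, and the two eigenvectors of the normalized graph
#' Laplacian next to the trivial one give the coordinates.  The embedding
#' is display-only (coordinates carry no downstream semantics), fully
#' deterministic, and maps duplicate input vectors to coincident points.
#'
#' @param vectors Frequency-vector tibble.
#' @param seed Accepted for interface symmetry; the embedding is
#'   deterministic and does not consume randomness.
#' @param n_neighbors Neighborhood size (default 15; auto-shrunk with a
#'   warning when fewer vectors are available).
#' @return Tibble: `peak_id`, `origin` (if present), `dim1`, `dim2`.
#' @export
embed_2d <- function(vectors, seed = 1L, n_neighbors = 15L) {
  x <- vector_matrix(vectors)
  n <- nrow(x)
  if (n < 10L) abort("need at least 10 vectors to embed")
  if (n_neighbors >= n) {
    warn("n_neighbors >= number of vectors; shrinking")
    n_neighbors <- n - 1L
  }
  d <- as.matrix(dist(x))
  # locally scaled Gaussian affinities over the kNN graph
  sigma <- apply(d, 1, function(r) sort(r)[n_neighbors + 1L]) # incl. self at 0
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  w <- exp(-d^2 / outer(sigma, sigma))
  diag(w) <- 0
  # keep only kNN edges, symmetrized
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(n_neighbors + 1L)]
    keep[i, nb] <- TRUE
  }
  keep <- keep | t(keep)
  w[!keep] <- 0
  deg <- rowSums(w)
  deg[deg == 0] <- 1
  dhalf <- 1 / sqrt(deg)
  lsym <- diag(n) - (dhalf * w) %*% diag(dhalf)
  eg <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  # smallest eigenvalues last; skip the trivial constant eigenvector
  vecs <- eg$vectors[, c(n - 1L, n - 2L), drop = FALSE]
  coords <- vecs * dhalf
  # deterministic sign convention
  for (j in 1:2) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s != 0) coords[, j] <- coords[, j] * s
  }
  out <- tibble(
    peak_id = vectors$peak_id,
    dim1 = coords[, 1], dim2 = coords[, 2]
  )
  if ("origin" %in% names(vectors)) {
    out <- mutate(out, origin = vectors$origin, .after = "peak_id")
  }
  out
}
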