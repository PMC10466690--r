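# broom-style accessors and ggplot2 displays for fitted objects.

#' Tidy a peak k-means fit
#'
#' One row per cluster with size and the centroid coordinates.
#'
#' @param x A `peak_kmeans` fit.
#' @param ... Unused.
#' @return A tibble with columns `cluster`, `size` and one column per
#'   motif.
#' @method tidy peak_kmeans
#' @export
tidy.peak_kmeans <- function(x, ...) {
  a <- x$assignments
  ctr <- as_tibble(x$centroids)
  names(ctr) <- x$motif_cols
  dplyr::bind_cols(
    tibble(
      cluster = seq_len(x$k),
      size = vapply(seq_len(x$k), function(j) sum(a$cluster == j), integer(1))
    ),
    ctr
  )
}

#' Glance at a peak k-means fit
#'
#' @param x A `peak_kmeans` fit.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n`, `tot_withinss`, `iterations`.
#' @method glance peak_kmeans
#' @export
glance.peak_kmeans <- function(x, ...) {
  tibble(
    k = x$k, n = nrow(x$assignments),
    tot_withinss = x$wcss, iterations = x$iterations
  )
}

#' Augment frequency vectors with cluster assignments
#'
#' @param x A `peak_kmeans` fit.
#' @param data The frequency-vector tibble the model was fitted on.
#' @param ... Unused.
#' @return `data` with a `.cluster` column.
#' @method augment peak_kmeans
#' @export
augment.peak_kmeans <- function(x, data, ...) {
  mutate(data, .cluster = x$assignments$cluster[match(
    data$peak_id, x$assignments$peak_id
  )])
}

#' Centroid motif-frequency profiles, one line per cluster
#'
#' The line-chart view of the fitted centroids: motif index on the x axis,
#' per-kb occurrence frequency on the y axis.
#'
#' @param object A `peak_kmeans` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_kmeans
#' @export
autoplot.peak_kmeans <- function(object, ...) {
  ctr <- as_tibble(object$centroids)
  names(ctr) <- object$motif_cols
  df <- ctr |>
    mutate(cluster = factor(seq_len(object$k))) |>
    pivot_longer(-"cluster", names_to = "motif", values_to = "frequency") |>
    mutate(motif_id = as.integer(sub("^motif_", "", .data$motif)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$motif_id, y = .data$frequency,
    colour = .data$cluster, group = .data$cluster
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "motif index", y = "occurrences / kb",
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Stacked-bar view of cluster composition by peak origin
#'
#' @param composition Output of [cluster_composition()].
#' @return A ggplot object.
#' @export
plot_cluster_composition <- function(composition) {
  df <- composition |>
    filter(.data$n > 0L) |>
    select("cluster", "n_peaks_2_0", "n_peaks_0_5") |>
    pivot_longer(-"cluster", names_to = "origin", values_to = "count") |>
    mutate(origin = ifelse(.data$origin == "n_peaks_2_0", "Peaks_2.0", "Peaks_0.5"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$cluster), y = .data$count, fill = .data$origin
  )) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_fill_manual(values = c(Peaks_2.0 = "#E69F00", Peaks_0.5 = "#56B4E9")) +
    ggplot2::labs(x = "cluster", y = "proportion", fill = "peak origin") +
    ggplot2::theme_minimal()
}

#' Scatter plot of the 2-D embedding
#'
#' @param embedding Output of [embed_2d()].
#' @param model Optional `peak_kmeans` fit to colour points by cluster;
#'   otherwise points are coloured by origin when available.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, model = NULL) {
  df <- embedding
  if (!is.null(model)) {
    df <- mutate(df, cluster = factor(model$assignments$cluster[match(
      df$peak_id, model$assignments$peak_id
    )]))
    aes <- ggplot2::aes(.data$dim1, .data$dim2, colour = .data$cluster)
  } else if ("origin" %in% names(df)) {
    aes <- ggplot2::aes(.data$dim1, .data$dim2, colour = .data$origin)
  } else {
    aes <- ggplot2::aes(.data$dim1, .data$dim2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Depth tracks and called peaks over a genomic window
#'
#' @param depth Depth table (`sample`, `group`, `chrom`, `bin`, `depth`).
#' @param peaks Optional peak tibble to overlay.
#' @param chrom Chromosome to display.
#' @param from,to Window in bp.
#' @return A ggplot object.
#' @export
plot_depth_region <- function(depth, peaks = NULL, chrom, from = 0, to = Inf) {
  bs <- bin_size_of(depth)
  df <- depth |>
    filter(.data$chrom == !!chrom, .data$bin * bs >= from, .data$bin * bs < to) |>
    mutate(pos = .data$bin * bs)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    .data$pos, .data$depth,
    colour = .data$group, group = .data$sample
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"), y = "read depth") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    pk <- filter(peaks, .data$chrom == !!chrom, .data$end >= from, .data$start < to)
    if (nrow(pk) > 0L) {
      p <- p + ggplot2::annotate("rect",
        xmin = pk$start, xmax = pk$end, ymin = -Inf, ymax = Inf,
        alpha = 0.15, fill = "grey40"
      )
    }
  }
  p
}
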