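# Expression integration: FPKM fold-change filtering, peak-to-gene linking
# within a distance window, and the cluster-linked regulated-gene report.

#' Compute per-gene fold changes and regulation directions
#'
#' Ratios are (mutant + pseudocount) / (control + pseudocount) per mutant
#' line, with the control value the mean over control samples.  A gene is
#' `DOWN` when its control FPKM exceeds `control_min_fpkm` and the ratio
#' is at most `down_max_ratio` in every mutant line; `UP` when the ratio
#' is at least `up_min_ratio` in every line; otherwise `NONE`.
#'
#' @param fpkm Long FPKM tibble (`gene_id`, `sample`, `group`, `fpkm`).
#' @param pseudocount Added to both sides of each ratio (default 0.1 FPKM;
#'   guards zero division, negligible above the control gate).
#' @param control_min_fpkm Control-expression gate for DOWN calls
#'   (default 10).
#' @param down_max_ratio All-line ratio ceiling for DOWN (default 0.5).
#' @param up_min_ratio All-line ratio floor for UP (default 2).
#' @return Tibble: `gene_id`, `control_fpkm`, one `ratio_<sample>` column
#'   per mutant line, `min_ratio`, `max_ratio`, `direction`.
#' @export
compute_fold_changes <- function(fpkm, pseudocount = 0.1,
                                 control_min_fpkm = 10,
                                 down_max_ratio = 0.5, up_min_ratio = 2) {
  stopifnot(all(c("gene_id", "sample", "group", "fpkm") %in% names(fpkm)))
  mut_samples <- unique(fpkm$sample[fpkm$group == "mutant"])
  if (length(mut_samples) < 1L) abort("need at least one mutant line")
  ctrl <- fpkm |>
    filter(.data$group == "control") |>
    group_by(.data$gene_id) |>
    summarise(control_fpkm = mean(.data$fpkm), .groups = "drop")
  ratios <- fpkm |>
    filter(.data$group == "mutant") |>
    left_join(ctrl, by = "gene_id") |>
    mutate(ratio = (.data$fpkm + pseudocount) / (.data$control_fpkm + pseudocount)) |>
    select("gene_id", "sample", "ratio") |>
    pivot_wider(names_from = "sample", values_from = "ratio", names_prefix = "ratio_")
  ratio_cols <- paste0("ratio_", mut_samples)
  out <- left_join(ctrl, ratios, by = "gene_id")
  rmat <- as.matrix(out[, ratio_cols])
  out$min_ratio <- apply(rmat, 1, min)
  out$max_ratio <- apply(rmat, 1, max)
  is_down <- out$control_fpkm > control_min_fpkm & out$max_ratio <= down_max_ratio
  is_up <- out$min_ratio >= up_min_ratio
  out$direction <- dplyr::case_when(
    is_down ~ "DOWN", is_up ~ "UP", .default = "NONE"
  )
  out
}

#' Link peaks to genes within a distance window
#'
#' All (peak, gene) pairs on the same chromosome whose edge-to-edge gap is
#' at most `max_distance` (inclusive); overlapping intervals link at
#' distance 0.  Distances are measured to the gene body.
#'
#' @param peaks Peak tibble with `peak_id`, `chrom`, `start`, `end`
#'   (bp, 0-based half-open).
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param max_distance Maximum gap in bp (default 10000, inclusive).
#' @return Tibble: `peak_id`, `gene_id`, `distance`.
#' @export
link_peaks_to_genes <- function(peaks, genes, max_distance = 10000) {
  if (nrow(peaks) == 0L || nrow(genes) == 0L) {
    return(tibble(peak_id = character(), gene_id = character(), distance = numeric()))
  }
  pgr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  )
  hits <- GenomicRanges::findOverlaps(pgr, ggr,
    maxgap = max_distance, ignore.strand = TRUE
  )
  d <- GenomicRanges::distance(
    pgr[S4Vectors::queryHits(hits)], ggr[S4Vectors::subjectHits(hits)]
  )
  keep <- !is.na(d) & d <= max_distance
  tibble(
    peak_id = peaks$peak_id[S4Vectors::queryHits(hits)[keep]],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)[keep]],
    distance = as.numeric(d[keep])
  ) |>
    arrange(.data$peak_id, .data$gene_id)
}

#' Regulated genes near peaks of group-specific clusters
#'
#' Rows are genes with the requested regulation direction linked (within
#' the distance window already applied in `links`) to peaks whose
#' frequency vectors belong to a selected cluster.  The same gene reached
#' via several peaks yields several rows.
#'
#' @param selected Selected clusters from
#'   [select_group_specific_clusters()].
#' @param model The `peak_kmeans` fit (provides peak -> cluster).
#' @param diff_peaks Classified peak tibble (provides coordinates).
#' @param links Peak-gene links from [link_peaks_to_genes()].
#' @param changes Fold-change table from [compute_fold_changes()].
#' @param direction Direction filter (default `"DOWN"`).
#' @return Tibble: `cluster`, `dominant_origin`, `peak_id`, `chrom`,
#'   `peak_start`, `peak_end`, `gene_id`, `direction`, `distance`, sorted
#'   by (cluster, chrom, peak start).
#' @export
build_cluster_gene_report <- function(selected, model, diff_peaks, links,
                                      changes, direction = "DOWN") {
  empty <- tibble(
    cluster = integer(), dominant_origin = character(),
    peak_id = character(), chrom = character(), peak_start = numeric(),
    peak_end = numeric(), gene_id = character(), direction = character(),
    distance = numeric()
  )
  if (nrow(selected) == 0L) {
    warn("no selected clusters; report is empty")
    return(empty)
  }
  member <- model$assignments |>
    filter(.data$cluster %in% selected$cluster) |>
    left_join(
      selected[, c("cluster", "dominant_origin")],
      by = "cluster"
    )
  genes_dir <- filter(changes, .data$direction == !!direction)
  out <- member |>
    dplyr::inner_join(links, by = "peak_id", relationship = "many-to-many") |>
    dplyr::inner_join(genes_dir[, c("gene_id", "direction")], by = "gene_id") |>
    left_join(
      diff_peaks[, c("peak_id", "chrom", "start", "end")],
      by = "peak_id"
    ) |>
    rename(peak_start = "start", peak_end = "end") |>
    select(
      "cluster", "dominant_origin", "peak_id", "chrom", "peak_start",
      "peak_end", "gene_id", "direction", "distance"
    ) |>
    arrange(.data$cluster, .data$chrom, .data$peak_start, .data$gene_id)
  out
}
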