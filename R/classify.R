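# Differential classification: compare mean unsmoothed depths over each
# peak interval between the control and mutant groups and label peaks
# PEAKS_2_0 (control below half the mutant depth), PEAKS_0_5 (control
# above twice the mutant depth) or UNCHANGED.

#' Mean group depth over peak intervals
#'
#' For each peak, the mean over bins `[start_bin, end_bin]` of the per-bin
#' mean across the group's samples, computed on the unsmoothed depth.
#'
#' @param peaks Peak tibble with `chrom`, `start_bin`, `end_bin`.
#' @param depth Depth table (`sample`, `group`, `chrom`, `bin`, `depth`).
#' @param group Group label to average over (`"control"` or `"mutant"`).
#' @return Numeric vector, one mean depth per peak.
#' @export
group_mean_depth <- function(peaks, depth, group) {
  check_depth_tibble(depth)
  gd <- depth |>
    filter(.data$group == !!group) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(depth = mean(.data$depth), .groups = "drop")
  if (nrow(gd) == 0L) abort(paste0("no samples in group '", group, "'"))
  interval_means(peaks, gd)
}

# mean of a per-bin signal over [start_bin, end_bin] per peak, via prefix
# sums per chromosome; errors if a peak leaves the track
interval_means <- function(peaks, signal) {
  out <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    v <- arrange(filter(signal, .data$chrom == ch), .data$bin)
    if (nrow(v) == 0L) abort(paste0("no depth data for chromosome ", ch))
    if (!identical(v$bin, seq_len(nrow(v)) - 1L) &&
      !identical(as.integer(v$bin), seq_len(nrow(v)) - 1L)) {
      abort("depth bins must be contiguous from 0")
    }
    cs <- c(0, cumsum(v$depth))
    idx <- which(peaks$chrom == ch)
    s <- peaks$start_bin[idx] + 1L
    e <- peaks$end_bin[idx] + 1L
    if (any(s < 1L) || any(e > nrow(v))) abort("peak outside track bounds")
    out[idx] <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
  }
  out
}

#' Classify peaks as Peaks_2.0 / Peaks_0.5 / unchanged
#'
#' Labels follow strict inequalities on group mean depths over the peak
#' interval: `PEAKS_2_0` when the control mean is below half the mutant
#' mean, `PEAKS_0_5` when it is above twice the mutant mean, otherwise
#' `UNCHANGED`.  Both means zero yields `UNCHANGED` (no division is
#' performed anywhere).
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param depth Depth table with `group` in `c("control", "mutant")`.
#' @param all_lines If `TRUE`, the inequality must hold against every
#'   mutant sample individually rather than the pooled mutant mean.
#' @return `peaks` with columns `dp_ctrl`, `dp_mut` and `label` added.
#' @export
classify_peaks <- function(peaks, depth, all_lines = FALSE) {
  check_depth_tibble(depth)
  if (!all(c("control", "mutant") %in% depth$group)) {
    abort("depth must contain both a control and a mutant group")
  }
  dp_ctrl <- group_mean_depth(peaks, depth, "control")
  dp_mut <- group_mean_depth(peaks, depth, "mutant")
  if (all_lines) {
    mut_samples <- unique(depth$sample[depth$group == "mutant"])
    per_line <- vapply(mut_samples, function(s) {
      interval_means(peaks, filter(depth, .data$sample == !!s))
    }, numeric(nrow(peaks)))
    per_line <- matrix(per_line, nrow = nrow(peaks))
    lab_20 <- vapply(seq_len(nrow(peaks)), function(i) {
      all(dp_ctrl[i] < 0.5 * per_line[i, ])
    }, logical(1))
    lab_05 <- vapply(seq_len(nrow(peaks)), function(i) {
      all(dp_ctrl[i] > 2 * per_line[i, ])
    }, logical(1))
  } else {
    lab_20 <- dp_ctrl < 0.5 * dp_mut
    lab_05 <- dp_ctrl > 2 * dp_mut
  }
  label <- dplyr::case_when(lab_20 ~ "PEAKS_2_0", lab_05 ~ "PEAKS_0_5",
    .default = "UNCHANGED"
  )
  out <- mutate(peaks, dp_ctrl = dp_ctrl, dp_mut = dp_mut, label = label)
  bs <- attr(peaks, "bin_size", exact = TRUE)
  if (!is.null(bs)) out <- set_bin_size(out, bs)
  out
}
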