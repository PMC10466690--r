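# The landmark-based peak caller: moving-average smoothing, landmark
# detection (minima / maxima / two-fold slope changes), exhaustive
# (start, apex, end) candidate enumeration, and filtering on
# baseline-relative maximum and integrated excess depth.

#' Peak-caller parameters
#'
#' @param window_bins Moving-average window in bins (odd, >= 1).
#' @param slope_factor Slope-change landmark threshold: consecutive
#'   same-sign first differences whose ratio exceeds this factor (or its
#'   reciprocal) mark a landmark.  Default 2 (a two-fold change).
#' @param max_excess_min Minimum baseline-relative maximum depth; strict
#'   (`>`), default 2.5 depth units.
#' @param area_min Minimum integrated excess depth over the candidate
#'   interval; strict (`>`), default 5.0 depth x bins.
#' @param max_width_bins Maximum candidate width considered by
#'   [call_peaks()] (default 500 bins; [enumerate_candidates()] itself is
#'   exhaustive and unaffected).
#' @param baseline_relative If `FALSE`, `max_excess_min` is applied to the
#'   raw smoothed apex depth instead of the baseline-subtracted excess.
#' @return A `peak_params` list.
#' @export
peak_params <- function(window_bins = 5L, slope_factor = 2, max_excess_min = 2.5,
                        area_min = 5, max_width_bins = 500L,
                        baseline_relative = TRUE) {
  window_bins <- as.integer(window_bins)
  if (window_bins < 1L || window_bins %% 2L == 0L) {
    stop_config("window_bins must be an odd integer >= 1")
  }
  if (slope_factor <= 1) stop_config("slope_factor must be > 1")
  if (max_excess_min <= 0 || area_min <= 0) stop_config("thresholds must be > 0")
  structure(
    list(
      window_bins = window_bins, slope_factor = slope_factor,
      max_excess_min = max_excess_min, area_min = area_min,
      max_width_bins = as.integer(max_width_bins),
      baseline_relative = isTRUE(baseline_relative)
    ),
    class = "peak_params"
  )
}

# centred moving average with shrinking windows at the edges; O(n)
moving_average <- function(x, window_bins) {
  n <- length(x)
  if (window_bins > n) abort("window longer than track")
  if (window_bins == 1L) return(x)
  h <- (window_bins - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a depth track with a centred moving average
#'
#' Edge bins use shrinking windows (the mean over the available bins), so
#' the output length equals the input length.
#'
#' @param track Depth track tibble (`chrom`, `bin`, `depth`; a `sample`
#'   column, if present, is smoothed independently).
#' @param window_bins Odd window width in bins.
#' @return The track with `depth` replaced by the smoothed signal.
#' @export
smooth_track <- function(track, window_bins = 5L) {
  check_depth_tibble(track)
  window_bins <- as.integer(window_bins)
  if (window_bins %% 2L == 0L) stop_config("window_bins must be odd")
  keys <- intersect(c("sample", "chrom"), names(track))
  out <- track |>
    group_by(across(all_of(keys))) |>
    arrange(.data$bin, .by_group = TRUE) |>
    mutate(depth = moving_average(.data$depth, window_bins)) |>
    ungroup()
  bs <- attr(track, "bin_size", exact = TRUE)
  if (!is.null(bs)) out <- set_bin_size(out, bs)
  out
}

# landmark detection on one numeric vector; returns tibble(bin, kind)
# with 0-based bins.  Plateau runs give one extremum at the (left-)centre;
# track ends always count as MINIMUM and additionally as a one-sided
# extremum when strictly above/below the adjacent run.
landmarks_vector <- function(d, slope_factor = 2) {
  n <- length(d)
  out_bin <- integer(0)
  out_kind <- character(0)
  if (n >= 1L) {
    r <- rle(d)
    k <- length(r$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    centers <- (starts + ends) %/% 2L # left-centre on even runs
    if (k >= 3L) {
      v <- r$values
      j <- 2L:(k - 1L)
      is_max <- v[j] > v[j - 1L] & v[j] > v[j + 1L]
      is_min <- v[j] < v[j - 1L] & v[j] < v[j + 1L]
      out_bin <- c(centers[j][is_max], centers[j][is_min])
      out_kind <- c(
        rep("MAXIMUM", sum(is_max)), rep("MINIMUM", sum(is_min))
      )
    }
    if (k >= 2L) {
      # boundary runs: one-sided extremum placed at the track end itself
      if (r$values[1L] > r$values[2L]) {
        out_bin <- c(out_bin, 1L); out_kind <- c(out_kind, "MAXIMUM")
      }
      if (r$values[k] > r$values[k - 1L]) {
        out_bin <- c(out_bin, n); out_kind <- c(out_kind, "MAXIMUM")
      }
    }
    # track ends are always MINIMUM landmarks (peaks may be truncated)
    out_bin <- c(out_bin, 1L, n)
    out_kind <- c(out_kind, "MINIMUM", "MINIMUM")
  }
  # slope changes: consecutive nonzero same-sign diffs with ratio beyond
  # the factor; zero slopes break eligibility
  if (n >= 3L) {
    s <- diff(d)
    s_prev <- s[-length(s)] # diff into bin i
    s_next <- s[-1L] # diff out of bin i
    elig <- s_prev != 0 & s_next != 0 & sign(s_prev) == sign(s_next)
    ratio <- abs(s_next) / abs(s_prev)
    hit <- elig & (ratio > slope_factor | ratio < 1 / slope_factor)
    idx <- which(hit) + 1L # 1-based bin index of the joint
    out_bin <- c(out_bin, idx)
    out_kind <- c(out_kind, rep("SLOPE_CHANGE", length(idx)))
  }
  out <- tibble(bin = out_bin - 1L, kind = out_kind)
  out <- distinct(arrange(out, .data$bin, .data$kind))
  out
}

#' Detect minima, maxima and slope-change landmarks on a smoothed track
#'
#' @param smoothed A smoothed depth track tibble.
#' @param params A [peak_params()] (only `slope_factor` is used).
#' @return Tibble with columns `chrom`, `bin`, `kind`
#'   (`MINIMUM`/`MAXIMUM`/`SLOPE_CHANGE`), sorted by position; several
#'   kinds may coexist at one bin.
#' @export
detect_landmarks <- function(smoothed, params = peak_params()) {
  check_depth_tibble(smoothed)
  smoothed |>
    group_by(.data$chrom) |>
    arrange(.data$bin, .by_group = TRUE) |>
    dplyr::group_modify(~ landmarks_vector(.x$depth, params$slope_factor)) |>
    ungroup()
}

# exact candidate statistics for one (s, a, e) triple on vector d (1-based)
candidate_stats <- function(d, s, a, e) {
  b <- (d[s] + d[e]) / 2
  seg <- d[s:e]
  list(
    baseline = b,
    max_excess = d[a] - b,
    net_excess = sum(seg) - b * length(seg),
    integrated_excess = sum(pmax(0, seg - b))
  )
}

# nearest strictly-greater element to the left/right of each position;
# returns 0 / n+1 when none exists.  Monotonic-stack scan, O(n).
nearest_greater <- function(d) {
  n <- length(d)
  left <- integer(n)
  stack <- integer(n)
  sp <- 0L
  for (i in seq_len(n)) {
    while (sp > 0L && d[stack[sp]] <= d[i]) sp <- sp - 1L
    left[i] <- if (sp > 0L) stack[sp] else 0L
    sp <- sp + 1L
    stack[sp] <- i
  }
  right <- integer(n)
  sp <- 0L
  for (i in rev(seq_len(n))) {
    while (sp > 0L && d[stack[sp]] <= d[i]) sp <- sp - 1L
    right[i] <- if (sp > 0L) stack[sp] else n + 1L
    sp <- sp + 1L
    stack[sp] <- i
  }
  list(left = left, right = right)
}

# all admissible (s, a, e) triples for one chromosome.  Admissibility:
# a is a MAXIMUM landmark, s and e are MINIMUM or SLOPE_CHANGE landmarks,
# s < a < e, and the smoothed depth attains its interval maximum at a
# (equivalently: no bin in (s, e) exceeds depth[a]).
enumerate_vector <- function(d, lm, exhaustive_stats = TRUE) {
  apexes <- sort(unique(lm$bin[lm$kind == "MAXIMUM"])) + 1L # to 1-based
  epts <- sort(unique(lm$bin[lm$kind %in% c("MINIMUM", "SLOPE_CHANGE")])) + 1L
  if (length(apexes) == 0L || length(epts) < 2L) {
    return(empty_candidates())
  }
  ng <- nearest_greater(d)
  cs <- c(0, cumsum(d))
  rows <- vector("list", length(apexes))
  for (ai in seq_along(apexes)) {
    a <- apexes[ai]
    lo <- ng$left[a] # s must be > lo is wrong: s may sit ON the greater bin?
    hi <- ng$right[a]
    # bins in (lo, hi) all have depth <= d[a]; s,e outside would admit a
    # larger interior value, so restrict to [lo+1, hi-1] minus the apex.
    ss <- epts[epts > lo & epts < a]
    ee <- epts[epts > a & epts < hi]
    if (length(ss) == 0L || length(ee) == 0L) next
    grid_s <- rep(ss, times = length(ee))
    grid_e <- rep(ee, each = length(ss))
    b <- (d[grid_s] + d[grid_e]) / 2
    w <- grid_e - grid_s + 1L
    net <- (cs[grid_e + 1L] - cs[grid_s]) - b * w
    rows[[ai]] <- tibble(
      start_bin = grid_s - 1L, apex_bin = a - 1L, end_bin = grid_e - 1L,
      baseline = b, max_excess = d[a] - b, net_excess = net,
      width_bins = as.integer(w)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(empty_candidates())
  if (exhaustive_stats) {
    out$integrated_excess <- vapply(seq_len(nrow(out)), function(i) {
      seg <- d[(out$start_bin[i] + 1L):(out$end_bin[i] + 1L)]
      sum(pmax(0, seg - out$baseline[i]))
    }, numeric(1))
  }
  out
}

empty_candidates <- function() {
  tibble(
    start_bin = integer(), apex_bin = integer(), end_bin = integer(),
    baseline = numeric(), max_excess = numeric(), net_excess = numeric(),
    width_bins = integer(), integrated_excess = numeric()
  )
}

#' Exhaustively enumerate peak candidates from landmarks
#'
#' Every (start, apex, end) combination with the apex a MAXIMUM landmark,
#' the endpoints MINIMUM or SLOPE_CHANGE landmarks, start < apex < end,
#' and the smoothed depth attaining its interval maximum at the apex.
#' The baseline is the mean smoothed depth at the two endpoints;
#' `max_excess` is the apex depth above baseline and `integrated_excess`
#' the sum of positive baseline-subtracted depth over the interval.
#'
#' @param smoothed Smoothed depth track tibble.
#' @param landmarks Landmarks from [detect_landmarks()] on the same track.
#' @return Tibble of candidates with columns `chrom`, `start_bin`,
#'   `apex_bin`, `end_bin`, `baseline`, `max_excess`, `net_excess`,
#'   `width_bins`, `integrated_excess`.
#' @export
enumerate_candidates <- function(smoothed, landmarks) {
  check_depth_tibble(smoothed)
  chroms <- unique(smoothed$chrom)
  out <- bind_rows(lapply(chroms, function(ch) {
    d <- arrange(filter(smoothed, .data$chrom == ch), .data$bin)$depth
    lm <- filter(landmarks, .data$chrom == ch)
    cc <- enumerate_vector(d, lm)
    if (nrow(cc) > 0L) mutate(cc, chrom = ch, .before = 1) else cc
  }))
  if (nrow(out) == 0L) {
    return(mutate(empty_candidates(), chrom = character(), .before = 1))
  }
  out
}

#' Filter peak candidates on excess-depth thresholds
#'
#' Keeps candidates with `max_excess` strictly above `max_excess_min` and
#' `integrated_excess` strictly above `area_min`, then (optionally)
#' deduplicates per apex: among candidates sharing an apex the one with the
#' largest net excess per square-root width (a matched-filter score) is
#' kept; ties go to the wider, then the leftmost candidate.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param params A [peak_params()].
#' @param dedup Apply per-apex deduplication (default `TRUE`).
#' @return Filtered candidate tibble sorted by (chrom, start).
#' @export
filter_candidates <- function(candidates, params = peak_params(), dedup = TRUE) {
  if (nrow(candidates) == 0L) return(candidates)
  score_max <- if (params$baseline_relative) {
    candidates$max_excess
  } else {
    candidates$max_excess + candidates$baseline
  }
  keep <- score_max > params$max_excess_min &
    candidates$integrated_excess > params$area_min
  out <- candidates[keep, , drop = FALSE]
  if (dedup && nrow(out) > 0L) {
    out <- out |>
      mutate(.score = .data$net_excess / sqrt(.data$width_bins)) |>
      group_by(.data$chrom, .data$apex_bin) |>
      arrange(desc(.data$.score), desc(.data$width_bins), .data$start_bin,
        .by_group = TRUE
      ) |>
      dplyr::slice_head(n = 1L) |>
      ungroup() |>
      select(-".score")
  }
  arrange(out, .data$chrom, .data$start_bin, .data$end_bin, .data$apex_bin)
}

#' Call peaks on a multi-sample depth table
#'
#' Detection runs on the mean depth across all samples of both groups:
#' the track is smoothed, landmarks detected, and for each apex the best
#' admissible (start, end) pair under the matched-filter score is selected
#' among endpoint landmarks within `max_width_bins`, subject to the
#' excess-depth filters.  Equivalent to
#' `enumerate_candidates() |> filter_candidates()` restricted to
#' `max_width_bins`, computed without materializing all candidates.
#'
#' @param depth Depth table (`sample`, `group`, `chrom`, `bin`, `depth`)
#'   with a `bin_size` attribute.
#' @param params A [peak_params()].
#' @return Tibble of peaks: `peak_id`, `chrom`, `start_bin`, `apex_bin`,
#'   `end_bin`, `start`, `end` (bp, 0-based half-open), `baseline`,
#'   `max_excess`, `integrated_excess`, with a `bin_size` attribute.
#' @export
call_peaks <- function(depth, params = peak_params()) {
  check_depth_tibble(depth)
  bs <- bin_size_of(depth)
  if (!"sample" %in% names(depth)) depth$sample <- "s1"
  n_by <- depth |>
    group_by(.data$sample, .data$chrom) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "n")
  counts <- as.matrix(n_by[, -1, drop = FALSE])
  if (any(is.na(counts)) || any(counts != counts[, 1])) {
    abort("inconsistent binning: samples cover different bins")
  }
  out <- bind_rows(lapply(unique(depth$chrom), function(ch) {
    sub <- depth[depth$chrom == ch, c("sample", "bin", "depth")]
    sub <- sub[order(sub$sample, sub$bin), ]
    ns <- length(unique(sub$sample))
    m <- matrix(sub$depth, ncol = ns)
    bins <- matrix(sub$bin, ncol = ns)
    if (ns > 1L && !identical(bins[, 1], bins[, ns])) {
      abort("inconsistent binning: samples cover different bins")
    }
    d0 <- rowMeans(m)[order(bins[, 1])]
    d <- moving_average(d0, params$window_bins)
    lm <- landmarks_vector(d, params$slope_factor)
    pk <- best_candidates_vector(d, lm, params)
    if (nrow(pk) > 0L) mutate(pk, chrom = ch, .before = 1) else pk
  }))
  if (nrow(out) == 0L) {
    out <- mutate(empty_candidates(), chrom = character(), .before = 1)
  }
  out <- suppress_overlapping_peaks(out)
  out <- out |>
    arrange(.data$chrom, .data$start_bin) |>
    mutate(
      start = .data$start_bin * bs,
      end = (.data$end_bin + 1L) * bs,
      peak_id = sprintf("peak_%05d", row_number())
    ) |>
    select(
      "peak_id", "chrom", "start_bin", "apex_bin", "end_bin", "start", "end",
      "baseline", "max_excess", "net_excess", "width_bins", "integrated_excess"
    )
  set_bin_size(out, bs)
}

# greedy non-maximum suppression: secondary apexes on a peak's flank
# survive per-apex deduplication as nested sub-peaks, so peaks whose
# interval overlaps a higher-scoring kept peak by at least half the
# shorter interval are dropped (one summit per region).
suppress_overlapping_peaks <- function(peaks, min_frac = 0.5) {
  if (nrow(peaks) <= 1L) return(peaks)
  score <- peaks$net_excess / sqrt(peaks$width_bins)
  keep <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    ord <- idx[order(-score[idx], -peaks$width_bins[idx], peaks$start_bin[idx])]
    kept_s <- integer(0)
    kept_e <- integer(0)
    for (i in ord) {
      ov <- pmin(peaks$end_bin[i], kept_e) - pmax(peaks$start_bin[i], kept_s) + 1L
      w_min <- pmin(peaks$width_bins[i], kept_e - kept_s + 1L)
      if (!any(ov >= min_frac * w_min)) {
        keep[i] <- TRUE
        kept_s <- c(kept_s, peaks$start_bin[i])
        kept_e <- c(kept_e, peaks$end_bin[i])
      }
    }
  }
  peaks[keep, , drop = FALSE]
}

# per-apex best admissible candidate under the matched-filter score with
# the width cap; filters applied before selection.  The integrated excess
# is bounded below by the net excess, so the O(width) clipped sum is only
# evaluated where the O(1) bound cannot decide.
best_candidates_vector <- function(d, lm, params) {
  apexes <- sort(unique(lm$bin[lm$kind == "MAXIMUM"])) + 1L
  epts <- sort(unique(lm$bin[lm$kind %in% c("MINIMUM", "SLOPE_CHANGE")])) + 1L
  if (length(apexes) == 0L || length(epts) < 2L) return(empty_candidates())
  ng <- nearest_greater(d)
  cs <- c(0, cumsum(d))
  cap <- params$max_width_bins
  # epts is sorted: binary-search all admissible endpoint index ranges at once
  lo_all <- pmax(ng$left[apexes], apexes - cap)
  hi_all <- pmin(ng$right[apexes], apexes + cap)
  s_from_all <- findInterval(lo_all, epts) + 1L
  s_to_all <- findInterval(apexes - 1L, epts)
  e_from_all <- findInterval(apexes, epts) + 1L
  e_to_all <- findInterval(hi_all - 1L, epts)
  n_apex <- length(apexes)
  win_s <- integer(n_apex)
  win_e <- integer(n_apex)
  win_a <- integer(n_apex)
  n_win <- 0L
  thr_max <- params$max_excess_min
  for (ai in seq_len(n_apex)) {
    a <- apexes[ai]
    if (s_from_all[ai] > s_to_all[ai] || e_from_all[ai] > e_to_all[ai]) next
    ss <- epts[s_from_all[ai]:s_to_all[ai]]
    ee <- epts[e_from_all[ai]:e_to_all[ai]]
    # cheap reject: even the lowest attainable baseline cannot clear the
    # max-excess threshold (the common case on background noise)
    if (params$baseline_relative &&
      d[a] - (min(d[ss]) + min(d[ee])) / 2 <= thr_max) {
      next
    }
    grid_s <- rep(ss, times = length(ee))
    grid_e <- rep(ee, each = length(ss))
    w <- grid_e - grid_s + 1L
    ok <- w <= cap
    if (!any(ok)) next
    grid_s <- grid_s[ok]; grid_e <- grid_e[ok]; w <- w[ok]
    b <- (d[grid_s] + d[grid_e]) / 2
    max_exc <- d[a] - b
    score_max <- if (params$baseline_relative) max_exc else rep(d[a], length(b))
    net <- (cs[grid_e + 1L] - cs[grid_s]) - b * w
    pass_max <- score_max > thr_max
    # net <= integrated: candidates failing on net get the exact check
    pass_area <- net > params$area_min
    need_exact <- pass_max & !pass_area
    if (any(need_exact)) {
      for (i in which(need_exact)) {
        seg <- d[grid_s[i]:grid_e[i]]
        pass_area[i] <- sum(pmax(0, seg - b[i])) > params$area_min
      }
    }
    keep <- pass_max & pass_area
    if (!any(keep)) next
    score <- net / sqrt(w)
    ord <- order(-score, -w, grid_s)
    best <- ord[keep[ord]][1]
    if (is.na(best)) next
    n_win <- n_win + 1L
    win_s[n_win] <- grid_s[best]
    win_e[n_win] <- grid_e[best]
    win_a[n_win] <- a
  }
  if (n_win == 0L) return(empty_candidates())
  win_s <- win_s[seq_len(n_win)]
  win_e <- win_e[seq_len(n_win)]
  win_a <- win_a[seq_len(n_win)]
  stats <- lapply(seq_len(n_win), function(i) {
    candidate_stats(d, win_s[i], win_a[i], win_e[i])
  })
  tibble(
    start_bin = win_s - 1L, apex_bin = win_a - 1L, end_bin = win_e - 1L,
    baseline = vapply(stats, `[[`, numeric(1), "baseline"),
    max_excess = vapply(stats, `[[`, numeric(1), "max_excess"),
    net_excess = vapply(stats, `[[`, numeric(1), "net_excess"),
    width_bins = as.integer(win_e - win_s + 1L),
    integrated_excess = vapply(stats, `[[`, numeric(1), "integrated_excess")
  )
}
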