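# Independent brute-force oracles.  These deliberately share no code with
# the package: naive loops and their own lookup tables.

# -- IUPAC tables for the oracle scanner ------------------------------------
.osets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
.ocomp <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

oracle_revcomp <- function(s) {
  paste(rev(unname(.ocomp[strsplit(s, "")[[1]]])), collapse = "")
}

# position-by-position scan; a sequence base matches a consensus letter when
# the letter's base set contains it (so sequence N never matches)
oracle_count_one_strand <- function(seq, motif) {
  sv <- strsplit(seq, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  k <- length(mv)
  n <- length(sv)
  if (n < k) return(0L)
  hits <- 0L
  for (i in 1:(n - k + 1L)) {
    ok <- TRUE
    for (j in 1:k) {
      if (!(sv[i + j - 1L] %in% .osets[[mv[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_count_occurrences <- function(seq, motif) {
  oracle_count_one_strand(seq, motif) +
    oracle_count_one_strand(seq, oracle_revcomp(motif))
}

# -- brute-force candidate enumeration --------------------------------------
# All (s, a, e) landmark triples with s < a < e, a a MAXIMUM, s and e
# MINIMUM or SLOPE_CHANGE, and the smoothed depth attaining its maximum
# over [s, e] at a; statistics computed directly from the definitions.
oracle_enumerate <- function(d, landmarks) {
  maxima <- landmarks$bin[landmarks$kind == "MAXIMUM"] + 1L
  ends <- sort(unique(landmarks$bin[landmarks$kind %in% c("MINIMUM", "SLOPE_CHANGE")])) + 1L
  rows <- list()
  for (a in maxima) {
    for (s in ends) {
      if (s >= a) next
      for (e in ends) {
        if (e <= a) next
        seg <- d[s:e]
        if (max(seg) != d[a]) next
        b <- (d[s] + d[e]) / 2
        rows[[length(rows) + 1L]] <- data.frame(
          start_bin = s - 1L, apex_bin = a - 1L, end_bin = e - 1L,
          baseline = b, max_excess = d[a] - b,
          integrated_excess = sum(pmax(0, seg - b))
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      start_bin = integer(), apex_bin = integer(), end_bin = integer(),
      baseline = numeric(), max_excess = numeric(),
      integrated_excess = numeric()
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$start_bin, out$end_bin, out$apex_bin), , drop = FALSE]
}

oracle_filter <- function(cands, max_excess_min = 2.5, area_min = 5) {
  cands[cands$max_excess > max_excess_min & cands$integrated_excess > area_min, ,
    drop = FALSE
  ]
}

# -- brute-force all-pairs peak-gene linking --------------------------------
oracle_links <- function(peaks, genes, max_distance = 10000) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      gap <- max(
        genes$start[j] - peaks$end[i],
        peaks$start[i] - genes$end[j],
        0
      )
      if (gap <= max_distance) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = genes$gene_id[j],
          distance = gap
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      peak_id = character(), gene_id = character(), distance = numeric()
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$peak_id, out$gene_id), , drop = FALSE]
}

# reciprocal-overlap matching of called peaks against planted intervals
reciprocal_match <- function(called, truth, min_frac = 0.5) {
  hit_called <- logical(nrow(called))
  hit_truth <- logical(nrow(truth))
  truth_of_called <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(called))) {
    for (j in seq_len(nrow(truth))) {
      if (called$chrom[i] != truth$chrom[j]) next
      ov <- min(called$end[i], truth$end[j]) - max(called$start[i], truth$start[j])
      if (ov >= min_frac * (called$end[i] - called$start[i]) &&
        ov >= min_frac * (truth$end[j] - truth$start[j])) {
        hit_called[i] <- TRUE
        hit_truth[j] <- TRUE
        if (is.na(truth_of_called[i])) truth_of_called[i] <- j
      }
    }
  }
  list(
    recall = mean(hit_truth), precision = mean(hit_called),
    truth_of_called = truth_of_called
  )
}
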