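# Motif catalogue: built-in k-mer enrichment discovery, consolidation of
# homologous motifs, IUPAC-aware occurrence counting on both strands, and
# conversion of peaks to motif-frequency vectors.

#' Count motif occurrences in sequences (both strands, overlapping)
#'
#' A position matches when every consensus letter's IUPAC base set contains
#' the sequence base; N in the sequence matches nothing.  Both-strand
#' counting adds occurrences of the motif and of its reverse complement on
#' the forward sequence, so palindrome-symmetric sites count twice (the
#' convention is documented because totals depend on it).
#'
#' @param sequences Character vector of DNA sequences (A/C/G/T/N).
#' @param motif A single IUPAC consensus string.
#' @param both_strands Count the reverse complement too (default `TRUE`).
#' @return Integer vector of counts, one per sequence.
#' @export
count_motif_occurrences <- function(sequences, motif, both_strands = TRUE) {
  stopifnot(length(motif) == 1L)
  if (!is_valid_iupac(motif)) stop_config("motif must be a valid IUPAC consensus")
  pats <- c(motif, if (both_strands) revcomp(motif))
  k <- nchar(motif)
  vapply(sequences, function(s) {
    # N in a sequence matches nothing, so windows containing N are excluded:
    # count inside the N-free segments only
    segs <- strsplit(s, "N+")[[1]]
    segs <- segs[nchar(segs) >= k]
    if (length(segs) == 0L) return(0L)
    subj <- Biostrings::DNAStringSet(segs)
    tot <- 0L
    for (p in pats) {
      tot <- tot + sum(Biostrings::vcountPattern(p, subj, fixed = "subject"))
    }
    as.integer(tot)
  }, integer(1), USE.NAMES = FALSE)
}

# shuffle each sequence's letters (a mononucleotide-composition-preserving
# background)
shuffle_sequences <- function(sequences, seed) {
  withr::with_seed(seed, {
    vapply(sequences, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

# canonical k-mer: lexicographic min of the k-mer and its reverse complement
canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# set of canonical k-mers present in one sequence (either strand)
present_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  unique(canonical_kmer(km))
}

#' Discover enriched short motifs with the built-in k-mer finder
#'
#' For each k in `k_range`, every k-mer observed in the foreground
#' sequences is tested for presence/absence enrichment against the
#' background (one-sided Fisher exact, i.e. the hypergeometric tail),
#' Bonferroni-corrected over all tested k-mers.  Significant k-mers are
#' collapsed greedily (best p first) when an ungapped alignment over
#' either strand matches in at least `min(k) - 1` positions, yielding
#' IUPAC-degenerate consensus motifs.
#'
#' An adapter to an external motif-discovery program can be supplied via
#' `external`; it must map `(sequences, background)` to a character vector
#' of consensus strings and is used verbatim when given.
#'
#' @param sequences Foreground sequences (>= 10).
#' @param background Background sequences; by default the shuffled
#'   foreground.
#' @param source_class Class label stamped on the motifs (e.g.
#'   `"PEAKS_2_0"`).
#' @param k_range Integer k-mer lengths to test (default 5:9).
#' @param alpha Family-wise significance level after Bonferroni
#'   (default 0.01).
#' @param max_motifs Cap on returned motifs (default 25, best p first).
#' @param seed Seed for the background shuffle.
#' @param external Optional function `(sequences, background) ->
#'   character` delegating discovery to an external program's adapter.
#' @return Tibble of motifs: `consensus`, `k`, `source_class`, `p_bonf`,
#'   `n_kmers`.
#' @export
discover_motifs <- function(sequences, background = NULL,
                            source_class = NA_character_, k_range = 5:9,
                            alpha = 0.01, max_motifs = 25L, seed = 1L,
                            external = NULL) {
  if (length(sequences) < 10L) abort("need at least 10 sequences for motif discovery")
  if (!is.null(external)) {
    if (!is.function(external)) {
      abort("external motif-discovery adapter unavailable; pass a function or use the built-in finder (external = NULL)")
    }
    cons <- external(sequences, background)
    return(tibble(
      consensus = as.character(cons), k = nchar(cons),
      source_class = source_class, p_bonf = NA_real_,
      n_kmers = NA_integer_
    ))
  }
  if (is.null(background)) {
    background <- shuffle_sequences(sequences, derive_seed(seed, 71L))
  }
  n_fg <- length(sequences)
  n_bg <- length(background)
  hits <- list()
  n_tested <- 0L
  for (k in sort(k_range)) {
    fg_sets <- lapply(sequences, present_kmers, k = k)
    bg_sets <- lapply(background, present_kmers, k = k)
    fg_tab <- table(unlist(fg_sets))
    if (length(fg_tab) == 0L) next
    bg_all <- unlist(bg_sets)
    kmers <- names(fg_tab)
    fg_count <- as.integer(fg_tab)
    bg_count <- as.integer(table(factor(bg_all, levels = kmers)))
    n_tested <- n_tested + length(kmers)
    # one-sided Fisher exact on the 2x2 presence table == hypergeometric tail
    p <- phyper(fg_count - 1L, fg_count + bg_count,
      n_fg + n_bg - fg_count - bg_count, n_fg,
      lower.tail = FALSE
    )
    hits[[as.character(k)]] <- tibble(
      kmer = kmers, k = k, fg = fg_count, bg = bg_count, p = p
    )
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L || n_tested == 0L) {
    return(tibble(
      consensus = character(), k = integer(),
      source_class = character(), p_bonf = numeric(), n_kmers = integer()
    ))
  }
  hits$p_bonf <- pmin(1, hits$p * n_tested)
  sig <- arrange(filter(hits, .data$p_bonf < alpha), .data$p_bonf, .data$kmer)
  if (nrow(sig) == 0L) {
    return(tibble(
      consensus = character(), k = integer(),
      source_class = character(), p_bonf = numeric(), n_kmers = integer()
    ))
  }
  groups <- collapse_kmers(sig$kmer, min_overlap_deficit = 1L)
  cons <- vapply(groups, `[[`, character(1), "consensus")
  pb <- vapply(groups, function(g) min(sig$p_bonf[sig$kmer %in% g$members]), numeric(1))
  nk <- vapply(groups, function(g) length(g$members), integer(1))
  out <- tibble(
    consensus = cons, k = nchar(cons), source_class = source_class,
    p_bonf = pb, n_kmers = nk
  )
  out <- arrange(out, .data$p_bonf, .data$consensus)
  head(out, max_motifs)
}

# best ungapped alignment between two IUPAC strings over both strands and
# all offsets; returns matches (compatible positions), overlap length,
# offset, strand and the merged consensus at that alignment
align_consensus <- function(a, b) {
  best <- list(matches = -1L)
  la <- nchar(a)
  av <- strsplit(a, "")[[1]]
  for (strand in c("+", "-")) {
    bb <- if (strand == "+") b else revcomp(b)
    bv <- strsplit(bb, "")[[1]]
    lb <- length(bv)
    for (off in seq(-lb + 1L, la - 1L)) {
      # b position j aligns with a position j + off
      js <- seq_len(lb)
      as_ <- js + off
      inside <- as_ >= 1L & as_ <= la
      if (!any(inside)) next
      m <- sum(mapply(iupac_compatible, av[as_[inside]], bv[js[inside]]))
      if (m > best$matches) {
        best <- list(
          matches = as.integer(m), overlap = sum(inside),
          offset = off, strand = strand, b_oriented = bb
        )
      }
    }
  }
  best
}

# merge string b into consensus a at the given alignment: IUPAC union on
# overlapping positions, extension at the ends
merge_consensus <- function(a, b_oriented, offset) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b_oriented, "")[[1]]
  lo <- min(1L, 1L + offset)
  hi <- max(length(av), length(bv) + offset)
  out <- character(hi - lo + 1L)
  for (pos in lo:hi) {
    i <- pos - lo + 1L
    in_a <- pos >= 1L && pos <= length(av)
    jb <- pos - offset
    in_b <- jb >= 1L && jb <= length(bv)
    out[i] <- if (in_a && in_b) {
      iupac_union(av[pos], bv[jb])
    } else if (in_a) av[pos] else bv[jb]
  }
  paste(out, collapse = "")
}

# greedy collapse of k-mers (ordered best-first) into degenerate consensi;
# a k-mer joins a group when its best alignment to the group consensus
# matches in >= min(len) - min_overlap_deficit positions
collapse_kmers <- function(kmers, min_overlap_deficit = 1L, max_len = 30L) {
  groups <- list()
  for (km in kmers) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      al <- align_consensus(groups[[gi]]$consensus, km)
      need <- min(nchar(groups[[gi]]$consensus), nchar(km)) - min_overlap_deficit
      if (al$matches >= need) {
        merged <- merge_consensus(groups[[gi]]$consensus, al$b_oriented, al$offset)
        if (nchar(merged) <= max_len) groups[[gi]]$consensus <- merged
        groups[[gi]]$members <- c(groups[[gi]]$members, km)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- list(consensus = km, members = km)
  }
  groups
}

#' Similarity between two motif consensi
#'
#' The maximum over ungapped offsets and both strands of the number of
#' IUPAC-compatible aligned positions, divided by the length of the
#' shorter motif.
#'
#' @param a,b IUPAC consensus strings.
#' @return Similarity in `[0, 1]`.
#' @export
motif_similarity <- function(a, b) {
  align_consensus(a, b)$matches / min(nchar(a), nchar(b))
}

#' Number of matching positions at the best alignment of two consensi
#'
#' @param a,b IUPAC consensus strings.
#' @return Integer count of IUPAC-compatible aligned positions.
#' @export
motif_match_count <- function(a, b) {
  align_consensus(a, b)$matches
}

#' Consolidate homologous motifs into one catalogue
#'
#' Single-linkage grouping under [motif_similarity()]: motifs join one
#' group whenever any pair crosses `similarity_threshold`.  Each group is
#' represented by its longest member (ties: first by input order); ids are
#' reassigned 0..m-1.
#'
#' @param motifs Motif tibble with at least `consensus` and
#'   `source_class`.
#' @param similarity_threshold Merge threshold in `[0, 1]` (default 0.8).
#' @return Motif catalogue tibble: `motif_id` (0-based), `consensus`, `k`,
#'   `source_class`, `n_merged`, with the threshold stored as attribute
#'   `similarity_threshold`.
#' @export
consolidate_motifs <- function(motifs, similarity_threshold = 0.8) {
  if (nrow(motifs) == 0L) abort("no motifs to consolidate")
  n <- nrow(motifs)
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (motif_similarity(motifs$consensus[i], motifs$consensus[j]) >=
          similarity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- lapply(unique(root), function(r) {
    idx <- which(root == r)
    lens <- nchar(motifs$consensus[idx])
    rep_i <- idx[which.max(lens)] # which.max: first on ties = input order
    list(rep = rep_i, members = idx)
  })
  # catalogue ordered by representative's input position
  ord <- order(vapply(reps, `[[`, integer(1), "rep"))
  reps <- reps[ord]
  tibble(
    motif_id = seq_along(reps) - 1L,
    consensus = motifs$consensus[vapply(reps, `[[`, integer(1), "rep")],
    k = nchar(motifs$consensus[vapply(reps, `[[`, integer(1), "rep")]),
    source_class = motifs$source_class[vapply(reps, `[[`, integer(1), "rep")],
    n_merged = vapply(reps, function(r) length(r$members), integer(1))
  ) |>
    set_similarity_threshold(similarity_threshold)
}

set_similarity_threshold <- function(x, thr) {
  attr(x, "similarity_threshold") <- thr
  x
}

#' Extract peak sequences from a genome
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end` (bp, 0-based
#'   half-open).
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]
    if (!ch %in% names(genome)) abort(paste0("chromosome ", ch, " not in genome"))
    if (peaks$end[i] > nchar(genome[[ch]])) abort("peak beyond chromosome end")
    substr(genome[[ch]], peaks$start[i] + 1L, peaks$end[i])
  }, character(1))
}

#' Convert differential peaks to motif-frequency vectors
#'
#' Each peak's value for motif m is its both-strand occurrence count per
#' kb of peak sequence.  Peaks labelled `UNCHANGED` are excluded by
#' default (only the differential classes are vectorized).
#'
#' @param diff_peaks Classified peak tibble from [classify_peaks()].
#' @param genome Named character vector of chromosome sequences.
#' @param catalog Motif catalogue from [consolidate_motifs()].
#' @param include_unchanged Keep `UNCHANGED` peaks too (default `FALSE`).
#' @param per_kb Normalize counts per kb of peak length (default `TRUE`;
#'   `FALSE` gives raw counts).
#' @return Tibble with `peak_id`, `origin` and one `motif_<id>` column per
#'   catalogue motif.
#' @export
build_frequency_vectors <- function(diff_peaks, genome, catalog,
                                    include_unchanged = FALSE, per_kb = TRUE) {
  if (nrow(catalog) == 0L) abort("empty motif catalogue")
  pk <- if (include_unchanged) {
    diff_peaks
  } else {
    filter(diff_peaks, .data$label %in% c("PEAKS_2_0", "PEAKS_0_5"))
  }
  if (nrow(pk) == 0L) abort("no peaks to vectorize")
  seqs <- peak_sequences(pk, genome)
  len_bp <- pk$end - pk$start
  counts <- vapply(catalog$consensus, function(m) {
    count_motif_occurrences(seqs, m)
  }, integer(nrow(pk)))
  counts <- matrix(counts, nrow = nrow(pk))
  vals <- if (per_kb) counts * 1000 / len_bp else counts
  colnames(vals) <- paste0("motif_", catalog$motif_id)
  dplyr::bind_cols(
    tibble(peak_id = pk$peak_id, origin = pk$label),
    as_tibble(vals)
  )
}
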