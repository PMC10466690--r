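# Readers and writers for the standard formats the pipeline touches.
# All genomic coordinates exposed by this package are 0-based half-open
# (bedGraph native); GRanges objects used internally are converted at the
# boundary.

#' Read a bedGraph coverage file into a binned depth track
#'
#' Intervals are re-binned to `bin_size` by coverage-weighted mean: each
#' bin's depth is the mean per-bp coverage over the bin, with uncovered
#' basepairs contributing 0.  Total mass (depth x bp) is conserved.
#'
#' @param path Path to a 4-column bedGraph file (chrom, start, end, value;
#'   0-based half-open, non-overlapping per chromosome).
#' @param bin_size Bin width in bp (default 10).
#' @return A tibble with columns `chrom`, `bin`, `depth` and a `bin_size`
#'   attribute.  Bins run from 0 to the last covered bin per chromosome.
#' @export
read_depth_bedgraph <- function(path, bin_size = 10L) {
  stopifnot(bin_size >= 1)
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop_format(paste0("cannot parse bedGraph: ", conditionMessage(e)))
  )
  if (length(gr) == 0L) stop_format("empty bedGraph file")
  if (any(gr$score < 0)) stop_format("negative coverage value in bedGraph")
  by_chrom <- S4Vectors::splitAsList(
    IRanges::ranges(gr), as.character(GenomicRanges::seqnames(gr))
  )
  if (!all(IRanges::isDisjoint(by_chrom))) {
    stop_format("overlapping intervals in bedGraph")
  }
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based
    end = GenomicRanges::end(gr),
    value = gr$score
  )
  out <- df |>
    group_by(.data$chrom) |>
    dplyr::group_modify(~ rebin_intervals(.x, bin_size)) |>
    ungroup() |>
    arrange(.data$chrom, .data$bin)
  set_bin_size(out, bin_size)
}

# coverage-weighted rebinning of disjoint intervals on one chromosome
rebin_intervals <- function(df, bin_size) {
  bs <- as.numeric(bin_size)
  first_bin <- df$start %/% bs
  last_bin <- (df$end - 1L) %/% bs
  nspan <- as.integer(last_bin - first_bin + 1L)
  idx <- rep.int(seq_len(nrow(df)), nspan)
  bin <- unlist(lapply(seq_len(nrow(df)), function(i) first_bin[i]:last_bin[i]),
    use.names = FALSE
  )
  lo <- pmax(df$start[idx], bin * bs)
  hi <- pmin(df$end[idx], (bin + 1) * bs)
  mass <- df$value[idx] * (hi - lo)
  agg <- rowsum(mass, bin)
  bins_present <- as.numeric(rownames(agg))
  n_bins <- max(bins_present) + 1
  depth <- numeric(n_bins)
  depth[bins_present + 1] <- agg[, 1] / bs
  tibble(bin = seq_len(n_bins) - 1L, depth = depth)
}

#' Write a depth track as bedGraph
#'
#' Adjacent bins with equal depth are merged into one record; zero-depth
#' bins are omitted (bedGraph convention: uncovered means zero).
#'
#' @param track A depth track tibble (`chrom`, `bin`, `depth`) with a
#'   `bin_size` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path) {
  check_depth_tibble(track)
  bs <- bin_size_of(track)
  recs <- track |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(x, ...) {
      x <- arrange(x, .data$bin)
      r <- rle(x$depth)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      tibble(
        start = x$bin[starts_i] * bs,
        end = (x$bin[ends_i] + 1L) * bs,
        value = r$values
      )
    }) |>
    ungroup() |>
    filter(.data$value != 0)
  readr::write_tsv(recs, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome FASTA file
#'
#' Sequences are uppercased and RNA U is mapped to T.  Ambiguity codes other
#' than A/C/G/T are mapped to N so the stored alphabet is {A,C,G,T,N};
#' characters outside the IUPAC alphabet are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_format(paste0("cannot parse FASTA: ", conditionMessage(e)))
  )
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop_format("duplicate FASTA header")
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  if (any(nchar(seqs) == 0L)) stop_format("empty sequence in FASTA")
  bad <- !grepl("^[ACGTRYSWKMBDHVN]*$", seqs)
  if (any(bad)) stop_format("illegal (non-IUPAC) character in FASTA sequence")
  # collapse ambiguity codes to N: stored alphabet is A/C/G/T/N
  seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  setNames(seqs, nm)
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path,
    width = width
  )
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' Coordinates are returned 0-based half-open.  For GFF3 only `gene`-type
#' records are kept (all records if none are typed `gene`), and the gene id
#' is taken from the ID, gene_id or Name attribute in that order.
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  gr <- tryCatch(
    rtracklayer::import(path, format = if (is_gff) "gff3" else "bed"),
    error = function(e) stop_format(paste0("cannot parse gene file: ", conditionMessage(e)))
  )
  if (is_gff) {
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
      gr <- gr[gr$type == "gene"]
    }
    md <- S4Vectors::mcols(gr)
    id <- NULL
    for (f in c("ID", "gene_id", "Name")) {
      if (f %in% names(md)) {
        id <- as.character(md[[f]])
        break
      }
    }
    if (is.null(id)) id <- paste0("gene_", seq_along(gr))
  } else {
    id <- if ("name" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$name)
    } else {
      paste0("gene_", seq_along(gr))
    }
  }
  out <- tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- "."
  if (any(out$start >= out$end)) stop_format("gene with start >= end")
  out
}

#' Read an FPKM expression table
#'
#' @param path TSV with a header row of sample ids; first column gene ids.
#' @param group_map Named character vector mapping every sample id in the
#'   file to a group, with values in `c("control", "mutant")`.  Exactly one
#'   control group and at least one mutant sample are required.
#' @return Long tibble with columns `gene_id`, `sample`, `group`, `fpkm`.
#' @export
read_fpkm_table <- function(path, group_map) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 2L) stop_format("FPKM table needs a gene column plus samples")
  names(raw)[1] <- "gene_id"
  samples <- names(raw)[-1]
  missing <- setdiff(samples, names(group_map))
  if (length(missing) > 0L) {
    stop_config(paste0("samples absent from group_map: ", paste(missing, collapse = ", ")))
  }
  groups <- group_map[samples]
  if (!all(groups %in% c("control", "mutant"))) {
    stop_config("group_map values must be 'control' or 'mutant'")
  }
  if (sum(groups == "control") < 1L) stop_config("group_map names no control sample")
  if (sum(groups == "mutant") < 1L) stop_config("group_map names no mutant sample")
  long <- pivot_longer(raw, -"gene_id", names_to = "sample", values_to = "fpkm")
  vals <- suppressWarnings(as.numeric(long$fpkm))
  if (any(is.na(vals))) stop_format("non-numeric cell in FPKM table")
  if (any(!is.finite(vals)) || any(vals < 0)) stop_format("FPKM values must be finite and >= 0")
  long$fpkm <- vals
  long$group <- unname(group_map[long$sample])
  long[, c("gene_id", "sample", "group", "fpkm")]
}

#' Write an FPKM table (genes x samples TSV)
#'
#' @param fpkm Long FPKM tibble as returned by [read_fpkm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(fpkm, path) {
  wide <- pivot_wider(
    fpkm[, c("gene_id", "sample", "fpkm")],
    names_from = "sample", values_from = "fpkm"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Combine per-sample depth tracks into one experiment table
#'
#' @param tracks Named list of depth track tibbles (one per sample).
#' @param group_map Named character vector sample -> group
#'   (`"control"`/`"mutant"`).
#' @return Tibble with columns `sample`, `group`, `chrom`, `bin`, `depth`.
#' @export
combine_depth_tracks <- function(tracks, group_map) {
  stopifnot(length(tracks) >= 1L, !is.null(names(tracks)))
  bs <- unique(vapply(tracks, bin_size_of, numeric(1)))
  if (length(bs) != 1L) abort("all tracks must share one bin_size")
  missing <- setdiff(names(tracks), names(group_map))
  if (length(missing) > 0L) stop_config("samples absent from group_map")
  out <- bind_rows(lapply(names(tracks), function(s) {
    mutate(tracks[[s]], sample = s, group = unname(group_map[s]), .before = 1)
  }))
  set_bin_size(out, bs)
}
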