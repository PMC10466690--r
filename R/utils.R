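# Shared helpers: IUPAC machinery, seed fan-out, input validation.

# IUPAC nucleotide codes as base sets.  N is the full set; gaps are not
# supported.  A plain N in a *sequence* matches nothing (it denotes an
# unknown base, not a wildcard); N in a *motif consensus* matches A/C/G/T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# set-of-bases -> IUPAC letter lookup, keyed by sorted, comma-joined bases
.iupac_key <- function(bases) paste(sort(unique(bases)), collapse = "")
IUPAC_FROM_SET <- local({
  m <- vapply(IUPAC_SETS, .iupac_key, character(1))
  setNames(names(m), unname(m))
})

iupac_union <- function(a, b) {
  IUPAC_FROM_SET[[.iupac_key(c(IUPAC_SETS[[a]], IUPAC_SETS[[b]]))]]
}

# TRUE where the two IUPAC letters share at least one base
iupac_compatible <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
}

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of an IUPAC consensus string
#'
#' @param x Character vector of sequences over the IUPAC alphabet.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr(
      "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
      "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", s
    ), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_valid_iupac <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

# Deterministic sub-seed derivation: one user-facing seed fans out to all
# stochastic components.  Kept strictly below 2^31 (R integers).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(offset) * 97) %%
    2147483647)
}

stop_format <- function(msg) abort(msg, class = "peakshift_format_error")
stop_config <- function(msg) abort(msg, class = "peakshift_config_error")

check_depth_tibble <- function(x, arg = "track") {
  if (!is.data.frame(x) || !all(c("chrom", "bin", "depth") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with columns chrom, bin, depth"))
  }
  if (any(!is.finite(x$depth)) || any(x$depth < 0)) {
    stop_format("depth values must be finite and non-negative")
  }
  invisible(x)
}

bin_size_of <- function(x) {
  bs <- attr(x, "bin_size", exact = TRUE)
  if (is.null(bs)) abort("input has no bin_size attribute; read or simulate tracks with peakshift functions")
  bs
}

set_bin_size <- function(x, bin_size) {
  attr(x, "bin_size") <- as.integer(bin_size)
  x
}
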