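# Fixture builders shared across test files.  Everything is generated in
# code; seeds are fixed so failures reproduce.

make_track <- function(depths, chrom = "chr1", bin_size = 10L) {
  out <- tibble::tibble(
    chrom = chrom, bin = seq_along(depths) - 1L, depth = as.numeric(depths)
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

# depth set from a named list of per-sample depth vectors
make_depth_set <- function(sample_depths, groups, chrom = "chr1", bin_size = 10L) {
  out <- dplyr::bind_rows(lapply(names(sample_depths), function(s) {
    tibble::tibble(
      sample = s, group = groups[[s]], chrom = chrom,
      bin = seq_along(sample_depths[[s]]) - 1L,
      depth = as.numeric(sample_depths[[s]])
    )
  }))
  attr(out, "bin_size") <- as.integer(bin_size)
  out
}

# a random noisy track for property tests: Poisson background with a few
# Gaussian bumps
random_track <- function(seed, n_bins = 50L, lambda = 3) {
  withr::with_seed(seed, {
    x <- stats::rpois(n_bins, lambda)
    n_bumps <- sample(0:2, 1)
    for (b in seq_len(n_bumps)) {
      c0 <- sample(5:(n_bins - 5), 1)
      h <- stats::runif(1, 3, 12)
      w <- stats::runif(1, 2, 6)
      x <- x + h * exp(-(seq_len(n_bins) - c0)^2 / (2 * w^2))
    }
    x
  })
}

# scaled-down simulation for unit tests: 28 planted peaks on 340 kb
# (each differential class keeps >= 10 peaks so motif discovery runs)
small_sim_config <- function(seed = 7L, ...) {
  simulation_config(
    seed = seed,
    genome_length = 340000L,
    n_peaks = c(mut_enriched = 12L, ctrl_enriched = 12L, shared = 4L),
    expression = list(n_genes = 60L),
    ...
  )
}

# memoised default-conditions dataset shared by the heavier tests
.run_cache <- new.env(parent = emptyenv())
default_run <- function() {
  if (is.null(.run_cache$run)) {
    cfg <- simulation_config(seed = 101L)
    sim <- simulate_experiment(cfg)
    peaks <- call_peaks(sim$depth)
    diff_peaks <- classify_peaks(peaks, sim$depth)
    .run_cache$run <- list(
      cfg = cfg, sim = sim, peaks = peaks, diff_peaks = diff_peaks
    )
  }
  .run_cache$run
}

# memoised small end-to-end pipeline run (no serialization)
small_run <- function() {
  if (is.null(.run_cache$small_run)) {
    cfg <- peakshift_config(
      sim = small_sim_config(seed = 11L),
      cluster = list(k = 4L), seed = 11L
    )
    .run_cache$small_run <- run_pipeline(cfg)
  }
  .run_cache$small_run
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_setequal(as.character(a), as.character(b))
}
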