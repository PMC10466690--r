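# Synthetic two-condition ChIP-seq experiment generator.  Every downstream
# stage of the pipeline is testable against the planted ground truth this
# module records: peak intervals and enrichment classes, motif insertion
# positions, and gene regulation directions.

#' Configuration for the synthetic experiment generator
#'
#' Defaults describe a single 600-kb chromosome carrying 50 planted
#' enrichment peaks (20 mutant-enriched, 20 control-enriched, 10 shared) in
#' 10-kb blocks over a Poisson background, sampled for 2 control and 3
#' mutant samples, with class-specific short motifs planted in the peak
#' sequences and a 200-gene FPKM table with known up/down/null regulation
#' across three mutant lines.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param genome_length Chromosome length in bp.
#' @param bin_size Depth bin width in bp.
#' @param n_peaks Named integer vector: planted peaks per class
#'   (`mut_enriched`, `ctrl_enriched`, `shared`).
#' @param peak_width Planted peak width in bp (the truth interval is the
#'   apex +/- `peak_width/2`; the Gaussian bump SD is `peak_width/4`).
#' @param peak_excess Mean excess depth at the apex for the enriched group.
#' @param background_lambda Poisson mean background depth per bin.
#' @param n_control_samples,n_mutant_samples Samples per group.
#' @param enrichment_ratio Named numeric vector: mutant:control mean excess
#'   ratio per class; must be > 2 for `mut_enriched` and < 0.5 for
#'   `ctrl_enriched`.
#' @param motif_plants List of `list(consensus=, class=, n_per_peak=)`
#'   entries; each consensus (IUPAC allowed) is inserted `n_per_peak` times
#'   into every planted peak of the target class.
#' @param block_size Spacing of planted peak blocks in bp.
#' @param expression List of FPKM-table settings: `n_genes`, `frac_down`,
#'   `frac_up`, `fold_down`, `fold_up`, `fold_null` (ranges),
#'   `control_fpkm` (log-uniform range), `noise_sdlog` (log-normal
#'   multiplicative noise on mutant lines), `n_mutant_lines`,
#'   `n_control_samples`.
#' @param gene_length Simulated gene length in bp.
#' @param linked_gene_max_gap Maximum planted peak-to-gene gap in bp for
#'   genes that are placed next to a peak (kept below the 10-kb linking
#'   window with margin).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 600000L,
                              bin_size = 10L,
                              n_peaks = c(mut_enriched = 20L, ctrl_enriched = 20L, shared = 10L),
                              peak_width = 400L,
                              peak_excess = 30,
                              background_lambda = 2,
                              n_control_samples = 2L,
                              n_mutant_samples = 3L,
                              enrichment_ratio = c(mut_enriched = 4, ctrl_enriched = 0.25, shared = 1),
                              motif_plants = list(
                                list(consensus = "CCCCACCCC", class = "MUT_ENRICHED", n_per_peak = 2L),
                                list(consensus = "TAGAAATA", class = "CTRL_ENRICHED", n_per_peak = 2L)
                              ),
                              block_size = 10000L,
                              expression = list(),
                              gene_length = 1000L,
                              linked_gene_max_gap = 8000L) {
  expr_defaults <- list(
    n_genes = 200L, frac_down = 0.15, frac_up = 0.15,
    fold_down = c(0.1, 0.4), fold_up = c(2.5, 8), fold_null = c(0.9, 1.1),
    control_fpkm = c(1, 1000), noise_sdlog = 0.03,
    n_mutant_lines = 3L, n_control_samples = 2L
  )
  unknown <- setdiff(names(expression), names(expr_defaults))
  if (length(unknown) > 0L) {
    stop_config(paste0("unknown expression settings: ", paste(unknown, collapse = ", ")))
  }
  expression <- utils::modifyList(expr_defaults, as.list(expression))
  # accept list form (e.g. from YAML) for the named-vector fields
  n_peaks <- unlist(n_peaks)
  enrichment_ratio <- unlist(enrichment_ratio)
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    bin_size = as.integer(bin_size), n_peaks = n_peaks,
    peak_width = as.integer(peak_width), peak_excess = peak_excess,
    background_lambda = background_lambda,
    n_control_samples = as.integer(n_control_samples),
    n_mutant_samples = as.integer(n_mutant_samples),
    enrichment_ratio = enrichment_ratio, motif_plants = motif_plants,
    block_size = as.integer(block_size), expression = expression,
    gene_length = as.integer(gene_length),
    linked_gene_max_gap = as.integer(linked_gene_max_gap)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  req <- c("mut_enriched", "ctrl_enriched", "shared")
  if (!all(req %in% names(cfg$n_peaks)) || !all(req %in% names(cfg$enrichment_ratio))) {
    stop_config("n_peaks and enrichment_ratio must name mut_enriched, ctrl_enriched, shared")
  }
  if (cfg$background_lambda <= 0) stop_config("background_lambda must be > 0")
  if (cfg$enrichment_ratio[["mut_enriched"]] <= 2) {
    stop_config("enrichment_ratio for mut_enriched must be > 2")
  }
  if (cfg$enrichment_ratio[["ctrl_enriched"]] >= 0.5) {
    stop_config("enrichment_ratio for ctrl_enriched must be < 0.5")
  }
  for (mp in cfg$motif_plants) {
    if (!is_valid_iupac(mp$consensus)) stop_config("motif consensus must be IUPAC")
    if (nchar(mp$consensus) > cfg$peak_width) {
      stop_config("planted motif longer than peak width")
    }
  }
  ex <- cfg$expression
  if (ex$frac_down + ex$frac_up > 1) stop_config("fraction down + up > 1")
  n_total <- sum(cfg$n_peaks)
  if (n_total * cfg$block_size > cfg$genome_length) {
    stop_config("genome too short for the requested peak blocks")
  }
  # planted peaks in adjacent blocks must stay >= 2x max width apart
  if (cfg$block_size < 4L * cfg$peak_width) {
    stop_config("block_size must be at least 4x peak_width")
  }
  invisible(cfg)
}

# planted peak layout: one peak per block, classes shuffled across blocks,
# apex jittered around the block centre.
planted_peaks <- function(cfg) {
  n <- cfg$n_peaks
  classes <- c(
    rep("MUT_ENRICHED", n[["mut_enriched"]]),
    rep("CTRL_ENRICHED", n[["ctrl_enriched"]]),
    rep("SHARED", n[["shared"]])
  )
  withr::with_seed(derive_seed(cfg$seed, 11L), {
    classes <- sample(classes)
    jitter <- round(runif(length(classes), -cfg$block_size / 10, cfg$block_size / 10))
  })
  center <- (seq_along(classes) - 1L) * cfg$block_size + cfg$block_size %/% 2L + jitter
  half <- cfg$peak_width %/% 2L
  tibble(
    planted_id = sprintf("P%03d", seq_along(classes)),
    class = classes,
    chrom = "chr1",
    center = as.integer(center),
    start = as.integer(center - half),
    end = as.integer(center + half)
  )
}

#' Simulate a genome sequence with planted motifs
#'
#' The background is i.i.d. uniform A/C/G/T.  Each configured motif
#' consensus is instantiated (IUPAC letters drawn uniformly from their
#' allowed bases) and inserted at recorded, non-overlapping positions inside
#' every planted peak of its target class.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector), `motif_truth`
#'   (tibble: planted_id, class, consensus, start, instance) and
#'   `truth_peaks` (the planted peak layout).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  peaks <- planted_peaks(config)
  withr::with_seed(derive_seed(config$seed, 23L), {
    genome <- paste(
      sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE),
      collapse = ""
    )
    truth <- list()
    for (mp in config$motif_plants) {
      targets <- peaks[peaks$class == mp$class, ]
      len <- nchar(mp$consensus)
      for (i in seq_len(nrow(targets))) {
        # non-overlapping insertion slots inside the peak interval
        lo <- targets$start[i]
        hi <- targets$end[i] - len
        slots <- integer(0)
        guard <- 0L
        while (length(slots) < mp$n_per_peak && guard < 1000L) {
          cand <- as.integer(round(runif(1, lo, hi)))
          if (all(abs(cand - slots) >= len)) slots <- c(slots, cand)
          guard <- guard + 1L
        }
        for (pos in slots) {
          inst <- paste(vapply(
            strsplit(mp$consensus, "")[[1]],
            function(l) {
              b <- IUPAC_SETS[[l]]
              if (length(b) == 1L) b else sample(b, 1L)
            },
            character(1)
          ), collapse = "")
          substr(genome, pos + 1L, pos + len) <- inst
          truth[[length(truth) + 1L]] <- tibble(
            planted_id = targets$planted_id[i], class = mp$class,
            consensus = mp$consensus, start = pos, instance = inst
          )
        }
      }
    }
  })
  motif_truth <- if (length(truth) > 0L) bind_rows(truth) else {
    tibble(
      planted_id = character(), class = character(),
      consensus = character(), start = integer(), instance = character()
    )
  }
  list(
    genome = c(chr1 = genome),
    motif_truth = motif_truth,
    truth_peaks = peaks
  )
}

# per-class excess depth for each group: the enriched side gets the full
# configured excess, the other side excess / |log-ratio|.
class_excess <- function(cfg, class) {
  key <- c(
    MUT_ENRICHED = "mut_enriched", CTRL_ENRICHED = "ctrl_enriched",
    SHARED = "shared"
  )[[class]]
  r <- cfg$enrichment_ratio[[key]]
  if (r >= 1) {
    c(control = cfg$peak_excess / r, mutant = cfg$peak_excess)
  } else {
    c(control = cfg$peak_excess, mutant = cfg$peak_excess * r)
  }
}

#' Simulate per-sample depth tracks with planted enrichment peaks
#'
#' Per bin the depth is Poisson with mean `background_lambda` plus, for
#' every planted peak, a Gaussian-shaped excess centred on the peak apex
#' (SD = width/4) scaled by the peak class and the sample's group.  Noise
#' is independent per sample.
#'
#' @param config A [simulation_config()].
#' @param truth_peaks Planted peak layout from [simulate_genome()]; when
#'   `NULL` the layout is regenerated from the config.
#' @return List with `depth` (tibble: sample, group, chrom, bin, depth with
#'   a `bin_size` attribute) and `truth_peaks` (planted intervals with
#'   expected per-group apex excess).
#' @export
simulate_depth <- function(config, truth_peaks = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$background_lambda <= 0) stop_config("background_lambda must be > 0")
  peaks <- truth_peaks %||% planted_peaks(config)
  n_bins <- config$genome_length %/% config$bin_size
  x <- (seq_len(n_bins) - 0.5) * config$bin_size # bin midpoints, bp
  shape <- matrix(0, nrow = n_bins, ncol = 2,
    dimnames = list(NULL, c("control", "mutant")))
  sd_bp <- config$peak_width / 4
  for (i in seq_len(nrow(peaks))) {
    exc <- class_excess(config, peaks$class[i])
    lo <- max(1L, (peaks$start[i] - 2L * config$peak_width) %/% config$bin_size)
    hi <- min(n_bins, (peaks$end[i] + 2L * config$peak_width) %/% config$bin_size)
    idx <- lo:hi
    g <- exp(-(x[idx] - peaks$center[i])^2 / (2 * sd_bp^2))
    shape[idx, "control"] <- shape[idx, "control"] + exc[["control"]] * g
    shape[idx, "mutant"] <- shape[idx, "mutant"] + exc[["mutant"]] * g
  }
  samples <- c(
    setNames(rep("control", config$n_control_samples),
      paste0("ctrl_", seq_len(config$n_control_samples))),
    setNames(rep("mutant", config$n_mutant_samples),
      paste0("mut_", seq_len(config$n_mutant_samples)))
  )
  depth <- bind_rows(lapply(seq_along(samples), function(i) {
    grp <- samples[[i]]
    d <- withr::with_seed(
      derive_seed(config$seed, 100L + i),
      rpois(n_bins, config$background_lambda + shape[, grp])
    )
    tibble(
      sample = names(samples)[i], group = grp, chrom = "chr1",
      bin = seq_len(n_bins) - 1L, depth = as.numeric(d)
    )
  }))
  exc_tab <- t(vapply(
    peaks$class, function(cl) class_excess(config, cl),
    c(control = 0, mutant = 0)
  ))
  peaks$control_excess <- exc_tab[, "control"]
  peaks$mutant_excess <- exc_tab[, "mutant"]
  list(depth = set_bin_size(depth, config$bin_size), truth_peaks = peaks)
}

#' Simulate an FPKM table with known regulation directions
#'
#' Control FPKM is log-uniform over the configured range; planted DOWN
#' genes are drawn with control FPKM above the downstream analysis gate
#' (> 10) so the planted truth coincides with the recoverable truth.
#' Mutant-line values are control x gene fold x log-normal noise;
#' planted folds keep DOWN ratios <= 0.5, UP ratios >= 2 and null ratios
#' inside [0.8, 1.25] in every line with margin to spare.
#'
#' @param config A [simulation_config()].
#' @return List with `fpkm` (long tibble: gene_id, sample, group, fpkm),
#'   `truth_genes` (tibble: gene_id, direction, fold) and `group_map`.
#' @export
simulate_fpkm <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ex <- config$expression
  if (ex$frac_down + ex$frac_up > 1) stop_config("fraction down + up > 1")
  n <- ex$n_genes
  n_down <- round(ex$frac_down * n)
  n_up <- round(ex$frac_up * n)
  withr::with_seed(derive_seed(config$seed, 37L), {
    direction <- sample(c(
      rep("DOWN", n_down), rep("UP", n_up),
      rep("NONE", n - n_down - n_up)
    ))
    lo <- log10(ex$control_fpkm[1])
    hi <- log10(ex$control_fpkm[2])
    ctrl <- 10^runif(n, lo, hi)
    # DOWN truth requires clearing the control FPKM > 10 analysis gate
    down_lo <- log10(max(12, ex$control_fpkm[1]))
    ctrl[direction == "DOWN"] <- 10^runif(sum(direction == "DOWN"), down_lo, hi)
    fold <- runif(n, ex$fold_null[1], ex$fold_null[2])
    fold[direction == "DOWN"] <- runif(sum(direction == "DOWN"), ex$fold_down[1], ex$fold_down[2])
    fold[direction == "UP"] <- runif(sum(direction == "UP"), ex$fold_up[1], ex$fold_up[2])
    gene_id <- sprintf("G%04d", seq_len(n))
    ctrl_cols <- lapply(seq_len(ex$n_control_samples), function(i) {
      tibble(
        gene_id = gene_id, sample = paste0("rna_ctrl_", i),
        group = "control", fpkm = ctrl
      )
    })
    mut_cols <- lapply(seq_len(ex$n_mutant_lines), function(i) {
      noise <- exp(rnorm(n, 0, ex$noise_sdlog))
      tibble(
        gene_id = gene_id, sample = paste0("rna_mut_", i),
        group = "mutant", fpkm = ctrl * fold * noise
      )
    })
  })
  fpkm <- bind_rows(c(ctrl_cols, mut_cols))
  samples <- unique(fpkm[, c("sample", "group")])
  list(
    fpkm = fpkm,
    truth_genes = tibble(gene_id = gene_id, direction = direction, fold = fold),
    group_map = setNames(samples$group, samples$sample)
  )
}

#' Place simulated gene models relative to planted peaks
#'
#' Planted DOWN genes are placed next to mutant-enriched peaks (one per
#' peak, edge-to-edge gap uniform in `[500, linked_gene_max_gap]`), planted
#' UP genes next to control-enriched peaks, and all remaining genes in a
#' background region at least 12 kb away from every planted peak, so that
#' "DOWN gene within 10 kb of a mutant-enriched peak" has an unambiguous
#' planted truth.
#'
#' @param config A [simulation_config()].
#' @param truth_peaks Planted peak layout.
#' @param truth_genes Gene direction table from [simulate_fpkm()].
#' @return Tibble of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `placement` (`"near_mut_peak"`, `"near_ctrl_peak"`,
#'   `"background"`).
#' @export
simulate_genes <- function(config, truth_peaks, truth_genes) {
  stopifnot(inherits(config, "simulation_config"))
  glen <- config$gene_length
  peaks_end <- max(truth_peaks$end)
  bg_lo <- peaks_end + 12000L
  bg_hi <- config$genome_length - glen - 1L
  if (bg_hi <= bg_lo) stop_config("genome too short for background gene region")
  mut_peaks <- truth_peaks[truth_peaks$class == "MUT_ENRICHED", ]
  ctrl_peaks <- truth_peaks[truth_peaks$class == "CTRL_ENRICHED", ]
  down_ids <- truth_genes$gene_id[truth_genes$direction == "DOWN"]
  up_ids <- truth_genes$gene_id[truth_genes$direction == "UP"]
  withr::with_seed(derive_seed(config$seed, 53L), {
    place_near <- function(ids, pk) {
      n_adj <- min(length(ids), nrow(pk))
      gap <- round(runif(n_adj, 500, config$linked_gene_max_gap))
      tibble(
        gene_id = ids[seq_len(n_adj)],
        start = pk$end[seq_len(n_adj)] + as.integer(gap),
        placement = if (nrow(pk) > 0 && pk$class[1] == "MUT_ENRICHED") {
          "near_mut_peak"
        } else {
          "near_ctrl_peak"
        }
      )
    }
    near_down <- place_near(down_ids, mut_peaks)
    near_up <- place_near(up_ids, ctrl_peaks)
    rest_ids <- setdiff(truth_genes$gene_id, c(near_down$gene_id, near_up$gene_id))
    bg <- tibble(
      gene_id = rest_ids,
      start = as.integer(round(runif(length(rest_ids), bg_lo, bg_hi))),
      placement = "background"
    )
    strands <- sample(c("+", "-"), nrow(truth_genes), replace = TRUE)
  })
  out <- bind_rows(near_down, near_up, bg)
  out <- out[match(truth_genes$gene_id, out$gene_id), ]
  tibble(
    gene_id = out$gene_id, chrom = "chr1",
    start = out$start, end = out$start + glen,
    strand = strands, placement = out$placement
  )
}

#' Simulate a complete two-condition ChIP + RNA experiment
#'
#' Composes [simulate_genome()], [simulate_depth()], [simulate_fpkm()] and
#' [simulate_genes()] under one seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `motif_truth`, `depth`, `truth_peaks`,
#'   `fpkm`, `truth_genes`, `group_map`, `genes`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  gen <- simulate_genome(config)
  dep <- simulate_depth(config, gen$truth_peaks)
  expr <- simulate_fpkm(config)
  genes <- simulate_genes(config, dep$truth_peaks, expr$truth_genes)
  list(
    genome = gen$genome, motif_truth = gen$motif_truth,
    depth = dep$depth, truth_peaks = dep$truth_peaks,
    fpkm = expr$fpkm, truth_genes = expr$truth_genes,
    group_map = expr$group_map, genes = genes
  )
}
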