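# Orchestration of the full simulate -> call -> classify -> motif ->
# cluster -> report chain as one reproducible run: a validated config with
# a single global seed, per-stage serialized intermediates, and a run
# manifest written on success and on handled failure.

#' Full-run configuration
#'
#' @param sim A [simulation_config()] describing the synthetic experiment;
#'   set to `NULL` to analyse files instead (see `inputs`).
#' @param inputs When `sim` is `NULL`: a list with paths `bedgraphs`
#'   (named by sample), `group_map`, `genome_fasta`, `genes`, `fpkm`,
#'   `fpkm_group_map` and `bin_size`.
#' @param peak A [peak_params()].
#' @param classify List: `all_lines` (logical).
#' @param motif List: `k_range`, `alpha`, `max_motifs`,
#'   `similarity_threshold`, `per_kb`.
#' @param cluster List: `k`, `n_restarts`, `purity_min`, `n_top_motifs`,
#'   `standardize`.
#' @param expression List: `pseudocount`, `control_min_fpkm`,
#'   `down_max_ratio`, `up_min_ratio`, `max_distance`, `direction`.
#' @param seed Global seed; all stage seeds derive from it.
#' @return A validated `peakshift_config` object.
#' @export
peakshift_config <- function(sim = simulation_config(),
                             inputs = NULL,
                             peak = peak_params(),
                             classify = list(),
                             motif = list(),
                             cluster = list(),
                             expression = list(),
                             seed = 1L) {
  defaults <- list(
    classify = list(all_lines = FALSE),
    motif = list(
      k_range = 5:9, alpha = 0.01, max_motifs = 25L,
      similarity_threshold = 0.8, per_kb = TRUE
    ),
    cluster = list(
      k = 8L, n_restarts = 5L, purity_min = 0.9, n_top_motifs = 3L,
      standardize = FALSE
    ),
    expression = list(
      pseudocount = 0.1, control_min_fpkm = 10, down_max_ratio = 0.5,
      up_min_ratio = 2, max_distance = 10000, direction = "DOWN"
    )
  )
  merge_block <- function(name, given) {
    unknown <- setdiff(names(given), names(defaults[[name]]))
    if (length(unknown) > 0L) {
      stop_config(paste0(
        "unknown ", name, " settings: ", paste(unknown, collapse = ", ")
      ))
    }
    utils::modifyList(defaults[[name]], given)
  }
  if (is.null(sim) && is.null(inputs)) {
    stop_config("either sim or inputs must be given")
  }
  structure(
    list(
      sim = sim, inputs = inputs, peak = peak,
      classify = merge_block("classify", classify),
      motif = merge_block("motif", motif),
      cluster = merge_block("cluster", cluster),
      expression = merge_block("expression", expression),
      seed = as.integer(seed),
      schema_version = "1"
    ),
    class = "peakshift_config"
  )
}

#' Read a run configuration from YAML
#'
#' The file mirrors the blocks of [peakshift_config()]; unknown keys are
#' rejected.  A `sim` block is passed to [simulation_config()], a `peak`
#' block to [peak_params()].
#'
#' @param path Path to a YAML file.
#' @return A `peakshift_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c(
    "sim", "inputs", "peak", "classify", "motif", "cluster",
    "expression", "seed", "schema_version"
  )
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop_config(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  sim <- if (!is.null(y$sim)) do.call(simulation_config, y$sim) else NULL
  peak <- if (!is.null(y$peak)) do.call(peak_params, y$peak) else peak_params()
  peakshift_config(
    sim = sim, inputs = y$inputs, peak = peak,
    classify = y$classify %||% list(), motif = y$motif %||% list(),
    cluster = y$cluster %||% list(), expression = y$expression %||% list(),
    seed = y$seed %||% 1L
  )
}

write_stage <- function(out_dir, name, df) {
  if (is.null(out_dir)) return(invisible(NULL))
  readr::write_tsv(df, file.path(out_dir, paste0(name, ".tsv")), progress = FALSE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate or ingest, callpeaks, classify,
#' motifs, vectors, cluster, expression, report), serializing every
#' intermediate as TSV under `out_dir` and writing a JSON run manifest
#' with the resolved config and per-stage record counts.  Identical
#' config, inputs and seed give byte-identical outputs.  On a stage
#' failure the partial outputs are retained, the manifest records the
#' failing stage, and the error is re-signalled.
#'
#' @param config A [peakshift_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   serialization.
#' @return A list of all stage results plus the `manifest`, invisibly on
#'   error.
#' @export
run_pipeline <- function(config = peakshift_config(), out_dir = NULL) {
  stopifnot(inherits(config, "peakshift_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(
    software = paste0("peakshift ", as.character(utils::packageVersion("peakshift"))),
    schema_version = config$schema_version,
    seed = config$seed,
    stages = list(),
    status = "running"
  )
  res <- list()
  current_stage <- NA_character_
  record <- function(stage, n, secs) {
    manifest$stages[[stage]] <<- list(records = n, seconds = round(secs, 3))
  }
  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) {
      manifest$failed_stage <<- current_stage
      manifest$error <<- conditionMessage(error)
    }
    manifest$config <<- config_as_list(config)
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
    }
  }
  run_stage <- function(stage, expr) {
    current_stage <<- stage
    t0 <- proc.time()[["elapsed"]]
    out <- expr()
    n <- if (is.data.frame(out)) nrow(out) else NA_integer_
    record(stage, n, proc.time()[["elapsed"]] - t0)
    out
  }
  tryCatch(
    {
      if (!is.null(config$sim)) {
        exp_data <- run_stage("simulate", function() {
          simulate_experiment(config$sim)
        })
      } else {
        exp_data <- run_stage("ingest", function() load_inputs(config$inputs))
      }
      if (!is.null(out_dir) && !is.null(exp_data$truth_peaks)) {
        write_stage(out_dir, "truth_peaks", exp_data$truth_peaks)
        write_stage(out_dir, "truth_genes", exp_data$truth_genes)
      }
      peaks <- run_stage("callpeaks", function() {
        call_peaks(exp_data$depth, config$peak)
      })
      write_stage(out_dir, "peaks", peaks)
      diff_peaks <- run_stage("classify", function() {
        classify_peaks(peaks, exp_data$depth, all_lines = config$classify$all_lines)
      })
      write_stage(out_dir, "diff_peaks", diff_peaks)
      if (!is.null(out_dir)) {
        for (cl in c("PEAKS_2_0", "PEAKS_0_5")) {
          sub <- filter(diff_peaks, .data$label == cl)
          bed <- tibble(
            chrom = sub$chrom, start = sub$start, end = sub$end,
            name = sub$peak_id, score = 0L, strand = "."
          )
          readr::write_tsv(
            bed,
            file.path(out_dir, paste0(tolower(sub("PEAKS", "peaks", cl)), ".bed")),
            col_names = FALSE, progress = FALSE
          )
        }
      }
      catalog <- run_stage("motifs", function() {
        per_class <- lapply(c("PEAKS_2_0", "PEAKS_0_5"), function(cl) {
          pk <- filter(diff_peaks, .data$label == cl)
          if (nrow(pk) < 10L) {
            return(tibble(
              consensus = character(), k = integer(),
              source_class = character(), p_bonf = numeric(),
              n_kmers = integer()
            ))
          }
          discover_motifs(
            peak_sequences(pk, exp_data$genome),
            source_class = cl,
            k_range = config$motif$k_range, alpha = config$motif$alpha,
            max_motifs = config$motif$max_motifs,
            seed = derive_seed(config$seed, if (cl == "PEAKS_2_0") 201L else 202L)
          )
        })
        consolidate_motifs(bind_rows(per_class), config$motif$similarity_threshold)
      })
      write_stage(out_dir, "motif_catalog", catalog)
      vectors <- run_stage("vectors", function() {
        build_frequency_vectors(diff_peaks, exp_data$genome, catalog,
          per_kb = config$motif$per_kb
        )
      })
      write_stage(out_dir, "frequency_vectors", vectors)
      model <- run_stage("cluster", function() {
        fit_kmeans(vectors,
          k = config$cluster$k,
          seed = derive_seed(config$seed, 301L),
          n_restarts = config$cluster$n_restarts,
          standardize = config$cluster$standardize
        )
      })
      composition <- cluster_composition(model)
      selected <- select_group_specific_clusters(
        model, composition,
        purity_min = config$cluster$purity_min,
        n_top_motifs = config$cluster$n_top_motifs
      )
      write_stage(out_dir, "cluster_assignments", model$assignments)
      write_stage(out_dir, "cluster_composition", composition)
      write_stage(
        out_dir, "selected_clusters",
        mutate(selected, top_motifs = map_chr(
          .data$top_motifs,
          ~ paste(.x, collapse = ",")
        ))
      )
      changes <- run_stage("expression", function() {
        compute_fold_changes(exp_data$fpkm,
          pseudocount = config$expression$pseudocount,
          control_min_fpkm = config$expression$control_min_fpkm,
          down_max_ratio = config$expression$down_max_ratio,
          up_min_ratio = config$expression$up_min_ratio
        )
      })
      write_stage(out_dir, "fold_changes", changes)
      links <- link_peaks_to_genes(diff_peaks, exp_data$genes,
        max_distance = config$expression$max_distance
      )
      write_stage(out_dir, "peak_gene_links", links)
      report <- run_stage("report", function() {
        build_cluster_gene_report(selected, model, diff_peaks, links, changes,
          direction = config$expression$direction
        )
      })
      write_stage(out_dir, "cluster_gene_report", report)
      finish("success")
      res <- list(
        data = exp_data, peaks = peaks, diff_peaks = diff_peaks,
        catalog = catalog, vectors = vectors, model = model,
        composition = composition, selected = selected, changes = changes,
        links = links, report = report, manifest = manifest
      )
      res
    },
    error = function(e) {
      finish("failed", e)
      abort(
        paste0("pipeline failed at stage '", current_stage, "': ", conditionMessage(e)),
        class = "peakshift_pipeline_error", parent = e
      )
    }
  )
}

config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      lapply(x, strip)
    } else if (is.function(x)) {
      "<function>"
    } else {
      x
    }
  }
  strip(unclass(config))
}

load_inputs <- function(inputs) {
  req <- c("bedgraphs", "group_map", "genome_fasta", "genes", "fpkm", "fpkm_group_map")
  missing <- setdiff(req, names(inputs))
  if (length(missing) > 0L) {
    stop_config(paste0("missing inputs: ", paste(missing, collapse = ", ")))
  }
  bs <- inputs$bin_size %||% 10L
  tracks <- lapply(inputs$bedgraphs, read_depth_bedgraph, bin_size = bs)
  list(
    genome = read_genome_fasta(inputs$genome_fasta),
    depth = combine_depth_tracks(tracks, unlist(inputs$group_map)),
    genes = read_genes(inputs$genes),
    fpkm = read_fpkm_table(inputs$fpkm, unlist(inputs$fpkm_group_map)),
    truth_peaks = NULL, truth_genes = NULL
  )
}
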