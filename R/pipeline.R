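# End-to-end orchestration: sequence pipeline (curation -> linker stats)
# and trajectory pipeline, with reproducible TSV/JSON outputs and a manifest.

#' Build a pipeline configuration
#'
#' @param hits,fasta,domains,lineage,ptm Input paths for the sequence
#'   pipeline (lineage and ptm optional).
#' @param pdb Input multi-model PDB path for the trajectory pipeline.
#' @param out_dir Output directory.
#' @param min_qcov,min_pident Hit-filter thresholds in percent.
#' @param class_thresholds Fixed short/long linker-length boundaries.
#' @param mixture_k,mixture_max_iter,mixture_tol Mixture-fit options.
#' @param ptm_cutoffs PTM score cutoffs.
#' @param ref_frame Trajectory reference frame (1-based).
#' @param marker_res_i,marker_res_j,marker_atom Interdomain distance markers.
#' @param selection Atom selection for RMSD.
#' @param frame_interval Nanoseconds per frame.
#' @param time_bins,distance_bins Density-map bin counts.
#' @param seed Seed recorded in every output header.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(hits = NULL, fasta = NULL, domains = NULL,
                            lineage = NULL, ptm = NULL, pdb = NULL,
                            out_dir = tempfile("limlinker_run_"),
                            min_qcov = 75, min_pident = 30,
                            class_thresholds = c(40, 70),
                            mixture_k = 3L, mixture_max_iter = 500L,
                            mixture_tol = 1e-8,
                            ptm_cutoffs = c(0.8, 0.9),
                            ref_frame = 1L,
                            marker_res_i = 10L, marker_res_j = 176L,
                            marker_atom = "CA", selection = "backbone",
                            frame_interval = 0.2,
                            time_bins = 10L, distance_bins = 20L,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (min_qcov < 0 || min_qcov > 100 || min_pident < 0 || min_pident > 100) {
    abort("Filter thresholds must lie in [0, 100].")
  }
  structure(cfg, class = "pipeline_config")
}

pkg_version <- function() {
  as.character(utils::packageVersion("limlinker"))
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

# write a tibble as TSV under a provenance header comment
write_output_tsv <- function(df, path, config) {
  hdr <- sprintf("# limlinker %s | config %s | seed %d", pkg_version(),
                 config_hash(config), config$seed)
  writeLines(hdr, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  path
}

write_manifest <- function(config, outputs, dir) {
  manifest <- list(tool = "limlinker", version = pkg_version(),
                   config_hash = config_hash(config),
                   seed = config$seed, outputs = basename(unname(outputs)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the sequence pipeline end to end
#'
#' Reads the hit, FASTA, domain and (optionally) lineage and PTM tables,
#' applies the coverage/identity filters, classifies architectures,
#' segments dual-LIM sequences, and emits the linker statistics: length
#' histogram, propensity table, mixture fit, linker-class labels, taxonomy
#' frequencies and PTM summary. Every output carries a header comment with
#' the tool version, config hash and seed; a JSON manifest lists the
#' outputs. Reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()] with `hits`, `fasta` and `domains`
#'   set (lineage and ptm optional).
#' @return Invisibly, a list with the in-memory results and `paths`.
#' @export
run_sequence_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  hits <- stage("parse_hits", read_hit_table(config$hits))
  sequences <- stage("read_fasta", read_fasta_tbl(config$fasta))
  domains <- stage("parse_domains", read_domtblout(config$domains))

  kept <- filter_hits(hits, config$min_qcov, config$min_pident)
  if (nrow(kept) == 0L) {
    warn("No hits pass the coverage/identity filters; downstream tables are empty.")
  }
  keep_ids <- intersect(sequences$seqid, kept$seqid)
  sequences_kept <- sequences[sequences$seqid %in% keep_ids, ]
  domains_kept <- domains[domains$seqid %in% keep_ids, ]
  arch <- classify_architecture(domains_kept, seqids = keep_ids)
  segments <- segment_sequences(sequences_kept, domains_kept)

  paths <- character(0)
  p <- function(df, file) write_output_tsv(df, file.path(config$out_dir, file),
                                           config)
  paths["filtered_hits"] <- p(kept, "filtered_hits.tsv")
  paths["architecture"] <- p(arch, "architecture.tsv")
  paths["segments"] <- p(
    dplyr::select(segments, -dplyr::any_of("sequence")), "segments.tsv")

  hist_tbl <- propensity <- mixture <- labels_tbl <- taxon_freq <- ptm_summary <- NULL
  if (nrow(segments) > 0L) {
    hist_tbl <- region_length_distribution(segments, "linker")
    propensity <- compute_propensity(segments)
    paths["length_histogram"] <- p(tibble::as_tibble(hist_tbl),
                                   "linker_length_histogram.tsv")
    paths["propensity"] <- p(tibble::as_tibble(propensity), "propensity.tsv")
    if (nrow(segments) >= 3L * config$mixture_k) {
      mixture <- fit_length_mixture(segments$linker_length,
                                    k = config$mixture_k, seed = config$seed,
                                    max_iter = config$mixture_max_iter,
                                    tol = config$mixture_tol)
      mj <- file.path(config$out_dir, "mixture.json")
      jsonlite::write_json(
        list(weights = mixture$weights, means = mixture$means,
             sds = mixture$sds, class_boundaries = mixture$class_boundaries,
             seed = config$seed, config_hash = config_hash(config)),
        mj, auto_unbox = FALSE, digits = NA, pretty = TRUE)
      paths["mixture"] <- mj
    }
    labels_tbl <- tibble::tibble(
      seqid = segments$seqid,
      linker_length = segments$linker_length,
      linker_class = classify_linker_lengths(segments$linker_length,
                                             thresholds = config$class_thresholds))
    paths["linker_classes"] <- p(labels_tbl, "linker_classes.tsv")
    if (!is.null(config$lineage)) {
      lineage <- stage("parse_lineage",
                       readr::read_tsv(config$lineage, progress = FALSE,
                                       col_types = readr::cols(.default = "c")))
      taxon_freq <- taxonomy_frequency(labels_tbl, lineage)
      paths["taxon_frequency"] <- p(tibble::as_tibble(taxon_freq),
                                    "taxon_frequency.tsv")
    }
    if (!is.null(config$ptm)) {
      ptm <- stage("parse_ptm",
                   readr::read_tsv(config$ptm, progress = FALSE,
                                   col_types = readr::cols(
                                     seqid = "c", position = "i",
                                     ptm_type = "c", score = "d")))
      ptm_summary <- summarize_ptms(ptm, segments, config$ptm_cutoffs)
      paths["ptm_summary"] <- p(tibble::as_tibble(ptm_summary),
                                "ptm_summary.tsv")
    }
  } else {
    for (f in c("linker_length_histogram.tsv", "propensity.tsv",
                "linker_classes.tsv")) {
      paths[sub("\\.tsv$", "", f)] <- p(tibble::tibble(), f)
    }
  }
  paths["manifest"] <- write_manifest(config, paths, config$out_dir)
  invisible(list(hits = kept, architecture = arch, segments = segments,
                 histogram = hist_tbl, propensity = propensity,
                 mixture = mixture, linker_classes = labels_tbl,
                 taxon_frequency = taxon_freq, ptm_summary = ptm_summary,
                 paths = paths))
}

#' Run the trajectory pipeline end to end
#'
#' Reads a multi-model PDB and emits the per-frame series (RMSD, radius of
#' gyration, interdomain distance), per-residue RMSF, time-distance density
#' map, phi/psi arrow map (first vs middle vs last frame) and the
#' secondary-structure timeline. Single-frame trajectories skip RMSF and
#' the arrow map with a warning.
#'
#' @param config A [pipeline_config()] with `pdb` set.
#' @return Invisibly, a list with the in-memory results and `paths`.
#' @export
run_trajectory_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- tryCatch(read_multimodel_pdb(config$pdb, config$frame_interval),
                   error = function(e) {
                     abort(sprintf("Stage 'read_pdb' failed: %s",
                                   conditionMessage(e)))
                   })
  nf <- n_frames(traj)
  paths <- character(0)
  p <- function(df, file) write_output_tsv(df, file.path(config$out_dir, file),
                                           config)

  rmsd <- rmsd_series(traj, config$ref_frame, config$selection)
  rog <- rog_series(traj, config$selection)
  dist <- interdomain_distance_series(traj, config$marker_res_i,
                                      config$marker_res_j, config$marker_atom)
  series <- dplyr::left_join(
    dplyr::left_join(rmsd, dplyr::select(rog, "frame", "rog"), by = "frame"),
    dplyr::select(dist, "frame", "distance"), by = "frame")
  paths["series"] <- p(series, "frame_series.tsv")

  density <- distance_time_density(dist, config$time_bins,
                                   config$distance_bins)
  paths["distance_density"] <- p(tibble::as_tibble(density),
                                 "distance_density.tsv")

  dihedrals <- compute_phi_psi(traj)
  sse <- assign_secondary_structure(dihedrals)
  paths["sse_timeline"] <- p(sse, "sse_timeline.tsv")

  rmsf <- arrows <- NULL
  if (nf >= 2L) {
    rmsf <- rmsf_per_residue(traj, ref_frame = config$ref_frame)
    paths["rmsf"] <- p(rmsf, "rmsf.tsv")
    mid <- max(1L, (nf + 1L) %/% 2L)
    arrows <- dplyr::bind_rows(
      dplyr::mutate(dihedral_arrow_map(dihedrals, 1L, mid),
                    comparison = sprintf("frame1_vs_frame%d", mid)),
      dplyr::mutate(dihedral_arrow_map(dihedrals, mid, nf),
                    comparison = sprintf("frame%d_vs_frame%d", mid, nf)))
    paths["arrow_map"] <- p(arrows, "arrow_map.tsv")
  } else {
    warn("Single-frame trajectory: RMSF and arrow map skipped.")
  }
  paths["manifest"] <- write_manifest(config, paths, config$out_dir)
  invisible(list(trajectory = traj, series = series, density = density,
                 dihedrals = dihedrals, sse = sse, rmsf = rmsf,
                 arrow_map = arrows, paths = paths))
}
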