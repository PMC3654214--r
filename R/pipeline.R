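#' Pipeline configuration
#'
#' @param input_mode `"synthetic"` (generate data in-process),
#'   `"timeseries"` (read TSV regional series) or `"volumes"` (parcellate
#'   4-D NIfTI volumes first).
#' @param band wavelet sub-band in Hz used before correlation.
#' @param thresholds strictly increasing correlation thresholds in (0, 1).
#' @param n_null null graphs per small-world estimate.
#' @param correction multiple-comparison correction, `"bh"` or
#'   `"bonferroni"`.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory.
#' @param synthetic a `synthetic_config` (synthetic mode).
#' @param timeseries_files named list with `pre` and `post` character
#'   vectors of TSV paths, matched by position (timeseries mode).
#' @param sampling_interval TR in seconds for timeseries mode.
#' @param run_smallworld compute small-world statistics per
#'   subject/session/threshold (the slowest stage; disable for quick runs).
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "timeseries",
                                           "volumes"),
                            band = c(0.06, 0.1),
                            thresholds = c(0.3, 0.4, 0.5, 0.6, 0.7),
                            n_null = 1000L,
                            correction = c("bh", "bonferroni"),
                            seed = 1L, out_dir = "restgraph_out",
                            synthetic = NULL, timeseries_files = NULL,
                            sampling_interval = 2.8,
                            run_smallworld = TRUE) {
  input_mode <- match.arg(input_mode)
  correction <- match.arg(correction)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must be strictly increasing within (0, 1)")
  }
  if (input_mode == "synthetic" && is.null(synthetic)) {
    synthetic <- synthetic_config(seed = seed)
  }
  structure(list(input_mode = input_mode, band = band,
                 thresholds = thresholds, n_null = as.integer(n_null),
                 correction = correction, seed = as.integer(seed),
                 out_dir = out_dir, synthetic = synthetic,
                 timeseries_files = timeseries_files,
                 sampling_interval = sampling_interval,
                 run_smallworld = isTRUE(run_smallworld)),
            class = "pipeline_config")
}

#' Parcellate a 4-D volume into regional mean time series
#'
#' Averages the functional signal over the voxels of each positive integer
#' label at every timepoint — the standard atlas-based reduction of a
#' volumetric acquisition to one series per anatomical region. Volumes are
#' used in their native orientation; the label grid must match the
#' functional grid exactly.
#'
#' @param volumes 4-D numeric array (x, y, z, time) or path to a NIfTI
#'   file (read with RNifti when installed).
#' @param labels 3-D integer array of region labels (0 = background) or a
#'   NIfTI path; spatial dimensions must equal those of `volumes`.
#' @param sampling_interval TR in seconds.
#' @param label_names optional named character vector mapping label values
#'   to region names.
#' @return a `regional_ts`, regions ordered by label value.
#' @export
parcellate <- function(volumes, labels, sampling_interval = 2.8,
                       label_names = NULL) {
  read_nii <- function(p) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI files requires the RNifti package")
    }
    as.array(RNifti::readNifti(p))
  }
  if (is.character(volumes)) volumes <- read_nii(volumes)
  if (is.character(labels)) labels <- read_nii(labels)
  if (length(dim(volumes)) != 4L) stop("functional input must be 4-D")
  if (!identical(dim(volumes)[1:3], dim(labels)[1:3])) {
    stop("label and functional grids have different spatial dimensions")
  }
  lab <- as.integer(round(labels))
  values <- sort(unique(lab[lab > 0L]))
  if (length(values) == 0L) stop("label volume contains no positive labels")
  n_t <- dim(volumes)[4L]
  flat <- matrix(volumes, ncol = n_t)   # voxels x time
  out <- t(vapply(values, function(v) colMeans(flat[lab == v, , drop = FALSE]),
                  numeric(n_t)))
  rl <- if (!is.null(label_names)) unname(label_names[as.character(values)])
        else sprintf("region_%03d", values)
  regional_ts(out, rl, sampling_interval)
}

#' Run the full connectivity analysis pipeline
#'
#' Executes the complete analysis flow for every subject and session:
#' wavelet sub-band filtering, Pearson correlation adjacency matrix, node
#' strength on the complete weighted graph, thresholding/binarization at
#' every configured threshold, all graph metrics, Louvain community
#' structure and participation coefficients on the group-mean graph,
#' small-world statistics against degree-preserving nulls, and the paired
#' pre/post comparison. All artefacts are written under the configured
#' output directory along with a JSON run manifest (effective config,
#' seed, package version, and a content hash per output file).
#'
#' @param config a `pipeline_config`.
#' @return list with `metrics` (combined long table), `comparison`,
#'   `smallworld` (per subject/session/threshold results, when enabled),
#'   `community` (group-mean partitions per session/threshold) and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  }

  # ---- load or generate the regional time series -------------------------
  if (config$input_mode == "synthetic") {
    log_stage("generating synthetic dataset (%d subjects)",
              config$synthetic$n_subjects)
    ds <- generate_dataset(config$synthetic)
    sessions <- lapply(ds$subjects, function(s) s[c("pre", "post")])
  } else if (config$input_mode == "timeseries") {
    tf <- config$timeseries_files
    if (is.null(tf$pre) || is.null(tf$post) ||
        length(tf$pre) != length(tf$post)) {
      stop("timeseries mode needs matched pre and post file lists")
    }
    sessions <- lapply(seq_along(tf$pre), function(i) {
      list(pre = read_regional_ts(tf$pre[i], config$sampling_interval),
           post = read_regional_ts(tf$post[i], config$sampling_interval))
    })
    names(sessions) <- sprintf("sub%02d", seq_along(sessions))
  } else {
    stop("volumes mode: parcellate() the volumes first and run in ",
         "timeseries mode")
  }

  # ---- per subject-session: filter, correlate, threshold, measure --------
  metrics <- list()
  cms <- list()
  sw <- list()
  for (sub in names(sessions)) {
    for (ses in c("pre", "post")) {
      log_stage("subject %s session %s: filter + correlate", sub, ses)
      filt <- wavelet_subband_filter(sessions[[sub]][[ses]], config$band)
      cm <- correlation_matrix(filt)
      cms[[paste(sub, ses, sep = ".")]] <- cm
      write_connectivity_matrix(
        cm, file.path(config$out_dir,
                      sprintf("connectivity_%s_%s.tsv", sub, ses)))
      for (th in config$thresholds) {
        g <- threshold_binarize(cm, th)
        metrics[[length(metrics) + 1L]] <-
          graph_metric_table(g, cm, subject = sub, session = ses)
        if (config$run_smallworld && n_edges(g) >= 2L) {
          res <- small_worldness(g, n_null = config$n_null,
                                 seed = config$seed)
          sw[[sprintf("%s.%s.r%g", sub, ses, th)]] <- res
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics_path <- file.path(config$out_dir, "metrics.tsv")
  utils::write.table(metrics, metrics_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ---- community structure on the group-mean graph per session -----------
  log_stage("community detection on group-mean graphs")
  community <- list()
  for (ses in c("pre", "post")) {
    keys <- grep(paste0("\\.", ses, "$"), names(cms), value = TRUE)
    mean_w <- Reduce(`+`, lapply(cms[keys], `[[`, "weights")) / length(keys)
    mean_cm <- connectivity_matrix(mean_w, cms[[keys[1L]]]$region_labels)
    for (th in config$thresholds) {
      g <- threshold_binarize(mean_cm, th)
      if (n_edges(g) < 1L) next
      part <- louvain_partition(g, seed = config$seed)
      pc <- participation_coefficients(g, part)
      key <- sprintf("%s.r%g", ses, th)
      community[[key]] <- list(partition = part, participation = pc)
      write_partition(part, file.path(config$out_dir,
                                      sprintf("partition_%s_r%g.tsv",
                                              ses, th)))
    }
  }

  # ---- paired pre/post comparison ----------------------------------------
  log_stage("pre/post comparison")
  comparison <- compare_sessions(metrics[metrics$session == "pre", ],
                                 metrics[metrics$session == "post", ],
                                 correction = config$correction)
  write_comparison(comparison,
                   file.path(config$out_dir, "comparison.tsv"))
  for (key in names(sw)) {
    write_small_world(sw[[key]],
                      file.path(config$out_dir,
                                sprintf("smallworld_%s.json", key)))
  }

  # ---- manifest ----------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("restgraph")),
    seed = config$seed,
    config = .config_as_list(config),
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  list(metrics = metrics, comparison = comparison, smallworld = sw,
       community = community, manifest_path = manifest_path)
}

.config_as_list <- function(config) {
  x <- unclass(config)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  x$timeseries_files <- NULL
  x
}

#' Verify a pipeline run manifest
#'
#' Recomputes the content hash of every file listed in a run manifest and
#' reports mismatches — the idempotence check for reruns with the same
#' seed.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @return TRUE if all hashes match; otherwise a character vector of
#'   mismatched file names.
#' @export
verify_manifest <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  bad <- character(0)
  for (o in man$outputs) {
    h <- unname(tools::md5sum(file.path(dir, o$path)))
    if (!identical(h, o$md5)) bad <- c(bad, o$path)
  }
  if (length(bad) == 0L) TRUE else bad
}
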