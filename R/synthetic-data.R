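#' Configuration for the synthetic resting-state dataset generator
#'
#' Describes a multi-subject pre/post study with planted modular
#' connectivity: regions fall into modules, within-module region pairs
#' correlate at `r_within` and between-module pairs at `r_between` in the
#' first (pre) session, and within-module correlations change by
#' `post_delta` in the second (post) session — emulating a learning-induced
#' connectivity increase (positive delta) or a decrease (negative delta).
#' Defaults mirror a typical resting-state acquisition: 116 atlas regions,
#' TR = 2.8 s, a 10-minute run of 214 volumes, and fluctuations confined to
#' the 0.01–0.1 Hz band.
#'
#' @param n_subjects subjects per group.
#' @param n_regions number of regions (nodes).
#' @param n_timepoints volumes per session.
#' @param sampling_interval TR in seconds.
#' @param module_sizes integer vector summing to `n_regions`; defaults to a
#'   near-even split into `4` modules.
#' @param r_within within-module correlation in \[0, 1).
#' @param r_between between-module correlation in \[0, r_within\].
#' @param post_delta signed within-module correlation increment applied in
#'   the post session; `|r_within + post_delta|` must stay below 1.
#' @param band frequency band of the fluctuations, Hz.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param seed master RNG seed; spawns per-subject substreams.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 12L, n_regions = 116L,
                             n_timepoints = 214L, sampling_interval = 2.8,
                             module_sizes = NULL, r_within = 0.5,
                             r_between = 0.1, post_delta = 0.1,
                             band = c(0.01, 0.1), noise_sd = 0.2,
                             seed = 1L) {
  if (is.null(module_sizes)) {
    k <- 4L
    base <- n_regions %/% k
    module_sizes <- rep(base, k)
    module_sizes[seq_len(n_regions %% k)] <-
      module_sizes[seq_len(n_regions %% k)] + 1L
  }
  if (sum(module_sizes) != n_regions) {
    stop("module_sizes must sum to n_regions")
  }
  if (r_within < 0 || r_within >= 1) stop("r_within must be in [0, 1)")
  if (r_between < 0 || r_between > r_within) {
    stop("r_between must be in [0, r_within]")
  }
  if (abs(r_within + post_delta) >= 1) {
    stop("|r_within + post_delta| must be below 1")
  }
  nyq <- 1 / (2 * sampling_interval)
  if (band[2L] > nyq + 1e-12) {
    stop("band upper edge exceeds the Nyquist frequency ", signif(nyq, 4))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 n_timepoints = as.integer(n_timepoints),
                 sampling_interval = sampling_interval,
                 module_sizes = as.integer(module_sizes),
                 r_within = r_within, r_between = r_between,
                 post_delta = post_delta, band = band,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# block correlation matrix with r_within inside planted modules and
# r_between elsewhere; unit diagonal
.planted_correlation <- function(module_sizes, r_within, r_between,
                                 delta = 0) {
  n <- sum(module_sizes)
  membership <- rep(seq_along(module_sizes), module_sizes)
  R <- matrix(r_between, n, n)
  same <- outer(membership, membership, `==`)
  R[same] <- r_within + delta
  diag(R) <- 1
  list(R = R, membership = membership)
}

# project a symmetric matrix to the nearest (Frobenius) positive
# semi-definite matrix by clipping negative eigenvalues, then restore the
# unit diagonal
.nearest_psd <- function(R, eps = 1e-10) {
  ee <- eigen(R, symmetric = TRUE)
  if (min(ee$values) >= -eps) return(list(R = R, adjusted = FALSE))
  vals <- pmax(ee$values, eps)
  R2 <- ee$vectors %*% (vals * t(ee$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  list(R = (R2 + t(R2)) / 2, adjusted = TRUE)
}

# band-limited correlated Gaussian series: filter white noise rows with a
# zero-phase band-pass, standardize, then impose the target correlation
# with the symmetric matrix square root. The signal correlation is inflated
# to compensate for the white measurement noise added afterwards, so the
# sample correlation of the OBSERVED series converges to the planted R.
.correlated_band_noise <- function(R, n_timepoints, fs, band, noise_sd) {
  n <- nrow(R)
  R_sig <- (1 + noise_sd^2) * R
  diag(R_sig) <- 1
  R_sig <- .nearest_psd(R_sig)$R
  raw <- matrix(stats::rnorm(n * n_timepoints), n, n_timepoints)
  filt <- t(apply(raw, 1L, .fft_bandpass, fs = fs, band = band))
  filt <- filt / apply(filt, 1L, stats::sd)
  ee <- eigen(R_sig, symmetric = TRUE)
  sqrtR <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  x <- sqrtR %*% filt
  if (noise_sd > 0) {
    x <- x + noise_sd * matrix(stats::rnorm(n * n_timepoints),
                               n, n_timepoints)
  }
  x
}

#' Generate a synthetic pre/post resting-state dataset
#'
#' Each subject gets one pre-session and one post-session regional time
#' series matrix. Region signals are band-limited Gaussian processes whose
#' zero-lag correlation structure equals the planted block matrix (within
#' sampling error); the post session differs only in the within-module
#' correlation level. Generation is fully deterministic given the config
#' seed, with independent per-subject substreams so any subject can be
#' regenerated alone.
#'
#' @param config a `synthetic_config`.
#' @return a `synthetic_dataset`: list with `subjects` (per subject, a list
#'   with `pre` and `post` `regional_ts`), `ground_truth` (planted module
#'   `membership` and per-session planted correlation matrices `R_pre`,
#'   `R_post`, plus `psd_adjusted` flags) and the `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  fs <- 1 / config$sampling_interval

  pre <- .planted_correlation(config$module_sizes, config$r_within,
                              config$r_between)
  post <- .planted_correlation(config$module_sizes, config$r_within,
                               config$r_between, delta = config$post_delta)
  pre_psd <- .nearest_psd(pre$R)
  post_psd <- .nearest_psd(post$R)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)

  labels <- sprintf("region_%03d", seq_len(config$n_regions))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(subject_seeds[s])
    make_session <- function(R) {
      x <- .correlated_band_noise(R, config$n_timepoints, fs,
                                  config$band, config$noise_sd)
      regional_ts(x, labels, config$sampling_interval)
    }
    list(pre = make_session(pre_psd$R), post = make_session(post_psd$R))
  })
  names(subjects) <- sprintf("sub%02d", seq_len(config$n_subjects))

  structure(list(
    subjects = subjects,
    ground_truth = list(membership = pre$membership,
                        R_pre = pre_psd$R, R_post = post_psd$R,
                        psd_adjusted = c(pre = pre_psd$adjusted,
                                         post = post_psd$adjusted)),
    config = config), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d subjects x 2 sessions, %d regions x %d timepoints\n",
    x$config$n_subjects, x$config$n_regions, x$config$n_timepoints))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One TSV per subject-session (regions as rows) plus a JSON sidecar with
#' the config and ground truth (module membership and any PSD adjustment;
#' planted matrices are reproducible from the config and are not
#' duplicated).
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return character vector of file paths written, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(ds$subjects)) {
    for (ses in c("pre", "post")) {
      p <- file.path(dir, sprintf("%s_%s.tsv", s, ses))
      write_regional_ts(ds$subjects[[s]][[ses]], p)
      paths <- c(paths, p)
    }
  }
  sidecar <- file.path(dir, "dataset.json")
  jsonlite::write_json(
    list(config = unclass(ds$config),
         membership = ds$ground_truth$membership,
         psd_adjusted = as.list(ds$ground_truth$psd_adjusted)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
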