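#' Regional BOLD time series
#'
#' Container for one subject-session matrix of region-wise signals: a
#' regions x timepoints numeric matrix, unique region labels and the
#' sampling interval (repetition time) in seconds.
#'
#' @param values numeric matrix, regions in rows, timepoints in columns.
#' @param region_labels character vector of unique region identifiers.
#' @param sampling_interval sampling interval (TR) in seconds.
#' @return an object of class `regional_ts`.
#' @export
regional_ts <- function(values, region_labels = rownames(values),
                        sampling_interval = 2.8) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series must not contain missing values")
  if (ncol(values) < 2L) stop("need at least 2 timepoints")
  if (is.null(region_labels)) {
    region_labels <- sprintf("region_%03d", seq_len(nrow(values)))
  }
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  if (length(region_labels) != nrow(values)) {
    stop("one label per region required")
  }
  rownames(values) <- region_labels
  structure(list(values = values,
                 region_labels = as.character(region_labels),
                 sampling_interval = as.numeric(sampling_interval)),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("regional_ts: %d regions x %d timepoints, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$sampling_interval))
  invisible(x)
}

#' Read regional time series from delimited text
#'
#' Expects regions in rows with the first column holding the region label
#' and the remaining columns the timepoints.
#'
#' @param path TSV/CSV file path.
#' @param sampling_interval TR in seconds.
#' @param sep field separator (tab by default).
#' @return a `regional_ts`.
#' @export
read_regional_ts <- function(path, sampling_interval = 2.8, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  values <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  regional_ts(values, labels, sampling_interval)
}

#' Write regional time series as TSV
#' @param ts a `regional_ts`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_regional_ts <- function(ts, path) {
  df <- data.frame(region = ts$region_labels, ts$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(ts$values))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson correlation (adjacency) matrix
#'
#' Computes the Pearson correlation between every pair of regional time
#' series, giving the weighted adjacency matrix of the functional
#' connectivity network. The diagonal is defined as zero: self-connections
#' carry no information and are excluded from all downstream measures.
#'
#' @param ts a `regional_ts`; every region must have nonzero variance.
#' @return an object of class `connectivity_matrix`: list with `weights`
#'   (symmetric matrix, zero diagonal, entries in \[-1, 1\]) and
#'   `region_labels`.
#' @export
correlation_matrix <- function(ts) {
  v <- apply(ts$values, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance region(s): ",
         paste(ts$region_labels[v == 0], collapse = ", "))
  }
  w <- stats::cor(t(ts$values))
  diag(w) <- 0
  connectivity_matrix(w, ts$region_labels)
}

#' Connectivity matrix constructor
#' @param weights symmetric numeric matrix of pairwise Pearson correlations.
#' @param region_labels node labels.
#' @return a `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, region_labels = rownames(weights)) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("weights must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  if (any(weights < -1 - 1e-10) || any(weights > 1 + 1e-10)) {
    stop("correlations must lie in [-1, 1]")
  }
  diag(weights) <- 0
  if (is.null(region_labels)) {
    region_labels <- sprintf("region_%03d", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights,
                 region_labels = as.character(region_labels)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d x %d regions\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Write a connectivity matrix as TSV
#' @param cm a `connectivity_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path) {
  df <- data.frame(region = cm$region_labels, cm$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold and binarize a connectivity matrix
#'
#' An edge is kept between regions i != j whenever the raw (signed)
#' correlation w_ij meets the threshold, w_ij >= r. Negative correlations
#' never become edges, and ties at the threshold are kept.
#'
#' @param cm a `connectivity_matrix`.
#' @param r threshold in (0, 1).
#' @return a `binary_graph` with the threshold recorded.
#' @export
threshold_binarize <- function(cm, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("threshold r must be a single value in (0, 1)")
  }
  A <- cm$weights >= r
  diag(A) <- FALSE
  graph_from_adjacency(A, threshold_r = r, labels = cm$region_labels)
}

#' Node strength
#'
#' Strength of region i is the sum of its connection weights over all other
#' regions, S_i = sum_j w_ij (j != i), computed on the complete weighted
#' correlation matrix (never on a thresholded graph). The graph strength is
#' the mean of S_i over regions.
#'
#' @param cm a `connectivity_matrix`.
#' @return list with `per_node` (named numeric) and `mean`.
#' @export
node_strength <- function(cm) {
  s <- rowSums(cm$weights)   # diagonal already zero
  names(s) <- cm$region_labels
  list(per_node = s, mean = mean(s))
}
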