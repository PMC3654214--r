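#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired Wilcoxon test: zero differences are dropped, ties are
#' mid-ranked, the p-value comes from exact enumeration for small samples
#' (n <= 25 after zero removal, no ties) and from the normal approximation
#' with continuity correction otherwise.
#'
#' @param x,y paired numeric vectors of equal length; fewer than 5 nonzero
#'   differences (including the all-zero case) leaves the test undefined
#'   and is flagged rather than thrown.
#' @return list with `statistic` (signed-rank sum V of positive ranks),
#'   `p` (two-sided), `n_pairs` (nonzero differences used), `direction`
#'   (`"increase"` if y tends above x, else `"decrease"`) and `defined`
#'   (FALSE when all differences are zero).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- y - x
  nz <- d[d != 0]
  if (length(nz) < 5L) {
    # all-zero differences (or too few to test) leave the test undefined;
    # flagged rather than thrown so that scans over many nodes keep going
    return(list(statistic = NA_real_, p = NA_real_,
                n_pairs = length(nz),
                direction = if (length(nz) && stats::median(nz) != 0) {
                  if (stats::median(nz) > 0) "increase" else "decrease"
                } else NA_character_,
                defined = FALSE))
  }
  n <- length(nz)
  r <- rank(abs(nz))                  # mid-ranks for tied magnitudes
  v <- sum(r[nz > 0])
  if (n <= 25L) {
    p <- .signed_rank_exact_p(r, v)
  } else {
    p <- suppressWarnings(stats::wilcox.test(
      y, x, paired = TRUE, alternative = "two.sided",
      exact = FALSE, correct = TRUE))$p.value
  }
  list(statistic = v, p = p, n_pairs = n,
       direction = if (stats::median(nz) > 0) "increase" else "decrease",
       defined = TRUE)
}

# exact two-sided p-value of the signed-rank sum under the null of
# exchangeable signs, valid with mid-ranked ties: the distribution of
# V = sum of ranks of the positive differences over all 2^n equally likely
# sign patterns, built by convolution over doubled (integer) ranks
.signed_rank_exact_p <- function(r, v) {
  s <- as.integer(round(2 * r))
  total <- sum(s)
  w <- numeric(total + 1L)
  w[1L] <- 1
  for (k in s) {
    shifted <- c(numeric(k), w[seq_len(total + 1L - k)])
    w <- w + shifted
  }
  w <- w / sum(w)
  v2 <- as.integer(round(2 * v))
  lo <- sum(w[seq_len(v2 + 1L)])                 # P(V <= v)
  hi <- sum(w[seq.int(v2 + 1L, total + 1L)])     # P(V >= v)
  min(1, 2 * min(lo, hi))
}

#' Multiple-comparison correction
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @param method `"bh"` (Benjamini-Hochberg step-up false discovery rate)
#'   or `"bonferroni"`.
#' @return adjusted p-values, monotone in the raw values and capped at 1.
#' @export
correct_multiple <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("no p-values supplied")
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[method])
}

#' Compare pre and post metric tables
#'
#' Runs the paired Wilcoxon signed-rank test between the two resting
#' sessions on the metric tables of matched subjects, at identical
#' thresholds, with multiple-comparison correction.
#'
#' Global scope pairs each subject's graph-level value (one test per
#' measure and threshold; correction across thresholds within each
#' measure). Node scope pairs subjects per node (one test per measure,
#' threshold and node; correction across the nodes, mirroring correction
#' over the 116 atlas regions).
#'
#' @param pre,post long-format metric tables as produced by
#'   [graph_metric_table()] (rows bound over subjects), with matched
#'   subject identifiers and identical threshold sets.
#' @param scope `"global"`, `"node"` or both.
#' @param correction `"bh"` or `"bonferroni"`.
#' @return data.frame with columns `scope`, `measure`, `threshold`, `node`,
#'   `statistic`, `p_raw`, `p_corrected`, `direction`, `n_pairs`.
#' @export
compare_sessions <- function(pre, post, scope = c("global", "node"),
                             correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  scope <- match.arg(scope, several.ok = TRUE)
  subs <- sort(unique(pre$subject))
  if (!setequal(subs, unique(post$subject))) {
    stop("subject identifiers differ between sessions")
  }
  thr_pre <- sort(unique(pre$threshold))
  if (!isTRUE(all.equal(thr_pre, sort(unique(post$threshold))))) {
    stop("threshold sets differ between sessions")
  }

  paired_test <- function(dpre, dpost) {
    key <- c("subject", if (!all(is.na(dpre$node))) "node")
    dpre <- dpre[do.call(order, dpre[key]), ]
    dpost <- dpost[do.call(order, dpost[key]), ]
    stopifnot(nrow(dpre) == nrow(dpost))
    wilcoxon_signed_rank(dpre$value, dpost$value)
  }

  rows <- list()
  add_row <- function(scope, measure, threshold, node, t) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scope = scope, measure = measure, threshold = threshold,
      node = node, statistic = t$statistic, p_raw = t$p,
      p_corrected = NA_real_, direction = t$direction,
      n_pairs = t$n_pairs, stringsAsFactors = FALSE)
  }

  same_thr <- function(a, b) {
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  }
  if ("global" %in% scope) {
    gpre <- pre[is.na(pre$node), ]
    gpost <- post[is.na(post$node), ]
    for (ms in unique(gpre$measure)) {
      for (th in unique(gpre$threshold[gpre$measure == ms])) {
        sel <- function(d) d[d$measure == ms & same_thr(d$threshold, th), ]
        t <- paired_test(sel(gpre), sel(gpost))
        add_row("global", ms, th, NA_character_, t)
      }
    }
  }
  if ("node" %in% scope) {
    npre <- pre[!is.na(pre$node), ]
    npost <- post[!is.na(post$node), ]
    for (ms in unique(npre$measure)) {
      for (th in unique(npre$threshold[npre$measure == ms])) {
        for (nd in unique(npre$node)) {
          sel <- function(d) d[d$measure == ms & d$node == nd &
                                 same_thr(d$threshold, th), ]
          t <- paired_test(sel(npre), sel(npost))
          add_row("node", ms, th, nd, t)
        }
      }
    }
  }
  out <- do.call(rbind, rows)

  # correction units: global -> across thresholds within measure;
  # node -> across nodes within (measure, threshold)
  grp <- ifelse(out$scope == "global",
                paste(out$scope, out$measure),
                paste(out$scope, out$measure, out$threshold))
  for (gkey in unique(grp)) {
    i <- which(grp == gkey & !is.na(out$p_raw))
    if (length(i)) out$p_corrected[i] <- correct_multiple(out$p_raw[i],
                                                          correction)
  }
  attr(out, "correction") <- correction
  out
}

#' Direction consistency of a global effect across thresholds
#'
#' Summarizes a [compare_sessions()] result for one global measure: is the
#' change in the same direction at every threshold, and significant at
#' every threshold at the given level?
#'
#' @param comparison a [compare_sessions()] data.frame.
#' @param measure measure name (e.g. `"degree_mean"`).
#' @param alpha significance level applied to corrected p-values.
#' @return list with `direction` (`"increase"`, `"decrease"` or
#'   `"mixed"`), `all_significant`, and `n_thresholds`.
#' @export
consistent_direction <- function(comparison, measure, alpha = 0.05) {
  d <- comparison[comparison$scope == "global" &
                    comparison$measure == measure, ]
  if (nrow(d) == 0L) stop("measure not found in comparison: ", measure)
  dirs <- unique(d$direction)
  list(direction = if (length(dirs) == 1L) dirs else "mixed",
       all_significant = all(d$p_corrected < alpha, na.rm = FALSE),
       n_thresholds = nrow(d))
}

#' Write a comparison result as TSV and JSON
#' @param comparison a [compare_sessions()] data.frame.
#' @param path output TSV path; a `.json` sidecar carries the rows plus the
#'   correction method metadata.
#' @return the path, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  utils::write.table(comparison, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(correction = attr(comparison, "correction"),
         results = comparison),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
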