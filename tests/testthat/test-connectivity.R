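tr <- 2.8

sinusoid_ts <- function(freqs, n = 214, tr = 2.8) {
  t <- (seq_len(n) - 1) * tr
  regional_ts(do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t))),
              sprintf("r%02d", seq_along(freqs)), tr)
}

test_that("wavelet sub-band filter keeps in-band energy, rejects DC and out-of-band tones", {
  # constant series: no detail-band energy at all
  const <- regional_ts(matrix(5, 2, 64), c("a", "b"), tr)
  expect_lt(max(abs(wavelet_subband_filter(const, c(0.06, 0.1))$values)),
            1e-12)

  # 0.08 Hz tone lies inside the 0.06-0.1 Hz sub-band
  inb <- sinusoid_ts(0.08)
  filt <- wavelet_subband_filter(inb, c(0.06, 0.1))
  expect_gte(var(filt$values[1, ]) / var(inb$values[1, ]), 0.7)

  # 0.005 Hz tone is far below the sub-band
  out <- sinusoid_ts(0.005)
  filt_out <- wavelet_subband_filter(out, c(0.06, 0.1))
  expect_lte(var(filt_out$values[1, ]) / var(out$values[1, ]), 0.1)

  # output length preserved; errors on a band beyond the Nyquist
  expect_equal(ncol(filt$values), ncol(inb$values))
  expect_error(wavelet_subband_filter(inb, c(0.06, 0.5)), "Nyquist")
})

test_that("the wavelet filter is linear; the fft variant shares its pass-band", {
  set.seed(4)
  x <- matrix(rnorm(3 * 128), 3, 128)
  y <- matrix(rnorm(3 * 128), 3, 128)
  f <- function(m) wavelet_subband_filter(
    regional_ts(m, c("a", "b", "c"), tr), c(0.06, 0.1))$values
  expect_equal(f(x + y), f(x) + f(y), tolerance = 1e-10)

  # same qualitative pass-band for the direct spectral filter
  inb <- sinusoid_ts(0.08)
  filt <- wavelet_subband_filter(inb, c(0.06, 0.1), method = "fft")
  expect_gte(var(filt$values[1, ]) / var(inb$values[1, ]), 0.9)
})

test_that("MODWT details are additive and reconstruct the input", {
  set.seed(2)
  x <- rnorm(200)
  wt <- modwt(x, 4)
  details <- Reduce(`+`, lapply(1:4, function(j) modwt_detail(wt, j)))
  gt <- restgraph:::.d4_scaling / sqrt(2)
  smooth <- wt$V
  for (j in 4:1) smooth <- restgraph:::.circ_up(smooth, gt, 2L^(j - 1L))
  expect_equal(details + smooth, x, tolerance = 1e-12)
  expect_error(modwt(rnorm(3), 1), "shorter")
})

test_that("correlation matrix matches the Pearson formula and its invariances", {
  # hand-computed example
  ts <- regional_ts(rbind(c(1, 2, 3), c(1, 2, 4)), c("x", "y"), tr)
  cm <- correlation_matrix(ts)
  expect_equal(cm$weights["x", "y"], 0.98198, tolerance = 1e-5)
  expect_equal(diag(cm$weights), c(x = 0, y = 0))

  # identical series correlate at 1; orthogonal sinusoids at ~0
  t <- (0:99) * tr
  ts2 <- regional_ts(rbind(sin(2 * pi * t / 70), sin(2 * pi * t / 70),
                           cos(2 * pi * t / 70)),
                     c("a", "b", "c"), tr)
  cm2 <- correlation_matrix(ts2)
  expect_equal(cm2$weights["a", "b"], 1)
  expect_lt(abs(cm2$weights["a", "c"]), 1e-8)

  # invariant under positive affine rescaling of any series
  ts3 <- regional_ts(rbind(ts2$values[1, ] * 7 + 3, ts2$values[3, ]),
                     c("a", "c"), tr)
  expect_equal(correlation_matrix(ts3)$weights["a", "c"],
               cm2$weights["a", "c"], tolerance = 1e-12)

  # zero-variance region reported by label
  bad <- regional_ts(rbind(rep(1, 10), rnorm(10)), c("flat", "ok"), tr)
  expect_error(correlation_matrix(bad), "flat")
})

test_that("thresholding follows the signed >= rule and is monotone", {
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  cm <- connectivity_matrix(w, c("a", "b", "c"))
  expect_equal(n_edges(threshold_binarize(cm, 0.6)), 0L)
  expect_equal(n_edges(threshold_binarize(cm, 0.4)), 3L)
  expect_equal(n_edges(threshold_binarize(cm, 0.5)), 3L)  # ties kept

  # documented 4x4 example: entries >= 0.6 are 0.72, 0.65, 0.69
  w4 <- matrix(0, 4, 4)
  w4[upper.tri(w4)] <- c(0.72, 0.65, 0.41, 0.33, 0.58, 0.69)
  w4 <- w4 + t(w4)
  cm4 <- connectivity_matrix(w4)
  expect_equal(n_edges(threshold_binarize(cm4, 0.6)), 3L)

  # negative correlations never become edges
  wn <- matrix(c(0, -0.9, -0.9, 0), 2, 2)
  expect_equal(n_edges(threshold_binarize(connectivity_matrix(wn), 0.3)), 0L)

  # raising the threshold never adds edges; count agrees with brute force
  set.seed(8)
  w6 <- matrix(0, 6, 6)
  w6[upper.tri(w6)] <- runif(15, -1, 1)
  w6 <- w6 + t(w6)
  cm6 <- connectivity_matrix(w6)
  prev <- NULL
  for (r in c(0.2, 0.4, 0.6, 0.8)) {
    g <- threshold_binarize(cm6, r)
    expect_equal(n_edges(g), sum(w6[upper.tri(w6)] >= r))
    if (!is.null(prev)) {
      cur <- paste(g$edges[, 1], g$edges[, 2])
      expect_true(all(cur %in% prev))
    }
    prev <- paste(g$edges[, 1], g$edges[, 2])
  }
  expect_error(threshold_binarize(cm6, 1.2), "in \\(0, 1\\)")
})

test_that("node strength sums weights over the complete weighted graph", {
  w <- matrix(0.5, 3, 3); diag(w) <- 0
  s <- node_strength(connectivity_matrix(w))
  expect_equal(unname(s$per_node), rep(1, 3))
  expect_equal(s$mean, 1)

  s0 <- node_strength(connectivity_matrix(matrix(0, 4, 4)))
  expect_equal(unname(s0$per_node), rep(0, 4))

  set.seed(5)
  w6 <- matrix(0, 6, 6)
  w6[upper.tri(w6)] <- runif(15, -1, 1)
  w6 <- w6 + t(w6)
  s6 <- node_strength(connectivity_matrix(w6))
  oracle <- vapply(1:6, function(i) sum(w6[i, -i]), numeric(1))
  expect_equal(unname(s6$per_node), oracle, tolerance = 1e-12)
})

test_that("regional series round-trip through TSV", {
  set.seed(6)
  ts <- regional_ts(matrix(rnorm(20), 4, 5), c("a", "b", "c", "d"), tr)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_regional_ts(ts, p)
  back <- read_regional_ts(p, tr)
  expect_equal(back$values, ts$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$region_labels, ts$region_labels)
})
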