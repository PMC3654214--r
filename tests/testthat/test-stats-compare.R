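# build a minimal long-format metric table for paired tests
fake_table <- function(values, measure = "strength_mean", session = "pre",
                       threshold = 0.3) {
  data.frame(subject = sprintf("sub%02d", seq_along(values)),
             session = session, threshold = threshold,
             node = NA_character_, measure = measure, value = values,
             stringsAsFactors = FALSE)
}

test_that("signed-rank test: exact enumeration, ties, and flags", {
  set.seed(1)
  x <- rnorm(12)
  # uniform shift: all |differences| tie at the same rank; exact
  # enumeration gives 2/2^12
  res <- wilcoxon_signed_rank(x, x + 1)
  expect_equal(res$p, 2 / 2^12, tolerance = 1e-12)
  expect_equal(res$statistic, sum(1:12))
  expect_equal(res$direction, "increase")

  # agreement with the exact reference when there are no ties
  set.seed(2)
  a <- rnorm(15); b <- a + rnorm(15)
  res2 <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)
  expect_equal(res2$p, ref$p.value, tolerance = 1e-12)

  # large-sample branch matches the continuity-corrected approximation
  set.seed(3)
  a2 <- rnorm(40); b2 <- a2 + rnorm(40, 0.3)
  res3 <- wilcoxon_signed_rank(a2, b2)
  ref3 <- stats::wilcox.test(b2, a2, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_equal(res3$p, ref3$p.value, tolerance = 1e-12)

  # identical samples: flagged undefined, not an error
  res4 <- wilcoxon_signed_rank(a, a)
  expect_false(res4$defined)
  expect_true(is.na(res4$p))
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank p-values are calibrated under the null", {
  # under exchangeable signs the p-value should be (sub)uniform
  set.seed(42)
  pvals <- replicate(400, {
    x <- rnorm(12)
    wilcoxon_signed_rank(x, x + rnorm(12))$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  # discrete support makes the KS statistic conservative; demand only no
  # gross miscalibration
  expect_gt(ks$p.value, 1e-4)
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("multiple-comparison correction follows both procedures", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(correct_multiple(p, "bonferroni"), c(0.04, 0.08, 0.12, 0.16))
  expect_equal(correct_multiple(p, "bh"), rep(0.04, 4))
  expect_equal(correct_multiple(0.3, "bh"), 0.3)
  expect_error(correct_multiple(numeric(0)), "no p-values")
  # bonferroni dominates BH elementwise
  set.seed(4)
  q <- runif(20)
  expect_true(all(correct_multiple(q, "bonferroni") >=
                  correct_multiple(q, "bh") - 1e-12))
})

test_that("identical sessions yield no significant comparisons", {
  set.seed(5)
  v <- runif(12)
  pre <- fake_table(v)
  post <- fake_table(v, session = "post")
  cmp <- compare_sessions(pre, post, scope = "global")
  expect_true(all(is.na(cmp$p_raw)))
})

test_that("planted connectivity shifts are recovered with the right sign", {
  cfg_up <- synthetic_config(n_subjects = 8, n_regions = 24,
                             n_timepoints = 128,
                             module_sizes = c(12, 12), r_within = 0.5,
                             r_between = 0.1, post_delta = 0.15, seed = 21)
  metrics_for <- function(cfg) {
    ds <- generate_dataset(cfg)
    do.call(rbind, lapply(names(ds$subjects), function(s) {
      do.call(rbind, lapply(c("pre", "post"), function(ses) {
        cm <- correlation_matrix(ds$subjects[[s]][[ses]])
        do.call(rbind, lapply(c(0.3, 0.4), function(th) {
          g <- threshold_binarize(cm, th)
          graph_metric_table(g, cm, subject = s, session = ses,
                             measures = c("degree", "strength"))
        }))
      }))
    }))
  }
  m_up <- metrics_for(cfg_up)
  cmp_up <- compare_sessions(m_up[m_up$session == "pre", ],
                             m_up[m_up$session == "post", ],
                             scope = "global")
  s_up <- cmp_up[cmp_up$measure == "strength_mean", ]
  expect_true(all(s_up$direction == "increase"))
  expect_equal(consistent_direction(cmp_up, "strength_mean")$direction,
               "increase")

  cfg_down <- synthetic_config(n_subjects = 8, n_regions = 24,
                               n_timepoints = 128,
                               module_sizes = c(12, 12), r_within = 0.5,
                               r_between = 0.1, post_delta = -0.15,
                               seed = 22)
  m_dn <- metrics_for(cfg_down)
  cmp_dn <- compare_sessions(m_dn[m_dn$session == "pre", ],
                             m_dn[m_dn$session == "post", ],
                             scope = "global")
  d_dn <- cmp_dn[cmp_dn$measure == "degree_mean", ]
  expect_true(all(d_dn$direction == "decrease"))
})

test_that("node-scope comparison corrects across nodes and keeps pairing", {
  set.seed(6)
  mk <- function(session, shift) {
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(subject = sprintf("sub%02d", i), session = session,
                 threshold = 0.3, node = sprintf("region_%02d", 1:10),
                 measure = "strength",
                 value = rnorm(10) + shift, stringsAsFactors = FALSE)
    }))
  }
  pre <- mk("pre", 0)
  post <- mk("post", 1.5)
  cmp <- compare_sessions(pre, post, scope = "node")
  expect_equal(nrow(cmp), 10L)
  expect_true(all(cmp$p_corrected >= cmp$p_raw - 1e-15))
  expect_true(all(cmp$direction == "increase"))
  expect_true(all(cmp$n_pairs == 8))

  expect_error(compare_sessions(pre[pre$subject != "sub01", ], post),
               "subject identifiers")
})

test_that("rejection rate rises with the planted effect size", {
  # same noise realization scanned at three effect sizes: the global
  # strength p-value must not increase with |post_delta|
  ps <- vapply(c(0, 0.1, 0.25), function(delta) {
    cfg <- synthetic_config(n_subjects = 8, n_regions = 16,
                            n_timepoints = 96, module_sizes = c(8, 8),
                            r_within = 0.4, r_between = 0.1,
                            post_delta = delta, seed = 77)
    ds <- generate_dataset(cfg)
    pre <- vapply(ds$subjects, function(s)
      node_strength(correlation_matrix(s$pre))$mean, numeric(1))
    post <- vapply(ds$subjects, function(s)
      node_strength(correlation_matrix(s$post))$mean, numeric(1))
    wilcoxon_signed_rank(pre, post)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})
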