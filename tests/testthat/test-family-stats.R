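test_that("mean feature occupancy averages defined positions and enforces the minimum length", {
  v <- rep(2, 1000)
  tr <- occupancy_track("chr1", v)
  expect_equal(mean_feature_occupancy(tr, 100L, 400L), 2)
  # short feature under the predicted-kind minimum is excluded
  expect_true(is.na(mean_feature_occupancy(tr, 100L, 220L,
                                           min_length = 129L)))
  expect_equal(mean_feature_occupancy(tr, 100L, 229L, min_length = 129L), 2)
  # half missing: mean over the defined half
  v2 <- v
  v2[101:250] <- NA
  tr2 <- occupancy_track("chr1", v2)
  expect_equal(mean_feature_occupancy(tr2, 100L, 400L), 2)
  v3 <- rep(NA_real_, 1000)
  expect_true(is.na(mean_feature_occupancy(occupancy_track("chr1", v3),
                                           100L, 400L)))
})

test_that("spearman rho matches rank-then-pearson and flags monotone families", {
  set.seed(61)
  # brute-force oracle: average ranks then the Pearson formula
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    x <- round(stats::runif(n), 2)  # rounding induces ties
    y <- round(stats::rnorm(n), 1)
    d <- data.frame(family_id = "f", gc_content = x, occ = y,
                    identity = NA_real_, divergence = NA_real_)
    res <- family_correlations(d, c(pred = "occ"),
                               correlates = "gc_content")
    expect_equal(res$rho, pearson(rank(x), rank(y)), tolerance = 1e-12)
  }

  # strictly monotone occupancy in GC: perfect correlation
  d <- data.frame(family_id = "m", gc_content = seq(0.3, 0.6, 0.02))
  d$occ <- exp(d$gc_content)
  res <- family_correlations(d, c(pred = "occ"), correlates = "gc_content")
  expect_equal(res$rho, 1)
  expect_true(res$significant)
  expect_equal(res$sign, 1L)
})

test_that("small or degenerate families are reported untested", {
  d <- data.frame(family_id = rep(c("small", "flat", "ok"), c(3, 8, 8)),
                  gc_content = c(runif(3), rep(0.5, 8), runif(8)),
                  occ = runif(19))
  res <- family_correlations(d, c(pred = "occ"), correlates = "gc_content",
                             min_family_size = 5L)
  expect_false(res$tested[res$family_id == "small"])
  expect_false(res$tested[res$family_id == "flat"])  # zero-variance GC
  expect_true(res$tested[res$family_id == "ok"])
  expect_true(is.na(res$rho[res$family_id == "flat"]))
  # members with missing values drop pairwise
  d2 <- data.frame(family_id = "x", gc_content = c(runif(6), NA),
                   occ = c(runif(6), 0.5))
  expect_equal(family_correlations(d2, c(pred = "occ"),
                                   correlates = "gc_content")$n, 6L)
})

test_that("null families are significant at about the nominal rate", {
  set.seed(73)
  n_fam <- 100L
  d <- data.frame(family_id = rep(sprintf("f%03d", seq_len(n_fam)),
                                  each = 30L),
                  gc_content = stats::runif(30L * n_fam),
                  occ = stats::runif(30L * n_fam))
  res <- family_correlations(d, c(pred = "occ"), correlates = "gc_content",
                             alpha = 0.05)
  expect_equal(sum(res$tested), n_fam)
  # binomial(100, 0.05): central 99% mass within [0, 11]
  expect_lte(sum(res$significant), 11L)
})

test_that("cohort summaries count and average only significant correlations", {
  s <- data.frame(family_id = c("a", "b", "c"), kind = "pred",
                  correlate = "gc_content", n = 10L,
                  rho = c(0.9, -0.5, 0.2), p = c(0.001, 0.01, 0.4),
                  tested = TRUE, significant = c(TRUE, TRUE, FALSE),
                  sign = c(1L, -1L, 1L))
  cs <- summarize_cohort(s)
  expect_equal(cs$n_families_tested, 3L)
  expect_equal(cs$n_significant, 2L)
  expect_equal(cs$n_significant_positive, 1L)
  expect_equal(cs$mean_significant_rho, 0.2)

  s$significant <- FALSE
  expect_true(is.na(summarize_cohort(s)$mean_significant_rho))

  s$significant <- TRUE
  s$rho <- abs(s$rho)
  cs3 <- summarize_cohort(s)
  expect_equal(cs3$n_significant_positive, cs3$n_significant)
  expect_equal(cs3$n_significant, cs3$n_families_tested)
})

test_that("count consistency holds on random correlation tables", {
  set.seed(5)
  for (rep in 1:10) {
    d <- data.frame(family_id = rep(sprintf("f%d", 1:12),
                                    each = sample(4:12, 1)))
    d$gc_content <- stats::runif(nrow(d))
    d$identity <- stats::runif(nrow(d))
    d$divergence <- stats::runif(nrow(d))
    d$occ <- stats::runif(nrow(d))
    cs <- summarize_cohort(
      family_correlations(d, c(pred = "occ")))
    expect_true(all(cs$n_significant_positive <= cs$n_significant))
    expect_true(all(cs$n_significant <= cs$n_families_tested))
  }
})

test_that("one-way ANOVA behaves at the null, under a strong effect, and degenerately", {
  set.seed(91)
  # calibration: same-distribution groups reject at about alpha
  rejections <- 0L
  for (rep in 1:200) {
    a <- group_anova(stats::rnorm(40), rep(c("t", "n"), each = 20L))
    rejections <- rejections + (a$p < 0.05)
  }
  # binomial(200, 0.05): central 99% mass within [3, 19]
  expect_gte(rejections, 3L)
  expect_lte(rejections, 19L)

  # 3-SD separation is overwhelming
  a <- group_anova(c(stats::rnorm(50), stats::rnorm(50, 3)),
                   rep(c("t", "n"), each = 50L))
  expect_lt(a$p, 0.001)

  # identical constants: no variance anywhere, F = 0
  a0 <- group_anova(rep(1, 10), rep(c("t", "n"), each = 5L))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  expect_error(group_anova(1:5, c("a", "a", "a", "a", "b")), "2 groups")
})
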