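test_that("per-bin summaries match hand-computed values and gate on n", {
  sch <- gratio:::new_bin_scheme(seq(0.5, 1.7, length.out = 7),
                                 "fiber_diameter", "equal_width", "test")
  # bin 1: constant triple; bin 2: the 4-point set; bin 3: a pair (n = 2)
  g <- c(0.7, 0.7, 0.7, 0.6, 0.7, 0.8, 0.9, 0.6, 0.8)
  f <- c(0.55, 0.56, 0.57, 0.75, 0.76, 0.77, 0.78, 0.95, 0.96)
  fib <- make_fibers(f * g, f * (1 - g))  # a + My = f, a/f = g
  fib$g_ratio <- g                        # exact g values for the oracle
  res <- summarize_bins(assign_bins(fib, sch)$records, sch, dip = FALSE)
  expect_equal(res$n, c(3L, 4L, 2L, 0L, 0L, 0L))
  expect_equal(res$mean_g[1:3], c(0.7, 0.75, 0.7))
  expect_equal(res$median_g[2], 0.75)
  # hand: var = ((0.15^2 + 0.05^2) * 2) / 3 = 0.05/3
  expect_equal(res$sd_g[2], sqrt(0.05 / 3), tolerance = 1e-12)
  expect_equal(res$sd_g[1], 0)
  # constant values: Shapiro undefined; n = 2: undefined; empty: all NA
  expect_true(is.na(res$shapiro_W[1]))
  expect_false(is.na(res$shapiro_W[2]))
  expect_true(is.na(res$shapiro_W[3]))
  expect_true(all(is.na(res$mean_g[4:6])))
})

test_that("grand mean g fits the constant-g model to bin means", {
  mk <- function(means, ns) tibble::tibble(
    bin_index = seq_along(means), n = ns, mean_g = means,
    median_g = means, sd_g = 0, shapiro_W = NA, shapiro_p = NA,
    dip_stat = NA, dip_p = NA)
  s <- mk(rep(0.7, 6), rep(10L, 6))
  expect_equal(grand_mean_g(s, "unweighted")$value, 0.7)
  expect_equal(grand_mean_g(s, "n_weighted")$value, 0.7)
  s2 <- mk(c(0.6, 0.6, 0.6, 0.8, 0.8, 0.8), rep(5L, 6))
  expect_equal(grand_mean_g(s2, "unweighted")$value, 0.7)
  s3 <- mk(c(0.6, 0.8, NA, NA, NA, NA), c(10L, 30L, 0L, 0L, 0L, 0L))
  expect_equal(grand_mean_g(s3, "n_weighted")$value, 0.75)
  expect_equal(grand_mean_g(s3, "unweighted")$value, 0.7)
  s4 <- mk(rep(NA_real_, 6), rep(0L, 6))
  expect_error(grand_mean_g(s4), "empty")
})

test_that("unweighted grand mean ignores bin sizes; weighted equals pooled", {
  set.seed(31)
  sch <- gratio:::new_bin_scheme(seq(0.5, 1.7, length.out = 7),
                                 "fiber_diameter", "equal_width", "t")
  f <- runif(400, 0.5, 1.7)
  g <- runif(400, 0.55, 0.85)
  fib <- make_fibers(f * g, f * (1 - g))
  rec <- assign_bins(fib, sch)$records
  s <- summarize_bins(rec, sch, dip = FALSE)
  gw <- grand_mean_g(s, "n_weighted")$value
  expect_equal(gw, mean(rec$g_ratio), tolerance = 1e-12)
  # doubling one bin's rows leaves the unweighted grand mean unchanged
  extra <- rec[rec$bin_index == 3, ]
  s2 <- summarize_bins(rbind(rec, extra), sch, dip = FALSE)
  expect_equal(grand_mean_g(s2, "unweighted")$value,
               grand_mean_g(s, "unweighted")$value, tolerance = 1e-12)
})

test_that("the 2x2 toy decomposition matches brute force exactly", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  grp <- rep(c("A", "B"), each = 4)
  bin <- rep(c(1L, 1L, 2L, 2L), 2)
  rec <- tibble::tibble(g_ratio = y, group_label = grp, bin_index = bin)
  tab <- two_way_anova(rec)
  # hand-computed: group means 2.5/6.5, bin means 3.5/5.5, additive cells
  expect_equal(tab$sum_sq, c(32, 8, 0, 2), tolerance = 1e-9)
  expect_equal(tab$df, c(1, 1, 1, 4))
  bf <- brute_force_anova(y, grp, bin)
  expect_equal(tab$sum_sq, unname(bf$ss), tolerance = 1e-9)
})

test_that("flat cell means give zero F everywhere", {
  rec <- tibble::tibble(
    g_ratio = rep(c(9, 11), 8),
    group_label = rep(c("A", "B"), each = 8),
    bin_index = rep(rep(1:2, each = 4), 2))
  tab <- two_way_anova(rec)
  expect_equal(tab$F[1:3], c(0, 0, 0), tolerance = 1e-12)
})

test_that("balanced random designs match the brute-force oracle", {
  set.seed(19)
  for (rep_i in 1:5) {
    ng <- sample(2:3, 1); nb <- sample(2:4, 1); npc <- sample(2:3, 1)
    n <- ng * nb * npc
    rec <- tibble::tibble(
      g_ratio = rnorm(n),
      group_label = rep(LETTERS[1:ng], each = nb * npc),
      bin_index = rep(rep(1:nb, each = npc), ng))
    tab <- two_way_anova(rec)
    bf <- brute_force_anova(rec$g_ratio, rec$group_label, rec$bin_index)
    expect_equal(tab$sum_sq, unname(bf$ss), tolerance = 1e-9)
    expect_equal(tab$df, unname(bf$df))
    expect_equal(sum(tab$sum_sq),
                 sum((rec$g_ratio - mean(rec$g_ratio))^2), tolerance = 1e-9)
  }
})

test_that("degenerate ANOVA inputs raise informative errors", {
  rec <- tibble::tibble(g_ratio = rnorm(8), group_label = rep("A", 8),
                        bin_index = rep(1:2, 4))
  expect_error(two_way_anova(rec), "2 groups")
  rec3 <- tibble::tibble(g_ratio = rnorm(6),
                         group_label = c("A", "A", "A", "A", "B", "B"),
                         bin_index = c(1, 1, 2, 2, 2, 2))
  expect_error(two_way_anova(rec3), "empty group x bin")
})

test_that("Shapiro-Wilk rejects at about the nominal rate under normality", {
  set.seed(23)
  rej <- 0L
  for (i in 1:1000) if (stats::shapiro.test(rnorm(50))$p.value < 0.05)
    rej <- rej + 1L
  expect_gt(rej / 1000, 0.03)
  expect_lt(rej / 1000, 0.07)
})
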