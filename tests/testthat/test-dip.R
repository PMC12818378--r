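# Expected dip values below were computed with an independent exact solver:
# the minimal sup-norm distance from the ECDF to a unimodal CDF expressed as
# a linear program over all candidate mode placements (scipy linprog), and
# frozen here.

test_that("dip statistic matches the exact LP solution on frozen cases", {
  cases <- list(
    list(x = (1:10) / 10, d = 0.05),                  # linear ECDF: 1/(2n)
    list(x = c(0, 1), d = 0.25),
    list(x = c(1, 1, 1), d = 0),                      # point mass is unimodal
    list(x = c(0, 0, 1, 1), d = 0.25),                # two-point mixture
    list(x = c(0, 1, 2, 2, 3), d = 0.1),
    list(x = c(0.5, 0.5, 0.797, 0.821), d = 0.231308411214953),
    list(x = c(0.21432320123825765, 0.30945203088169171, 0.79946609677483316,
               0.99580209886546678, 0.1422318152800518, 0.078725533761998978),
         d = 0.103075319513567),
    list(x = c(0.55383204222017468, 0.37165898082652515, 0.83389703092895406,
               0.34877257842761322, 0.68165405198431517, 0.22835056975573742,
               0.5, 0.5, 0.5, 0.5), d = 0.0848662351305401),
    list(x = c(1, 0, 2, 3, 3, 3, 0, 3, 0, 1, 0, 3, 0), d = 0.192307692307692),
    list(x = c(0.22012043626195821, 0.94815258273503134, 0.87361491576938965,
               0.14083846029013269, 0.78018798415011137, 0.0065342916306376786,
               0.66394735288956341, 0.31263706955826531, 0.35781330528630029,
               0.22556785772719046, 0.56210306454719383, 0.93039220960272373,
               0.5, 0.5), d = 0.0725754488388145),
    list(x = c(1, 2, -1.5, 1, 1, 1, -0.5, 0.5, -0.5, 0.5, 1, -0.5, 0, 1),
         d = 0.107142857142857))
  for (cs in cases) expect_equal(dip_stat(cs$x), cs$d, tolerance = 1e-9)
})

test_that("dip properties: scale invariance, bounds, tie handling", {
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(5:60, 1))
    d <- dip_stat(x)
    expect_gte(d, 1 / (2 * length(x)) - 1e-12)
    expect_lte(d, 0.25 + 1e-12)
    expect_equal(dip_stat(3 * x - 7), d, tolerance = 1e-8)
  }
  expect_equal(dip_stat(rep(2, 10)), 0)
})

test_that("dip test gates on n >= 4 and returns the statistic", {
  r <- dip_test(c(1, 2, 3))
  expect_true(is.na(r$statistic) && is.na(r$p_value))
  set.seed(99)
  x <- runif(30)
  r2 <- dip_test(x)
  expect_false(is.na(r2$p_value))
  expect_equal(r2$statistic, dip_stat(x))
  expect_equal(r2$n, 30L)
})

test_that("a unimodal sample rarely rejects; strong bimodality always does", {
  set.seed(57)
  p_uni <- replicate(100, {
    x <- truncnorm::rtruncnorm(200, a = 0.65, b = 0.95, mean = 0.7, sd = 0.03)
    dip_test(x)$p_value
  })
  expect_gte(mean(p_uni > 0.05), 0.95)
  p_bi <- replicate(20, {
    x <- c(rnorm(100, 0.6, 0.01), rnorm(100, 0.9, 0.01))
    dip_test(x)$p_value
  })
  expect_true(all(p_bi < 0.05))
})

test_that("table and bootstrap p-values broadly agree", {
  set.seed(73)
  x <- c(rnorm(60, 0, 0.4), rnorm(40, 2.4, 0.4))
  pt <- dip_test(x, method = "table")$p_value
  pb <- dip_test(x, method = "bootstrap", B = 400)$p_value
  expect_lt(abs(pt - pb), 0.12)
  y <- runif(100)
  pt2 <- dip_test(y, method = "table")$p_value
  pb2 <- dip_test(y, method = "bootstrap", B = 400)$p_value
  expect_lt(abs(pt2 - pb2), 0.15)
})
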