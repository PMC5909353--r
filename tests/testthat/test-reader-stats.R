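test_that("summarize_tumor computes mean, n-1 SD, cv, min, max", {
  s <- summarize_tumor(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  expect_equal(s$cv, 0.5)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  expect_equal(s$n_readings, 3L)
  expect_error(summarize_tumor(5), "two readings")
  expect_error(summarize_tumor(c(1, -2, 3)), "positive")
})

test_that("cv is scale-invariant and reproduces the published cells", {
  set.seed(501)
  x <- rlnorm(20, 3, 0.2)
  expect_equal(summarize_tumor(x)$cv, summarize_tumor(7.3 * x)$cv)
  # two-point samples with the published (mean, SD): cv to 2 d.p.
  two_point <- function(m, s) c(m + s / sqrt(2), m - s / sqrt(2))
  s1 <- summarize_tumor(two_point(76.72, 10.14))  # liver 3 diameter
  expect_equal(round(s1$cv, 2), 0.13)
  s2 <- summarize_tumor(two_point(11.66, 2.96))   # liver 2 area
  expect_equal(round(s2$cv, 2), 0.25)
})

test_that("icc_agreement matches a direct ANOVA mean-squares oracle", {
  # identical readers, nonzero between-tumour spread -> ICC = 1
  y <- matrix(rep(c(3, 7, 11), each = 4), nrow = 4)
  r <- icc_agreement(y)
  expect_equal(r$icc, 1)
  expect_equal(r$icc_class, "excellent")
  # 3 readers x 3 tumours toy matrix vs hand arithmetic
  m <- rbind(c(9, 2, 5), c(10, 4, 6), c(11, 6, 10))
  k <- 3; n <- 3
  grand <- mean(m)
  msr <- k * sum((colMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((rowMeans(m) - grand)^2) / (k - 1)
  mse <- (sum((m - grand)^2) - k * sum((colMeans(m) - grand)^2) -
            n * sum((rowMeans(m) - grand)^2)) / ((n - 1) * (k - 1))
  icc21 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icc31 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc_agreement(m)$icc, icc21, tolerance = 1e-10)
  expect_equal(icc_agreement(m, type = "consistency")$icc, icc31,
               tolerance = 1e-10)
  # and against the aov() decomposition as an independent route
  df <- data.frame(y = as.vector(m),
                   reader = factor(rep(1:3, times = 3)),
                   tumour = factor(rep(1:3, each = 3)))
  ms <- summary(aov(y ~ tumour + reader, data = df))[[1]][["Mean Sq"]]
  expect_equal(unname(icc_agreement(m)$ms[c("MSR", "MSC", "MSE")]),
               ms, tolerance = 1e-10)
  expect_error(icc_agreement(matrix(5, 3, 3)), "zero total variance")
})

test_that("icc_agreement approaches the variance-components limit", {
  # 20 readers x 100 tumours, between-SD 20, within-SD 1:
  # ICC -> 400 / 401 = 0.9975
  set.seed(502)
  target <- 400 / 401
  for (i in 1:200) {
    mu <- rnorm(100, 50, 20)
    y <- matrix(rnorm(20 * 100, rep(mu, each = 20), 1), nrow = 20)
    expect_equal(icc_agreement(y)$icc, target, tolerance = 0.01)
  }
})

test_that("icc is invariant under shift and scale, monotone in noise", {
  set.seed(503)
  mu <- rnorm(15, 40, 15)
  y <- matrix(rnorm(10 * 15, rep(mu, each = 10), 3), nrow = 10)
  i0 <- icc_agreement(y)$icc
  expect_equal(icc_agreement(y + 100)$icc, i0, tolerance = 1e-12)
  expect_equal(icc_agreement(y * 3.7)$icc, i0, tolerance = 1e-12)
  # fixed between-tumour spread, shrinking within noise -> ICC increases
  eps <- matrix(rnorm(10 * 15), nrow = 10)
  base <- matrix(rep(mu, each = 10), nrow = 10)
  iccs <- vapply(c(8, 4, 2, 1, 0.5),
                 function(s) icc_agreement(base + s * eps)$icc, 0)
  expect_true(all(diff(iccs) > 0))
  expect_gt(iccs[length(iccs)], 0.99)
})

test_that("chi2_yates reproduces the aberrant-split test", {
  # 4 vs 9 aberrant out of 260 per group
  tab <- rbind(c(4, 256), c(9, 251))
  r <- chi2_yates(tab)
  expect_equal(round(r$p_value, 3), 0.261)
  expect_equal(r$n, 520L)
  # uncorrected statistic as cross-check
  expect_equal(round(chi2_yates(tab, correct = FALSE)$statistic, 3),
               1.972)
  # identical rows: statistic floors at 0, p = 1
  r0 <- chi2_yates(rbind(c(5, 95), c(5, 95)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(chi2_yates(rbind(c(0, 0), c(5, 5))), "margins")
})

test_that("chi2_yates p is symmetric under row and column swaps", {
  set.seed(504)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 1L, 2L)
    p <- chi2_yates(tab)$p_value
    expect_equal(chi2_yates(tab[2:1, ])$p_value, p)
    expect_equal(chi2_yates(tab[, 2:1])$p_value, p)
  }
})

test_that("wilcoxon_signed_rank: exact enumeration and edge cases", {
  x <- 1:6
  expect_error(wilcoxon_signed_rank(x, x), "all differences are zero")
  # n = 6 all-positive differences: two-sided exact p = 2 / 2^6
  r <- wilcoxon_signed_rank(x + 1, x)
  expect_equal(r$p_value, 0.03125)
  expect_equal(r$n, 6L)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(0, 0, 0, 0)),
               "fewer than 5")
  # agreement with the reference exact test on tie-free data
  set.seed(505)
  for (i in 1:20) {
    d <- round(rnorm(12, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 5 || any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p agree at moderate n", {
  set.seed(506)
  for (i in 1:30) {
    d <- rnorm(12, 0.4, 1)
    pe <- wilcoxon_signed_rank(d)$p_value
    pn <- wilcoxon_signed_rank(d, exact_max = 5L)$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("compare_groups detects a planted shift and is label-symmetric", {
  set.seed(507)
  sizes <- runif(13, 20, 70)
  hits <- 0L
  for (i in 1:200) {
    noise <- function(t, r, m) sizes[t] * (1 + rnorm(length(t), 0, 0.05))
    meas <- synthetic_measurements(noise)
    # plant a +10% shift in the scientist arm
    sci <- meas$reader_group == "scientist"
    meas$diameter_mm[sci] <- meas$diameter_mm[sci] * 1.10
    res <- compare_groups(meas, compare = "reader_group")
    p <- res$p_value[res$metric == "diameter_mm"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 160L)  # >= 80% power over 200 replicates
  # two-sided symmetry under arm relabelling
  set.seed(508)
  meas <- synthetic_measurements(function(t, r, m)
    sizes[t] * (1 + rnorm(length(t), 0, 0.05)))
  p1 <- compare_groups(meas, compare = "reader_group")$p_value
  flip <- meas
  flip$reader_group <- ifelse(meas$reader_group == "physician",
                              "scientist", "physician")
  p2 <- compare_groups(flip, compare = "reader_group")$p_value
  expect_equal(p2, p1)
  # duplicated arms: all differences zero -> error per stratum
  dup <- meas
  dup$diameter_mm <- ave(dup$diameter_mm, dup$tumour_id)
  dup$area_cm2 <- ave(dup$area_cm2, dup$tumour_id)
  expect_error(compare_groups(dup, compare = "reader_group"),
               "all differences are zero")
})

test_that("compare_groups pairs methods per reader x tumour and errors
           on unmatched units", {
  set.seed(509)
  sizes <- runif(5, 20, 60)
  meas <- synthetic_measurements(function(t, r, m)
    sizes[t] * (1 + rnorm(length(t), 0, 0.03)), n_tumours = 5L,
    n_readers = 6L)
  res <- compare_groups(meas, compare = "method")
  expect_equal(res$n_pairs[res$metric == "diameter_mm"], 30L)
  # removing one arm of a unit without dropping raises the listed error
  broken <- meas[!(meas$tumour_id == "t1" & meas$reader_id == "R01" &
                     meas$method == 1L), ]
  expect_error(compare_groups(broken, compare = "method"), "t1/R01")
  expect_silent(compare_groups(broken, compare = "method",
                               on_unmatched = "drop"))
})
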