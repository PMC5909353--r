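test_that("fit_sd_regression recovers exact relationships", {
  s <- c(10, 20, 30, 50)
  # perfect proportional law
  m <- fit_sd_regression(s, 0.1 * s, form = "linear")
  expect_equal(unname(m$coefficients["a"]), 0, tolerance = 1e-12)
  expect_equal(unname(m$coefficients["b"]), 0.1, tolerance = 1e-12)
  expect_equal(m$residual_sd, 0, tolerance = 1e-10)
  # through-origin on the same data
  m0 <- fit_sd_regression(s, 0.1 * s, form = "through_origin")
  expect_equal(unname(m0$coefficients["b"]), 0.1, tolerance = 1e-12)
  expect_error(fit_sd_regression(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  expect_error(fit_sd_regression(c(5, 6), c(1, 2)), "3 points")
})

test_that("liver diameter fit matches the closed-form OLS oracle", {
  ref <- reference_summary()
  sub <- ref[ref$organ == "liver" & ref$metric == "diameter_mm", ]
  m <- liver_diameter_model()
  # normal equations computed directly
  x <- sub$mean; y <- sub$sd
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(unname(m$coefficients["a"]), a, tolerance = 1e-12)
  expect_equal(unname(m$coefficients["b"]), b, tolerance = 1e-12)
  expect_equal(a, -2.99, tolerance = 0.002)
  expect_equal(b, 0.1675, tolerance = 0.0005)
})

test_that("predicted dispersion clamps at zero below the crossing", {
  m <- liver_diameter_model()
  a <- m$coefficients["a"]; b <- m$coefficients["b"]
  x0 <- unname(-a / b)  # zero-crossing near 17.9 mm
  expect_equal(predict(m, x0 - 5), 0)
  expect_gt(predict(m, x0 + 5), 0)
  expect_equal(ci_band(m, x0 - 5), 0)
})

test_that("ci_band scales with z and matches plug-in arithmetic", {
  m <- liver_diameter_model()
  expect_equal(ci_band(m, 44.18, z = 0), 0)
  a <- unname(m$coefficients["a"]); b <- unname(m$coefficients["b"])
  expect_equal(ci_band(m, 44.18), 1.96 * (a + b * 44.18))
  expect_equal(ci_band(m, 44.18), 8.64, tolerance = 0.01)
  # limit-line variants: evaluated at k x vs scaled by k
  expect_equal(ci_band(m, 30, k = 1.2, variant = "evaluated"),
               1.96 * (a + b * 36))
  expect_equal(ci_band(m, 30, k = 1.2, variant = "scaled"),
               1.96 * 1.2 * (a + b * 30))
  expect_error(ci_band(m, -3), "non-negative")
})

test_that("limit lines carry the RECIST multipliers to both metrics", {
  ld <- limit_lines(recist_limits("diameter_mm"))
  expect_equal(unname(ld), c(1, 1.2, 0.7))
  la <- limit_lines(recist_limits("area_cm2"))
  expect_equal(unname(la["pd"]), 1.44)
  expect_equal(unname(la["pr"]), 0.49)
  expect_equal(recist_limits("area_cm2", area_pr = "printed")$k_pr, 0.47)
  # identity multiplier squares to itself
  expect_error(recist_limits("diameter_mm", pd_multiplier = 0.9),
               "pd_multiplier")
})

test_that("solve_cutoff: zero dispersion means no overlap anywhere", {
  m <- fit_sd_regression(c(10, 20, 30), c(0, 0, 0), form = "linear",
                         organ = "x", metric = "diameter_mm")
  lim <- recist_limits("diameter_mm")
  r <- solve_cutoff(m, lim, "PD", range = c(5, 100))
  expect_equal(r$overlap, "none")
  expect_true(is.na(r$cutoff))
})

test_that("liver diameter cut-offs land at the published intersections", {
  m <- liver_diameter_model()
  lim <- recist_limits("diameter_mm")
  pd <- solve_cutoff(m, lim, "PD")
  expect_equal(pd$overlap, "above_cutoff")
  expect_equal(pd$cutoff, 22.46, tolerance = 0.001)
  pr_eval <- solve_cutoff(m, lim, "PR", variant = "evaluated")
  pr_scaled <- solve_cutoff(m, lim, "PR", variant = "scaled")
  expect_equal(pr_eval$cutoff, 45.45, tolerance = 0.001)
  expect_equal(pr_scaled$cutoff, 38.63, tolerance = 0.001)
})

test_that("bisection agrees with the closed-form linear root to 1e-6", {
  # exact liver-like dispersion law over sizes where no clamping occurs
  s <- c(20, 35, 50, 65, 80)
  y <- -3 + 0.17 * s
  lim <- recist_limits("diameter_mm")
  m_lin <- fit_sd_regression(s, y, form = "linear",
                             organ = "liver", metric = "diameter_mm")
  # a quadratic fit to the same exact values has ~0 curvature, and its
  # root is found by bisection on an identical gap function
  m_quad <- fit_sd_regression(s, y, form = "quadratic",
                              organ = "liver", metric = "diameter_mm")
  expect_lt(abs(unname(m_quad$coefficients["c"])), 1e-10)
  for (side in c("PD", "PR")) {
    r1 <- solve_cutoff(m_lin, lim, side)
    r2 <- solve_cutoff(m_quad, lim, side)
    expect_equal(r2$cutoff, r1$cutoff, tolerance = 1e-6)
  }
})

test_that("cut-off solutions agree with a dense-grid band evaluation", {
  m <- liver_diameter_model()
  lim <- recist_limits("diameter_mm")
  xs <- seq(17.66, 76.72, length.out = 1e5)
  for (side in c("PD", "PR")) {
    k <- if (side == "PD") lim$k_pd else lim$k_pr
    r <- solve_cutoff(m, lim, side)
    # band inequality evaluated directly at every grid point
    overlap <- if (side == "PD") {
      xs + ci_band(m, xs) >= k * xs - ci_band(m, xs, k = k)
    } else {
      xs - ci_band(m, xs) <= k * xs + ci_band(m, xs, k = k)
    }
    grid_cut <- xs[which(overlap)[1L]]
    expect_equal(r$cutoff, grid_cut, tolerance = 1e-3)
    expect_false(any(overlap[xs < r$cutoff - 1e-3]))
    expect_true(all(overlap[xs > r$cutoff + 1e-3]))
  }
})

test_that("gap shrinks with z and cut-offs move down with z", {
  m <- liver_diameter_model()
  lim <- recist_limits("diameter_mm")
  cuts <- vapply(c(1.5, 1.96, 2.5), function(z)
    solve_cutoff(m, lim, "PD", z = z)$cutoff, 0)
  expect_true(all(diff(cuts) < 0))
})

test_that("small proportional dispersion never overlaps (closed form)", {
  # sigma = b s with z b (1 + k) < |k - 1| implies a positive gap at
  # every size
  lim <- recist_limits("diameter_mm")
  b_max_pd <- (lim$k_pd - 1) / (1.96 * (1 + lim$k_pd))
  for (b in c(0.2, 0.6, 0.95) * b_max_pd) {
    s <- c(10, 30, 60)
    m <- fit_sd_regression(s, b * s, form = "through_origin",
                           organ = "x", metric = "diameter_mm")
    r <- solve_cutoff(m, lim, "PD", range = c(1, 500))
    expect_equal(r$overlap, "none")
  }
})

test_that("overlap_report covers all strata and ignores input order", {
  models <- fit_summary_models(reference_summary())
  rep1 <- overlap_report(models)
  rep2 <- overlap_report(rev(models))
  expect_equal(rep1, rep2)
  expect_equal(nrow(rep1), 8L)  # 2 organs x 2 metrics x 2 limits
  # liver area: overlap everywhere on the observed range
  la <- rep1[rep1$organ == "liver" & rep1$metric == "area_cm2", ]
  expect_true(all(la$overlap == "everywhere"))
  # zero-noise models: no overlap in any cell
  zero <- list(
    fit_sd_regression(c(10, 20, 30), c(0, 0, 0), organ = "liver",
                      metric = "diameter_mm"),
    fit_sd_regression(c(10, 20, 30), c(0, 0, 0), organ = "lung",
                      metric = "diameter_mm"))
  expect_true(all(overlap_report(zero)$overlap == "none"))
})
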