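test_that("generalized measure interpolates length and area", {
  st <- strain_config("wt", 1.876, division_rule("area", 165))
  rec <- simulate_lineages(st, 200, seed = 1)
  g0 <- homeostasis_points(rec, "general", gamma = 0)
  expect_equal(g0$birth, homeostasis_points(rec, "length")$birth)
  g1 <- homeostasis_points(rec, "general", gamma = 1)
  a <- homeostasis_points(rec, "area")
  expect_equal(g1$birth, a$birth / (2 * pi))
  expect_equal(g1$delta, a$delta / (2 * pi))
  expect_error(homeostasis_points(rec, "girth"), "unknown measure")
})

test_that("perfect sizer points sit on the line delta = threshold - birth", {
  st <- strain_config("wt", 1.876, division_rule("area", 165),
                      threshold_cv = 0, division_asymmetry_cv = 0.05)
  rec <- simulate_lineages(st, 200, seed = 2)
  pts <- homeostasis_points(rec, "area")
  expect_equal(pts$delta, 165 - pts$birth, tolerance = 1e-12)
})

test_that("binned regression recovers exact linear relations", {
  set.seed(3)
  x <- runif(500, 0, 10)
  b <- bin_series(x, 2 * x)
  ln <- fit_line(b)
  expect_equal(ln$slope, 2, tolerance = 1e-9)
  expect_equal(ln$intercept, 0, tolerance = 1e-9)
  expect_true(all(b$count >= 5))
  expect_error(bin_series(x[1:6], x[1:6] * 2, min_per_bin = 5),
               "length|bins")
})

test_that("normalized RMSD matches the hand-computed example and its symmetries", {
  mk <- function(s, i, r = c(0, 1)) {
    structure(list(slope = s, intercept = i, slope_sd = 0.1,
                   intercept_sd = 0.1,
                   covariance = diag(c(0.01, 0.01)), range = r),
              class = "regression_line")
  }
  # identical lines: zero
  same <- normalized_rmsd(list(mk(1, 0), mk(1, 0), mk(1, 0)))
  expect_equal(same$normalized, 0)
  # y = x, y = x, y = x + 1 on [0, 1]
  rep1 <- normalized_rmsd(list(mk(1, 0), mk(1, 0), mk(1, 1)))
  expect_equal(sort(rep1$pairwise), c(0, 1, 1))
  expect_equal(rep1$mean_y, 5 / 6, tolerance = 1e-12)
  expect_equal(rep1$normalized, 2.400, tolerance = 1e-12)
  # scale invariance: y -> k y
  k <- 7.3
  rep2 <- normalized_rmsd(list(mk(k, 0), mk(k, 0), mk(k, k)))
  expect_equal(rep2$normalized, rep1$normalized)
  # strain reordering invariance
  rep3 <- normalized_rmsd(list(mk(1, 1), mk(1, 0), mk(1, 0)))
  expect_equal(rep3$normalized, rep1$normalized)
  # disjoint ranges: diagnostic error
  expect_error(
    normalized_rmsd(list(mk(1, 0, c(0, 1)), mk(1, 0, c(2, 3)),
                         mk(1, 0, c(0, 1)))),
    "common range")
})

test_that("Monte-Carlo RMSD p values behave at the two extremes", {
  st <- strain_config("wt", 1.876, division_rule("area", 165))
  recs <- three_strain_records(division_rule("area", 165), n = 300,
                               seed = 4)
  lines_for <- function(measure) {
    lapply(recs, function(r) {
      pts <- homeostasis_points(r, measure)
      fit_line(bin_series(pts$birth, pts$delta))
    })
  }
  A <- list(lines = unname(lines_for("area")))
  # identical setups, same seed: identical samples, p = 1
  res <- rmsd_difference_pvalue(A, A, n_mc = 500, seed = 5)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # well separated setups: vanishing p
  far <- lapply(A$lines, function(l) {
    l$intercept <- l$intercept + 300; l
  })
  far[[1]]$intercept <- far[[1]]$intercept + 500
  res2 <- rmsd_difference_pvalue(A, list(lines = far), n_mc = 2000,
                                 seed = 6)
  expect_lt(res2$p_value, 1e-10)
})

test_that("gamma scan recovers the generating measure's exponent", {
  # noise-free area sizer: optimum exactly 1, objective ~ 0 there
  recs <- three_strain_records(division_rule("area", 165), n = 300,
                               seed = 7, radius_cv = 0, threshold_cv = 0,
                               division_asymmetry_cv = 0.05)
  sc <- gamma_scan(recs)
  expect_equal(sc$optimum, 1.00, tolerance = 1e-9)
  expect_lt(min(sc$objective, na.rm = TRUE), 1e-6)
  # noise-free length sizer: optimum exactly 0
  recl <- three_strain_records(division_rule("length", 14), n = 300,
                               seed = 8, radius_cv = 0, threshold_cv = 0,
                               division_asymmetry_cv = 0.05)
  expect_equal(gamma_scan(recl)$optimum, 0.00, tolerance = 1e-9)
  # exact-volume sizer: effective exponent near 1.75
  recv <- three_strain_records(division_rule("volume_exact", 180),
                               n = 500, seed = 9, threshold_cv = 0.05)
  expect_equal(gamma_scan(recv)$optimum, 1.8, tolerance = 0.1 / 1.8)
})

test_that("alpha/beta scan identifies exact power laws and flags degeneracy", {
  set.seed(10)
  R <- rep(c(1.5, 1.876, 2.2), each = 80)
  L <- runif(240, 7, 16)
  s1 <- alpha_beta_scan(data.frame(R = R, L = L, Q = 7 * R^2 * L))
  expect_equal(s1$optimum, 2.00)
  expect_lt(min(s1$objective), 1e-9)
  s2 <- alpha_beta_scan(data.frame(R = R, L = L, Q = 7 * L))
  expect_equal(s2$optimum, 0.00)
  expect_warning(
    alpha_beta_scan(data.frame(R = rep(2, 50), L = L[1:50], Q = L[1:50])),
    "unidentifiable")
})

test_that("segmented fits recover two-regime homeostasis structure", {
  set.seed(11)
  n <- 1000
  x <- runif(n, 6, 15)
  brk <- 10.5
  y <- ifelse(x <= brk, 5 - 0.8 * x, 5 - 0.8 * brk - 0.3 * (x - brk)) +
    rnorm(n, 0, 0.3)
  pts <- data.frame(birth = x, delta = y)
  fit <- segmented_homeostasis_fit(pts, breakpoint = "grid")
  expect_equal(fit$slope1, -0.8, tolerance = 0.1 / 0.8)
  expect_equal(fit$slope2, -0.3, tolerance = 0.1 / 0.3)
  expect_lt(abs(fit$breakpoint - 10.5), 0.5)
  # fixed-fraction breakpoint: 60% of mean division size
  fitf <- segmented_homeostasis_fit(pts, breakpoint = "fixed",
                                    division_sizes = rep(17.5, n))
  expect_equal(fitf$breakpoint, 10.5)
  # single-regime data: the two slopes agree within joint uncertainty
  y1 <- 5 - 0.8 * x + rnorm(n, 0, 0.3)
  f1 <- segmented_homeostasis_fit(data.frame(birth = x, delta = y1),
                                  breakpoint = "grid")
  se <- sqrt(sum(summary(f1$line1)$coefficients[2, 2]^2,
                 summary(f1$line2)$coefficients[2, 2]^2))
  expect_lt(abs(f1$slope1 - f1$slope2), 4 * se)
  # breakpoint beyond the data is rejected
  expect_error(segmented_homeostasis_fit(pts, breakpoint = 20), "insufficient")
})

test_that("division geometry fits recover thresholds and reject wrong models", {
  radii <- seq(1.4, 2.3, length.out = 10)
  simg <- function(rule, seed, cv = 0.05) {
    do.call(rbind, lapply(seq_along(radii), function(i) {
      simulate_lineages(
        strain_config(paste0("r", i), radii[i], rule, radius_cv = 0,
                      threshold_cv = cv), 60, seed = seed + i)
    }))
  }
  # area sizer: area model fits with A_div at the generating threshold
  reca <- simg(division_rule("area", 165), 100)
  fa <- division_geometry_fit(reca, "area")
  expect_equal(fa$A_div, 165, tolerance = 3 / 165)
  expect_lt(fa$chi2 / fa$dof, 3)
  # cylinder-volume sizer: area model is rejected, volume model fits
  recv <- simg(division_rule("volume_cylinder", 180), 200)
  fav <- division_geometry_fit(recv, "area")
  expect_lt(fav$p_value, 0.01)
  fvv <- division_geometry_fit(recv, "volume")
  expect_equal(fvv$V_div, 180, tolerance = 0.02)
  # competing rule: crossover fit recovers R* = sqrt(V*/(pi L*))
  rulec <- division_rule("competing", rules = list(
    division_rule("length", 17.5),
    division_rule("volume_cylinder", 180)))
  recc <- do.call(rbind, lapply(seq_along(radii), function(i) {
    simulate_lineages(
      strain_config(paste0("r", i), radii[i], rulec, radius_cv = 0.02,
                    threshold_cv = 0.03), 60, seed = 300 + i)
  }))
  fc <- division_geometry_fit(recc, "crossover")
  expect_equal(fc$R_star, 1.809, tolerance = 0.05 / 1.809)
  expect_error(division_geometry_fit(reca, "area", n_bins = 2), "bins|3")
})

test_that("chi-squared of the generating model is calibrated", {
  radii <- seq(1.4, 2.3, length.out = 10)
  set.seed(12)
  ratios <- vapply(1:200, function(rep) {
    rec <- do.call(rbind, lapply(seq_along(radii), function(i) {
      simulate_lineages(
        strain_config(paste0("r", i), radii[i],
                      division_rule("area", 165), radius_cv = 0,
                      threshold_cv = 0.05), 30,
        seed = 10000 + rep * 17 + i)
    }))
    f <- division_geometry_fit(rec, "area")
    f$chi2 / f$dof
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.15)
})

test_that("division CV matches hand arithmetic and simulation", {
  expect_equal(division_cv(rep(7, 10)), 0)
  expect_equal(division_cv(c(9, 10, 11)), 0.08165, tolerance = 1e-4)
  expect_error(division_cv(c(1)), "at least 2")
  expect_error(division_cv(c(-3, 1)), "positive")
})
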