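test_that("axial projection is flat for uniform images and conserves intensity", {
  img <- matrix(3, 20, 30)
  mask <- matrix(FALSE, 20, 30); mask[6:15, 5:26] <- TRUE
  x <- seq(0, by = 0.1, length.out = 30)
  prof <- project_intensity(img, mask, x, pixel_size = 0.1)
  expect_equal(diff(range(prof$I)), 0)
  expect_equal(sum(prof$I) * attr(prof, "bin_width"), sum(img[mask]))
  expect_error(project_intensity(img, mask & FALSE, x, 0.1), "empty mask")
})

test_that("Gaussian peak fit recovers parameters on clean profiles", {
  prof <- gaussian_profile(10, 50, 7, 0.5)
  fit <- fit_nodal_peak(prof)
  expect_equal(fit$baseline, 10, tolerance = 0.01)
  expect_equal(fit$amplitude, 50, tolerance = 0.01)
  expect_equal(fit$m, 7, tolerance = 0.01)
  expect_equal(fit$sigma, 0.5, tolerance = 0.01)
  expect_equal(fit$W, 2.00, tolerance = 0.01)
})

test_that("flat profiles raise a no-peak error", {
  prof <- gaussian_profile(10, 0, 7, 0.5)
  prof$I <- prof$I + rep(c(-0.01, 0.01), length.out = nrow(prof))
  expect_error(fit_nodal_peak(prof), "no-peak|converge")
})

test_that("peak center is robust to additive noise (Monte Carlo)", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    prof <- gaussian_profile(10, 50, 7, 0.5)
    prof$I <- prof$I + rnorm(nrow(prof), 0, 1)
    fit <- fit_nodal_peak(prof)
    if (abs(fit$m - 7) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("nodal metrics implement the band-integral definitions", {
  # arithmetic identity on a hand-built fit
  fit <- structure(list(m = 7, sigma = 0.75, baseline = 0, amplitude = 1,
                        W = 3, profile = gaussian_profile(0, 1, 7, 0.75)),
                   class = "nodal_fit")
  fit$N_nodal <- 100; fit$A_nodal <- 2 * pi * 2 * 3
  expect_equal(100 / (2 * pi * 2 * 3), 2.6526, tolerance = 1e-4)
  # band integral of a pure Gaussian: 95.45% of the total mass
  prof <- gaussian_profile(0, 50, 7, 0.5, dx = 0.01)
  f <- fit_nodal_peak(prof)
  mfit <- nodal_metrics(f, R = 2)
  expect_equal(mfit$N_nodal, 0.9545 * 50 * 0.5 * sqrt(2 * pi),
               tolerance = 0.01)
  # identity rho * A = N for arbitrary fits
  expect_equal(mfit$rho_nodal * mfit$A_nodal, mfit$N_nodal)
  # baseline subtraction changes the integral by baseline x span exactly
  prof2 <- gaussian_profile(10, 50, 7, 0.5, dx = 0.01)
  f2 <- fit_nodal_peak(prof2)
  on <- nodal_metrics(f2, R = 2, subtract_baseline = TRUE)
  off <- nodal_metrics(f2, R = 2, subtract_baseline = FALSE)
  inb <- prof2$x >= f2$m - 2 * f2$sigma & prof2$x <= f2$m + 2 * f2$sigma
  expect_equal(off$N_nodal - on$N_nodal, f2$baseline * sum(inb) * 0.01)
  # band outside support is an error
  prof3 <- gaussian_profile(10, 50, 0.4, 0.5, xlim = c(0, 3))
  f3 <- fit_nodal_peak(prof3)
  expect_error(nodal_metrics(f3, R = 2), "support")
})

test_that("cytoplasmic concentration excludes nucleus and nodal zone", {
  img <- matrix(5, 10, 10)
  cellm <- matrix(TRUE, 10, 10)
  nucm <- matrix(FALSE, 10, 10)
  expect_equal(cytoplasmic_concentration(img, cellm, nucm), 5)
  img[4:6, 4:6] <- 20; nucm[4:6, 4:6] <- TRUE
  expect_equal(cytoplasmic_concentration(img, cellm, nucm), 5)
  expect_error(cytoplasmic_concentration(img, cellm, cellm), "empty")
})

test_that("rendered cells round-trip through quantification", {
  p <- model_params(W = 2)
  img <- render_cell(12, 1.876, p, "wt", noise = 0, pixel_size = 0.1)
  q <- quantify_cell(img)
  expect_equal(q$m, img$truth$m, tolerance = 0.1 / img$truth$m)
  expect_equal(q$sigma, img$truth$sigma_band, tolerance = 0.01)
  # integral of (image - backgrounds) over the band = N_nodal metric
  zone <- img$x >= q$m - 2 * q$sigma & img$x <= q$m + 2 * q$sigma
  bg <- img$truth$cyto_bg + img$truth$memb_bg
  direct <- sum((img$zsum - bg * img$mask)[, zone])
  expect_equal(q$N_nodal, direct, tolerance = 0.01)
  expect_error(render_cell(12, 1.876, p, "wt", pixel_size = 0.6),
               "too coarse")
})

test_that("rendered nodal amounts follow the model scalings exactly at zero noise", {
  p <- model_params(W = 2)
  # wt: same L, doubled radius -> amount scales with (cylinder) volume
  a <- render_cell(14, 1, p, "wt", noise = 0)$truth$N_nodal
  b <- render_cell(14, 2, p, "wt", noise = 0)$truth$N_nodal
  expect_equal(b / a, 4)
  # t166a: equal area, different shape -> equal amounts
  a2 <- render_cell(16, 1.25, p, "t166a", noise = 0)$truth$N_nodal
  b2 <- render_cell(10, 2, p, "t166a", noise = 0)$truth$N_nodal
  expect_equal(a2, b2)
})

test_that("fitted nodal width is independent of cell size on constant-W renders", {
  p <- model_params(W = 2)
  Ws <- c(
    vapply(c(9, 12, 15, 18), function(L)
      quantify_cell(render_cell(L, 1.876, p, "wt"))$W, numeric(1)),
    vapply(c(1.5, 1.876, 2.2), function(R)
      quantify_cell(render_cell(14, R, p, "wt"))$W, numeric(1)))
  expect_lt(diff(range(Ws)), 0.02)
  expect_equal(mean(Ws), 2, tolerance = 0.01)
})

test_that("measured nodal quantities track the predicted geometric quantity", {
  p <- model_params(W = 2)
  n <- 120
  set.seed(42)
  Ls <- runif(n, 7.5, 20)
  Rs <- sample(c(1.5, 1.876, 2.2), n, TRUE)
  qw <- do.call(rbind, lapply(seq_len(n), function(i) {
    im <- render_cell(Ls[i], Rs[i], p, "wt", noise = 0.1, pixel_size = 0.15)
    cbind(quantify_cell(im), V = pi * Rs[i]^2 * Ls[i],
          A = 2 * pi * Rs[i] * Ls[i], L = Ls[i])
  }))
  r2 <- function(f, d) summary(stats::lm(f, d))$r.squared
  # wt: N tracks volume (and beats length); rho tracks area
  expect_gt(r2(N_nodal ~ V, qw), 0.85)
  expect_gt(r2(N_nodal ~ V, qw), r2(N_nodal ~ L, qw))
  expect_gt(r2(rho_nodal ~ A, qw), 0.85)
  set.seed(43)
  qt <- do.call(rbind, lapply(seq_len(n), function(i) {
    im <- render_cell(Ls[i], Rs[i], p, "t166a", noise = 0.1,
                      pixel_size = 0.15)
    cbind(quantify_cell(im), V = pi * Rs[i]^2 * Ls[i],
          A = 2 * pi * Rs[i] * Ls[i], L = Ls[i])
  }))
  # t166a: N tracks area (and beats volume); rho tracks length
  expect_gt(r2(N_nodal ~ A, qt), 0.85)
  expect_gt(r2(N_nodal ~ A, qt), r2(N_nodal ~ V, qt))
  expect_gt(r2(rho_nodal ~ L, qt), 0.8)
  # cytoplasmic concentration is flat against length in the wt model
  cc <- stats::lm(cyto_conc ~ L, qw)
  drift <- abs(coef(cc)[2]) * diff(range(qw$L)) / mean(qw$cyto_conc)
  expect_lt(drift, 0.03)
})

test_that("profile CSV loads with inferred bin width", {
  path <- withr::local_tempfile(fileext = ".csv")
  prof <- gaussian_profile(5, 20, 6, 0.4)
  utils::write.csv(data.frame(x_um = prof$x, intensity = prof$I), path,
                   row.names = FALSE)
  back <- read_profile(path)
  expect_equal(attr(back, "bin_width"), 0.05, tolerance = 1e-9)
  fit <- fit_nodal_peak(back)
  expect_equal(fit$m, 6, tolerance = 0.01)
})
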