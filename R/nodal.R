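#' Axial intensity projection
#'
#' Sums masked pixel intensities within axial bins along the symmetry
#' axis and reports an intensity density (a.u. per um): the integral of
#' the profile over x equals the total masked intensity exactly.
#'
#' @param image A `synthetic_cell_image`, or a numeric matrix with
#'   `mask`, `x` (column coordinates, um) and `pixel_size` supplied.
#' @param mask,x,pixel_size Required when `image` is a bare matrix.
#' @return Object of class `axial_profile`: data.frame with columns
#'   `x` (bin centre, um) and `I` (a.u./um), attribute `bin_width`.
#' @export
project_intensity <- function(image, mask = NULL, x = NULL,
                              pixel_size = NULL) {
  if (inherits(image, "synthetic_cell_image")) {
    mask <- image$mask; x <- image$x; pixel_size <- image$pixel_size
    image <- image$zsum
  }
  stopifnot(is.matrix(image), is.matrix(mask),
            all(dim(image) == dim(mask)))
  if (!any(mask)) stop("empty mask")
  I <- colSums(image * mask) / pixel_size
  keep <- colSums(mask) > 0
  out <- data.frame(x = x[keep], I = I[keep])
  attr(out, "bin_width") <- pixel_size
  class(out) <- c("axial_profile", "data.frame")
  out
}

#' Load an axial profile from CSV
#'
#' Columns `x_um`, `intensity`. Bin width is inferred from the median
#' spacing.
#'
#' @param path CSV path.
#' @export
read_profile <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_um", "intensity") %in% names(d))) {
    stop("profile CSV must have columns x_um, intensity")
  }
  out <- data.frame(x = d$x_um, I = d$intensity)
  attr(out, "bin_width") <- stats::median(diff(sort(out$x)))
  class(out) <- c("axial_profile", "data.frame")
  out
}

#' Fit the nodal peak with a Gaussian over background
#'
#' Least-squares fit of `I(x) = baseline + amplitude *
#' exp(-(x - m)^2 / (2 sigma^2))`. Initialization: `m` at the argmax of
#' the running-mean-smoothed profile, `sigma` from the full width at
#' half maximum, `baseline` at the profile median. The nodal width is
#' `W = 4 sigma`.
#'
#' @param profile An `axial_profile`.
#' @return Object of class `nodal_fit`: list with `m`, `sigma`,
#'   `baseline`, `amplitude`, `W`, `profile`.
#' @export
fit_nodal_peak <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  x <- profile$x; I <- profile$I
  if (length(x) < 8L) stop("profile too short to fit")
  sm <- stats::filter(I, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- I[is.na(sm)]
  i0 <- which.max(sm)
  m0 <- x[i0]
  b0 <- stats::median(I)
  a0 <- max(sm) - b0
  if (a0 <= 0) stop("no-peak: profile has no maximum above the baseline")
  half <- b0 + a0 / 2
  above <- which(sm >= half)
  fwhm <- if (length(above) > 1) diff(range(x[above])) else diff(range(x)) / 10
  s0 <- max(fwhm / 2.355, diff(range(x)) / 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ baseline + amplitude * exp(-(x - m)^2 / (2 * sigma^2)),
      data = data.frame(x = x, I = I),
      start = list(baseline = b0, amplitude = a0, m = m0, sigma = s0),
      lower = c(-Inf, 0, min(x), 1e-6),
      upper = c(Inf, Inf, max(x), diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("nodal peak fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  resid_sd <- stats::sd(stats::residuals(fit))
  if (cf[["amplitude"]] < 2 * resid_sd) {
    stop("no-peak: amplitude not significantly above baseline")
  }
  structure(list(m = cf[["m"]], sigma = cf[["sigma"]],
                 baseline = cf[["baseline"]],
                 amplitude = cf[["amplitude"]],
                 W = 4 * cf[["sigma"]], profile = profile),
            class = "nodal_fit")
}

#' @export
print.nodal_fit <- function(x, ...) {
  cat("<nodal_fit> m =", format(x$m, digits = 4), "um, sigma =",
      format(x$sigma, digits = 4), "um (W =",
      format(x$W, digits = 4), "um), baseline =",
      format(x$baseline, digits = 4), ", amplitude =",
      format(x$amplitude, digits = 4), "\n")
  if (!is.null(x$N_nodal)) {
    cat("  N_nodal =", format(x$N_nodal, digits = 5),
        " A_nodal =", format(x$A_nodal, digits = 5),
        " rho_nodal =", format(x$rho_nodal, digits = 5), "\n")
  }
  invisible(x)
}

#' @export
coef.nodal_fit <- function(object, ...) {
  c(m = object$m, sigma = object$sigma, baseline = object$baseline,
    amplitude = object$amplitude, W = object$W)
}

#' @export
plot.nodal_fit <- function(x, ...) {
  p <- x$profile
  graphics::plot(p$x, p$I, type = "l", xlab = "axial position (um)",
                 ylab = "intensity (a.u./um)", ...)
  xx <- seq(min(p$x), max(p$x), length.out = 400)
  graphics::lines(xx, x$baseline + x$amplitude *
                    exp(-(xx - x$m)^2 / (2 * x$sigma^2)), col = 2)
  graphics::abline(v = x$m + c(-2, 2) * x$sigma, lty = 3)
  invisible(x)
}

#' Nodal intensity and density
#'
#' The nodal intensity is the integral of the profile over the band
#' `m +/- 2 sigma` (minus the fitted baseline when `subtract_baseline`
#' is on, the default). Dividing by the nodal membrane area
#' `A_nodal = 2 pi R W` gives the nodal density.
#'
#' @param fit A [fit_nodal_peak()] result.
#' @param R Cell radius (um).
#' @param subtract_baseline Subtract `baseline * span` from the band
#'   integral (default `TRUE`).
#' @return The `nodal_fit` completed with `N_nodal`, `A_nodal`,
#'   `rho_nodal`, `R`.
#' @export
nodal_metrics <- function(fit, R, subtract_baseline = TRUE) {
  stopifnot(inherits(fit, "nodal_fit"), R > 0)
  p <- fit$profile
  lo <- fit$m - 2 * fit$sigma
  hi <- fit$m + 2 * fit$sigma
  if (lo < min(p$x) || hi > max(p$x)) {
    stop("band m +/- 2 sigma extends outside the profile support")
  }
  w <- attr(p, "bin_width")
  inb <- p$x >= lo & p$x <= hi
  N <- sum(p$I[inb]) * w
  span <- sum(inb) * w
  if (subtract_baseline) N <- N - fit$baseline * span
  fit$N_nodal <- N
  fit$A_nodal <- 2 * pi * R * fit$W
  fit$rho_nodal <- N / fit$A_nodal
  fit$R <- R
  fit
}

#' Cytoplasmic concentration from the midplane image
#'
#' Mean intensity over the cell mask with the nucleus (and, by
#' default, the medial nodal zone) excluded.
#'
#' @param midplane Numeric matrix.
#' @param cell_mask,nucleus_mask Logical matrices.
#' @param x Column coordinates (um), needed for nodal-zone exclusion.
#' @param nodal_zone Optional `c(lo, hi)` axial window to exclude.
#' @param exclude_nodal Exclude the nodal zone (default `TRUE` when a
#'   zone is given).
#' @return Mean intensity (a.u.).
#' @export
cytoplasmic_concentration <- function(midplane, cell_mask, nucleus_mask,
                                      x = NULL, nodal_zone = NULL,
                                      exclude_nodal = TRUE) {
  keep <- cell_mask & !nucleus_mask
  if (!is.null(nodal_zone) && exclude_nodal) {
    if (is.null(x)) stop("x coordinates needed to exclude the nodal zone")
    inzone <- x >= nodal_zone[1] & x <= nodal_zone[2]
    keep <- keep & !matrix(inzone, nrow = nrow(keep),
                           ncol = ncol(keep), byrow = TRUE)
  }
  if (!any(keep)) stop("empty cytoplasmic region")
  mean(midplane[keep])
}

#' Quantify one rendered cell end to end
#'
#' Projection, peak fit, nodal metrics and cytoplasmic concentration in
#' one call.
#'
#' @param image A `synthetic_cell_image`.
#' @param subtract_baseline Passed to [nodal_metrics()].
#' @return One-row `data.frame`: `m, sigma, W, baseline, N_nodal,
#'   A_nodal, rho_nodal, cyto_conc`.
#' @export
quantify_cell <- function(image, subtract_baseline = TRUE) {
  prof <- project_intensity(image)
  # restrict the fit to the cylindrical midzone: within one cap length
  # of the poles the projected background follows the cap geometry
  # rather than a flat baseline
  R <- image$truth$R; L <- image$truth$L
  keep <- prof$x >= R & prof$x <= L - R
  bw <- attr(prof, "bin_width")
  prof <- prof[keep, ]
  attr(prof, "bin_width") <- bw
  class(prof) <- c("axial_profile", "data.frame")
  fit <- fit_nodal_peak(prof)
  fit <- nodal_metrics(fit, R = image$truth$R,
                       subtract_baseline = subtract_baseline)
  cyto <- cytoplasmic_concentration(
    image$midplane, image$mask, image$nucleus_mask, x = image$x,
    nodal_zone = fit$m + c(-2, 2) * fit$sigma)
  data.frame(m = fit$m, sigma = fit$sigma, W = fit$W,
             baseline = fit$baseline, N_nodal = fit$N_nodal,
             A_nodal = fit$A_nodal, rho_nodal = fit$rho_nodal,
             cyto_conc = cyto)
}
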