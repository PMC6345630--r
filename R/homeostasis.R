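#' Homeostasis points: size increment versus birth size
#'
#' For each cell, the chosen size measure at birth and the increment
#' accumulated by division. On such a plot a perfect sizer has slope
#' -1, an adder slope 0, and a timer (with linear growth and symmetric
#' division) slope 0.
#'
#' @param records A `cell_cycle_records` data.frame.
#' @param measure `"length"`, `"area"`, `"volume_exact"`,
#'   `"volume_cylinder"` or `"general"` (R^gamma L).
#' @param gamma Exponent for the generalized measure.
#' @return `data.frame` with columns `birth`, `delta` (and `strain`).
#' @export
homeostasis_points <- function(records, measure = "area", gamma = NULL) {
  Sb <- switch(measure,
    length = records$L_birth,
    area = records$A_birth,
    volume_exact = records$V_birth,
    volume_cylinder = pi * records$R^2 * records$L_birth,
    general = ,
    general_gamma = records$R^gamma * records$L_birth,
    stop("unknown measure: ", measure))
  Sd <- switch(measure,
    length = records$L_div,
    area = records$A_div,
    volume_exact = records$V_div,
    volume_cylinder = pi * records$R^2 * records$L_div,
    general = ,
    general_gamma = records$R^gamma * records$L_div)
  out <- data.frame(birth = Sb, delta = Sd - Sb)
  if (!is.null(records$strain)) out$strain <- records$strain
  out
}

#' Bin a scatter into equal-width bins
#'
#' Bins span the central 95% of x; bins with fewer than `min_per_bin`
#' points are merged into their nearest neighbour. Each bin reports the
#' mean, standard error and count.
#'
#' @param x,y Numeric vectors.
#' @param n_bins Number of bins (default 10).
#' @param min_per_bin Minimum points per bin (default 5).
#' @return Object of class `binned_series`: data.frame with
#'   `bin_center, mean_x, mean_y, se, count`.
#' @export
bin_series <- function(x, y, n_bins = 10, min_per_bin = 5) {
  stopifnot(length(x) == length(y), length(x) >= 2 * min_per_bin)
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  if (q[1] >= q[2]) stop("degenerate x range: cannot bin")
  brk <- seq(q[1], q[2], length.out = n_bins + 1L)
  idx <- findInterval(x, brk, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  # merge under-populated bins into the nearest populated neighbour
  cnt <- tabulate(idx, n_bins)
  repeat {
    small <- which(cnt > 0L & cnt < min_per_bin)
    if (length(small) == 0L) break
    i <- small[1]
    others <- setdiff(which(cnt > 0L), i)
    if (length(others) == 0L) stop("fewer than 2 usable bins")
    j <- others[which.min(abs(others - i))]
    idx[idx == i] <- j
    cnt <- tabulate(idx, n_bins)
  }
  used <- sort(unique(idx))
  if (length(used) < 2L) stop("fewer than 2 usable bins")
  agg <- function(v, f) as.numeric(tapply(v, idx, f)[as.character(used)])
  out <- data.frame(
    bin_center = (brk[used] + brk[used + 1L]) / 2,
    mean_x = agg(x, mean),
    mean_y = agg(y, mean),
    se = agg(y, stats::sd) / sqrt(agg(y, length)),
    count = agg(y, length))
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Ordinary least squares on binned means
#'
#' Unweighted regression of the bin mean y on the bin mean x, returning
#' the slope and intercept with their standard deviations and the full
#' coefficient covariance.
#'
#' @param binned A [bin_series()] result, or anything with `mean_x`,
#'   `mean_y`.
#' @param weighted Weight bins by `1/se^2` (default `FALSE`).
#' @return Object of class `regression_line`: list with `slope`,
#'   `intercept`, `slope_sd`, `intercept_sd`, `covariance` (2x2,
#'   intercept first), `range` (of `mean_x`).
#' @export
fit_line <- function(binned, weighted = FALSE) {
  w <- if (weighted) 1 / binned$se^2 else NULL
  fit <- stats::lm(mean_y ~ mean_x, data = binned, weights = w)
  # exact linear data (noise-free sizers) triggers a benign
  # "essentially perfect fit" warning from summary.lm
  V <- withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_sd = sqrt(V[2, 2]), intercept_sd = sqrt(V[1, 1]),
                 covariance = V, range = range(binned$mean_x)),
            class = "regression_line")
}

#' @export
print.regression_line <- function(x, ...) {
  cat("<regression_line> slope =", format(x$slope, digits = 4), "+/-",
      format(x$slope_sd, digits = 3), ", intercept =",
      format(x$intercept, digits = 4), "+/-",
      format(x$intercept_sd, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.regression_line <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Fit a size homeostasis plot
#'
#' The standard single-strain analysis: compute increment-vs-birth
#' points in a measure, bin them, and regress the bin means. The fitted
#' slope diagnoses the division control mode (-1 sizer, 0 adder/timer).
#'
#' @param records A `cell_cycle_records` data.frame (one strain).
#' @param measure,gamma See [homeostasis_points()].
#' @param n_bins,min_per_bin See [bin_series()].
#' @param weighted See [fit_line()].
#' @return Object of class `homeostasis_fit`: list with `points`,
#'   `binned`, `line`, `measure`.
#' @export
homeostasis_fit <- function(records, measure = "area", gamma = NULL,
                            n_bins = 10, min_per_bin = 5,
                            weighted = FALSE) {
  pts <- homeostasis_points(records, measure, gamma)
  b <- bin_series(pts$birth, pts$delta, n_bins, min_per_bin)
  ln <- fit_line(b, weighted)
  structure(list(points = pts, binned = b, line = ln,
                 measure = measure, gamma = gamma),
            class = "homeostasis_fit")
}

#' @export
print.homeostasis_fit <- function(x, ...) {
  cat("<homeostasis_fit> measure =", x$measure,
      if (!is.null(x$gamma)) paste0("(gamma=", x$gamma, ")") else "",
      "\n  slope =", format(x$line$slope, digits = 4), "+/-",
      format(x$line$slope_sd, digits = 3),
      " (-1 = sizer, 0 = adder/timer)\n")
  invisible(x)
}

#' @export
coef.homeostasis_fit <- function(object, ...) coef(object$line)

#' @export
summary.homeostasis_fit <- function(object, ...) {
  cat("Size homeostasis fit (", object$measure, ")\n", sep = "")
  cat("  n cells:", nrow(object$points), " bins:", nrow(object$binned), "\n")
  print(object$line)
  invisible(object)
}

#' @export
plot.homeostasis_fit <- function(x, ...) {
  graphics::plot(x$points$birth, x$points$delta, pch = 16,
                 col = grDevices::adjustcolor(1, 0.2),
                 xlab = paste("birth size,", x$measure),
                 ylab = "increment to division", ...)
  graphics::points(x$binned$mean_x, x$binned$mean_y, col = 2, pch = 19)
  graphics::arrows(x$binned$mean_x, x$binned$mean_y - x$binned$se,
                   x$binned$mean_x, x$binned$mean_y + x$binned$se,
                   angle = 90, code = 3, length = 0.03, col = 2)
  graphics::abline(x$line$intercept, x$line$slope, col = 2)
  invisible(x)
}

#' Two-regime (segmented) homeostasis fit
#'
#' Some mutants show distinct slopes for small and large birth sizes.
#' `breakpoint = "fixed"` places the break at 60% of the mean division
#' size; `breakpoint = "grid"` searches bin-mean candidates for the
#' break minimizing the total SSE of two independent lines (continuity
#' is not enforced).
#'
#' @param points Output of [homeostasis_points()].
#' @param breakpoint `"grid"`, `"fixed"`, or a numeric break.
#' @param division_sizes Division sizes (needed for `"fixed"`).
#' @param fixed_fraction Fraction of mean division size (default 0.6).
#' @param min_points Minimum points per segment (default 10).
#' @return Object of class `segmented_fit`: `slope1`, `slope2`,
#'   `breakpoint`, `line1`, `line2`, `sse`.
#' @export
segmented_homeostasis_fit <- function(points, breakpoint = "grid",
                                      division_sizes = NULL,
                                      fixed_fraction = 0.6,
                                      min_points = 10) {
  x <- points$birth; y <- points$delta
  fit_two <- function(bp) {
    lo <- x <= bp; hi <- !lo
    if (sum(lo) < min_points || sum(hi) < min_points) return(NULL)
    f1 <- stats::lm(y[lo] ~ x[lo])
    f2 <- stats::lm(y[hi] ~ x[hi])
    list(bp = bp, f1 = f1, f2 = f2,
         sse = sum(stats::residuals(f1)^2) + sum(stats::residuals(f2)^2))
  }
  if (identical(breakpoint, "fixed")) {
    if (is.null(division_sizes)) {
      stop("breakpoint = 'fixed' needs division_sizes")
    }
    cand <- fixed_fraction * mean(division_sizes)
    best <- fit_two(cand)
    if (is.null(best)) stop("insufficient points on one side of the breakpoint")
  } else if (is.numeric(breakpoint)) {
    best <- fit_two(breakpoint)
    if (is.null(best)) stop("insufficient points on one side of the breakpoint")
  } else {
    cand <- stats::quantile(x, seq(0.1, 0.9, by = 0.02), names = FALSE)
    fits <- Filter(Negate(is.null), lapply(cand, fit_two))
    if (length(fits) == 0L) stop("no admissible breakpoint: too few points per segment")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  }
  s1 <- unname(stats::coef(best$f1)[2])
  s2 <- unname(stats::coef(best$f2)[2])
  structure(list(slope1 = s1, slope2 = s2, breakpoint = best$bp,
                 line1 = best$f1, line2 = best$f2, sse = best$sse),
            class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> break at", format(x$breakpoint, digits = 4),
      ": slopes", format(x$slope1, digits = 3), "/",
      format(x$slope2, digits = 3), "\n")
  invisible(x)
}

#' Coefficient of variation of division sizes
#'
#' Population convention: the SD uses the 1/n divisor (a descriptive
#' statistic of the measured population, not an estimator).
#'
#' @param sizes Division sizes (n >= 2, positive mean).
#' @return sd/mean.
#' @export
division_cv <- function(sizes) {
  n <- length(sizes)
  if (n < 2L) stop("need at least 2 division sizes")
  m <- mean(sizes)
  if (m <= 0) stop("mean division size must be positive")
  sqrt(sum((sizes - m)^2) / n) / m
}
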