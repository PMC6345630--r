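#' Normalized RMSD between three strain regression lines
#'
#' The model-discrimination statistic for strain overlap. On the common
#' x range (intersection of the three per-strain ranges), each pair of
#' regression lines is evaluated at `N = 20` equally spaced points and
#' their RMSD computed; the sum of the three pairwise RMSDs is divided
#' by the mean of all 3 x 20 line values. Low values mean the strains
#' collapse onto a single curve in the chosen size measure.
#'
#' @param lines List of three [fit_line()] results (or any objects with
#'   `slope` and `intercept`).
#' @param ranges List of three `c(min, max)` x ranges; defaults to the
#'   lines' own `range` fields.
#' @param n_points Number of evaluation points (default 20).
#' @return Object of class `rmsd_report`: `pairwise` (3 values),
#'   `normalized`, `mean_y`, `common_range`, `n_points`.
#' @export
normalized_rmsd <- function(lines, ranges = NULL, n_points = 20) {
  stopifnot(length(lines) == 3L)
  if (is.null(ranges)) ranges <- lapply(lines, `[[`, "range")
  stopifnot(length(ranges) == 3L)
  lo <- max(vapply(ranges, `[`, numeric(1), 1))
  hi <- min(vapply(ranges, `[`, numeric(1), 2))
  if (lo >= hi) {
    stop(sprintf("empty common range: [%g, %g] vs [%g, %g] vs [%g, %g]",
                 ranges[[1]][1], ranges[[1]][2], ranges[[2]][1],
                 ranges[[2]][2], ranges[[3]][1], ranges[[3]][2]))
  }
  xi <- seq(lo, hi, length.out = n_points)
  Y <- vapply(lines, function(l) l$intercept + l$slope * xi,
              numeric(n_points))
  pair <- utils::combn(3, 2)
  pw <- apply(pair, 2, function(p) sqrt(mean((Y[, p[1]] - Y[, p[2]])^2)))
  mean_y <- mean(Y)
  structure(list(pairwise = pw, normalized = sum(pw) / mean_y,
                 mean_y = mean_y, common_range = c(lo, hi),
                 n_points = n_points),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat("<rmsd_report> normalized RMSD =", format(x$normalized, digits = 4),
      "\n  pairwise:", paste(format(x$pairwise, digits = 4), collapse = ", "),
      "\n  common range: [", format(x$common_range[1], digits = 4), ",",
      format(x$common_range[2], digits = 4), "], mean y =",
      format(x$mean_y, digits = 4), "\n")
  invisible(x)
}

# sample (intercept, slope) jointly from the fitted covariance
sample_line <- function(line, n) {
  Vc <- chol(line$covariance)
  z <- matrix(stats::rnorm(2 * n), n, 2) %*% Vc
  data.frame(intercept = line$intercept + z[, 1],
             slope = line$slope + z[, 2])
}

#' Monte-Carlo p value for an RMSD difference
#'
#' Propagates regression uncertainty into the normalized RMSD: for each
#' setup (three lines + ranges), slope/intercept pairs are drawn from
#' the fitted bivariate normal of each line, the normalized RMSD is
#' recomputed per draw, and the two RMSD samples are compared with a
#' two-sample t test.
#'
#' @param setupA,setupB Lists with `lines` (3 [fit_line()] results) and
#'   optional `ranges`.
#' @param n_mc Monte-Carlo draws (default 10000).
#' @param seed Seed for the draws.
#' @return List with `p_value`, `t_statistic`, `rmsdA`, `rmsdB`
#'   (sample means), `n_mc`.
#' @export
rmsd_difference_pvalue <- function(setupA, setupB, n_mc = 10000,
                                   seed = NULL) {
  draw <- function(setup) {
    # common random numbers across the two setups: identical setups
    # give identical RMSD samples (t = 0, p = 1)
    if (!is.null(seed)) set.seed(seed)
    lines <- setup$lines
    ranges <- if (is.null(setup$ranges)) lapply(lines, `[[`, "range")
              else setup$ranges
    for (l in lines) {
      if (any(diag(l$covariance) <= 0)) {
        stop("degenerate uncertainty: zero-variance regression")
      }
    }
    samp <- lapply(lines, sample_line, n = n_mc)
    vapply(seq_len(n_mc), function(i) {
      li <- lapply(seq_along(lines), function(k) {
        list(slope = samp[[k]]$slope[i],
             intercept = samp[[k]]$intercept[i])
      })
      normalized_rmsd(li, ranges)$normalized
    }, numeric(1))
  }
  a <- draw(setupA)
  b <- draw(setupB)
  if (stats::sd(a - b) == 0) {
    return(list(p_value = 1, t_statistic = 0,
                rmsdA = mean(a), rmsdB = mean(b), n_mc = n_mc))
  }
  tt <- stats::t.test(a, b)
  list(p_value = tt$p.value, t_statistic = unname(tt$statistic),
       rmsdA = mean(a), rmsdB = mean(b), n_mc = n_mc)
}

#' Generalized size-measure exponent scan (gamma)
#'
#' For each gamma on the grid, homeostasis plots in the measure
#' R^gamma L are fitted per strain and the three-strain normalized RMSD
#' evaluated; the optimum is the gamma minimizing it. gamma = 0 is
#' length sensing, gamma = 1 area sensing, and gamma of about 1.75 the
#' effective exponent of spherocylinder volume.
#'
#' @param records_by_strain List of three `cell_cycle_records` (one per
#'   strain), or one records data.frame with a `strain` column holding
#'   three strains.
#' @param gammas Exponent grid (default `seq(0, 3, 0.01)`).
#' @param n_bins,min_per_bin Passed to [bin_series()].
#' @return Object of class `exponent_scan`: `grid`, `objective`,
#'   `optimum`, `kind = "gamma"`.
#' @export
gamma_scan <- function(records_by_strain, gammas = seq(0, 3, by = 0.01),
                       n_bins = 10, min_per_bin = 5) {
  if (is.data.frame(records_by_strain)) {
    records_by_strain <- split(records_by_strain,
                               records_by_strain$strain)
  }
  stopifnot(length(records_by_strain) == 3L)
  obj <- vapply(gammas, function(g) {
    fits <- lapply(records_by_strain, function(rec) {
      pts <- homeostasis_points(rec, "general", gamma = g)
      fit_line(bin_series(pts$birth, pts$delta, n_bins, min_per_bin))
    })
    # exponents at which the strains share no birth-size range cannot
    # be compared (and cannot be the sensed measure): objective NA
    tryCatch(normalized_rmsd(fits)$normalized,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(obj))) stop("no exponent gives a common birth-size range")
  structure(list(grid = gammas, objective = obj,
                 optimum = gammas[which.min(obj)], kind = "gamma"),
            class = "exponent_scan")
}

#' Exponent scan for nodal quantities (alpha, beta = 1)
#'
#' Fits a quantity Q (total nodal amount or nodal density) against the
#' general size measure R^alpha L^beta by least squares
#' `Q = a R^alpha L + b` for each alpha on the grid (beta fixed at 1:
#' only the ratio alpha/beta is identifiable, so beta is a gauge
#' choice). The objective is the fit RMSD normalized by mean Q.
#'
#' @param data `data.frame` with columns `R`, `L`, `Q` spanning at
#'   least two radii.
#' @param alphas Exponent grid (default `seq(-1, 3, 0.05)`).
#' @return Object of class `exponent_scan`: `grid`, `objective`,
#'   `optimum` (alpha/beta), `kind = "alpha_beta"`.
#' @export
alpha_beta_scan <- function(data, alphas = seq(-1, 3, by = 0.05)) {
  stopifnot(all(c("R", "L", "Q") %in% names(data)), all(data$Q > 0))
  if (length(unique(round(data$R, 6))) < 2L) {
    warning("alpha unidentifiable: data span a single radius")
  }
  obj <- vapply(alphas, function(a) {
    x <- data$R^a * data$L
    fit <- stats::lm(Q ~ x, data = data.frame(Q = data$Q, x = x))
    sqrt(mean(stats::residuals(fit)^2)) / mean(data$Q)
  }, numeric(1))
  structure(list(grid = alphas, objective = obj,
                 optimum = alphas[which.min(obj)], kind = "alpha_beta"),
            class = "exponent_scan")
}

#' @export
print.exponent_scan <- function(x, ...) {
  lab <- if (x$kind == "gamma") "gamma" else "alpha/beta"
  cat("<exponent_scan>", lab, "grid [",
      format(min(x$grid)), ",", format(max(x$grid)), "], optimum",
      lab, "=", format(x$optimum, digits = 4),
      "(objective", format(min(x$objective, na.rm = TRUE), digits = 4),
      ")\n")
  invisible(x)
}

#' @export
plot.exponent_scan <- function(x, ...) {
  lab <- if (x$kind == "gamma") expression(gamma) else expression(alpha / beta)
  graphics::plot(x$grid, x$objective, type = "l", xlab = lab,
                 ylab = "normalized RMSD", ...)
  graphics::abline(v = x$optimum, col = 2, lty = 2)
  invisible(x)
}
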