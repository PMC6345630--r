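#' Division length versus radius: log-log geometry fits
#'
#' Bins cells by single-cell mean radius and fits binned
#' log(L_div) vs log(R) under competing sizer hypotheses:
#' * `length`: flat line, intercept log L*;
#' * `area`: slope fixed at -1, intercept log(A_div / 2 pi);
#' * `volume`: slope fixed at -2, intercept log(V_div / pi)
#'   (cylinder approximation V = pi R^2 L);
#' * `free`: unconstrained slope and intercept;
#' * `crossover`: flat (length sizer, thin cells) switching to slope -2
#'   (volume sizer, fat cells) at a radius R*, with continuity
#'   L* = V* / (pi R*^2); R* is grid-searched over the binned radii.
#'
#' Fits are weighted by the inverse squared SE of each bin;
#' chi2 = sum(((obs - model) / SE)^2) with dof = bins - n_params and an
#' upper-tail chi-squared p value.
#'
#' @param records `cell_cycle_records` with `R` and `L_div`.
#' @param model Hypothesis to fit.
#' @param n_bins Radius bins (default 10).
#' @param min_per_bin Minimum cells per bin (default 5).
#' @return Object of class `division_geometry_fit`: `model`, `binned`
#'   (log-log bin table), `slope`, `intercept`, plus per-model
#'   parameters (`A_div`, `V_div`, `L_star`, `R_star`), `chi2`, `dof`,
#'   `p_value`.
#' @export
division_geometry_fit <- function(records,
                                  model = c("area", "volume", "length",
                                            "free", "crossover"),
                                  n_bins = 10, min_per_bin = 5) {
  model <- match.arg(model)
  lR <- log(records$R)
  lL <- log(records$L_div)
  b <- bin_series(lR, lL, n_bins, min_per_bin)
  if (nrow(b) < 3L) stop("need at least 3 radius bins")
  x <- b$mean_x; y <- b$mean_y; se <- b$se
  if (any(se <= 0)) se[se <= 0] <- min(se[se > 0])
  w <- 1 / se^2
  wmean <- function(v) sum(w * v) / sum(w)
  out <- list(model = model, binned = b)
  if (model == "free") {
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    out$slope <- unname(cf[2]); out$intercept <- unname(cf[1])
    pred <- out$intercept + out$slope * x
    npar <- 2L
  } else if (model == "length") {
    out$slope <- 0; out$intercept <- wmean(y)
    out$L_star <- exp(out$intercept)
    pred <- rep(out$intercept, length(x))
    npar <- 1L
  } else if (model == "area") {
    out$slope <- -1; out$intercept <- wmean(y + x)
    out$A_div <- 2 * pi * exp(out$intercept)
    pred <- out$intercept - x
    npar <- 1L
  } else if (model == "volume") {
    out$slope <- -2; out$intercept <- wmean(y + 2 * x)
    out$V_div <- pi * exp(out$intercept)
    pred <- out$intercept - 2 * x
    npar <- 1L
  } else { # crossover: flat then slope -2, continuous at R*
    best <- NULL
    for (rstar in x[-length(x)]) {
      thin <- x <= rstar
      # single parameter c = log(V*/pi); model: thin -> c - 2 rstar,
      # fat -> c - 2 x
      design <- ifelse(thin, -2 * rstar, -2 * x)
      cc <- sum(w * (y - design)) / sum(w)
      pred_c <- cc + design
      chi2 <- sum(w * (y - pred_c)^2)
      if (is.null(best) || chi2 < best$chi2) {
        best <- list(chi2 = chi2, rstar = rstar, cc = cc, pred = pred_c)
      }
    }
    out$R_star <- exp(best$rstar)
    out$V_div <- pi * exp(best$cc)
    out$L_star <- out$V_div / (pi * out$R_star^2)
    out$slope <- c(0, -2)
    out$intercept <- best$cc
    pred <- best$pred
    npar <- 2L
  }
  out$chi2 <- sum(((y - pred) / se)^2)
  out$dof <- nrow(b) - npar
  out$p_value <- stats::pchisq(out$chi2, out$dof, lower.tail = FALSE)
  out$predicted <- pred
  structure(out, class = "division_geometry_fit")
}

#' @export
print.division_geometry_fit <- function(x, ...) {
  cat("<division_geometry_fit>", x$model, "sizer model\n")
  if (x$model == "free") {
    cat("  slope =", format(x$slope, digits = 4), "\n")
  } else if (x$model == "area") {
    cat("  A_div =", format(x$A_div, digits = 5), "um^2 (slope -1)\n")
  } else if (x$model == "volume") {
    cat("  V_div =", format(x$V_div, digits = 5), "um^3 (slope -2)\n")
  } else if (x$model == "length") {
    cat("  L_star =", format(x$L_star, digits = 5), "um (flat)\n")
  } else {
    cat("  R* =", format(x$R_star, digits = 4), "um, V_div =",
        format(x$V_div, digits = 5), "um^3, L* =",
        format(x$L_star, digits = 5), "um\n")
  }
  cat("  chi2 =", format(x$chi2, digits = 4), "on", x$dof,
      "dof, p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.division_geometry_fit <- function(object, ...) {
  c(slope = object$slope[1], intercept = object$intercept)
}

#' @export
plot.division_geometry_fit <- function(x, ...) {
  b <- x$binned
  graphics::plot(b$mean_x, b$mean_y, pch = 19,
                 xlab = "log R (um)", ylab = "log L_div (um)", ...)
  graphics::arrows(b$mean_x, b$mean_y - b$se, b$mean_x, b$mean_y + b$se,
                   angle = 90, code = 3, length = 0.03)
  o <- order(b$mean_x)
  graphics::lines(b$mean_x[o], x$predicted[o], col = 2)
  invisible(x)
}
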