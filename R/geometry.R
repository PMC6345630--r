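#' Cell contour
#'
#' A closed polygon (in micrometres) outlining a segmented cell. The
#' contour is the interface between image segmentation and all geometry
#' computations: downstream code never touches pixels.
#'
#' @param x,y Numeric vectors of vertex coordinates (um), ordered along
#'   the boundary. The polygon is implicitly closed; do not repeat the
#'   first vertex.
#' @param cell_id Identifier carried through the pipeline.
#' @return An object of class `cell_contour`: a list with `x`, `y`,
#'   `cell_id`.
#' @export
cell_contour <- function(x, y, cell_id = "cell") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 12L) stop("contour needs at least 12 vertices")
  if (anyNA(x) || anyNA(y)) stop("contour coordinates must be finite")
  a <- polygon_area(x, y)
  if (abs(a) <= 0) stop("contour encloses no area")
  if (a < 0) { # enforce counter-clockwise orientation
    x <- rev(x); y <- rev(y)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 cell_id = as.character(cell_id)),
            class = "cell_contour")
}

# signed area by the shoelace formula (positive = counter-clockwise)
polygon_area <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# uniform-lamina centroid and covariance from exact polygon moments
# (Green's theorem); equivalent to PCA of the interior point cloud in
# the continuum limit.
polygon_moments <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A  <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Exx <- sum((x^2 + x * xn + xn^2) * cr) / (12 * A)
  Eyy <- sum((y^2 + y * yn + yn^2) * cr) / (12 * A)
  Exy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / (24 * A)
  cov <- matrix(c(Exx - cx^2, Exy - cx * cy,
                  Exy - cx * cy, Eyy - cy^2), 2, 2)
  list(area = A, centroid = c(cx, cy), cov = cov)
}

#' Symmetry axis of a rod-shaped cell
#'
#' Principal-component analysis of the cell interior (computed exactly
#' from polygon moments) gives the dominant elongation direction; cell
#' length is measured along this axis.
#'
#' @param contour A [cell_contour()].
#' @return List with `centroid` (numeric length 2) and `axis` (unit
#'   vector along the long axis, oriented toward positive x when
#'   possible).
#' @export
compute_symmetry_axis <- function(contour) {
  stopifnot(inherits(contour, "cell_contour"))
  m <- polygon_moments(contour$x, contour$y)
  e <- eigen(m$cov, symmetric = TRUE)
  if (e$values[2] / e$values[1] > 0.95^2) {
    stop("axis-undefined: contour is near-circular (principal axes within 5%)")
  }
  ax <- e$vectors[, 1]
  if (ax[1] < 0 || (ax[1] == 0 && ax[2] < 0)) ax <- -ax
  list(centroid = m$centroid, axis = ax)
}

#' Radius profile R(x) along the symmetry axis
#'
#' Vertices are projected on the axis; within axial bins the distances
#' of vertices above and below the axis are averaged separately and the
#' two half-widths averaged, giving the local radius. The axial origin
#' (x = 0) is the pole with the smaller axis projection.
#'
#' @param contour A [cell_contour()].
#' @param axis Output of [compute_symmetry_axis()]; computed if `NULL`.
#' @param bin_width Axial bin width (um). Default `max(0.1, L/100)`.
#' @return Object of class `radius_profile`: list with `x`, `r`, `L`.
#' @export
radius_profile <- function(contour, axis = NULL, bin_width = NULL) {
  stopifnot(inherits(contour, "cell_contour"))
  if (is.null(axis)) axis <- compute_symmetry_axis(contour)
  dx <- contour$x - axis$centroid[1]
  dy <- contour$y - axis$centroid[2]
  t <- dx * axis$axis[1] + dy * axis$axis[2]          # axial coordinate
  s <- -dx * axis$axis[2] + dy * axis$axis[1]         # signed offset
  if (diff(range(t)) <= 0) stop("empty projection range")
  L <- diff(range(t))
  x0 <- t - min(t)
  if (is.null(bin_width)) bin_width <- max(0.1, L / 100)
  brk <- seq(0, L + bin_width, by = bin_width)
  idx <- findInterval(x0, brk, rightmost.closed = TRUE)
  centers <- (brk[-length(brk)] + brk[-1]) / 2
  up <- tapply(abs(s[s >= 0]), idx[s >= 0], mean)
  lo <- tapply(abs(s[s < 0]), idx[s < 0], mean)
  r <- numeric(length(centers)); cnt <- integer(length(centers))
  for (side in list(up, lo)) {
    i <- as.integer(names(side))
    r[i] <- r[i] + side
    cnt[i] <- cnt[i] + 1L
  }
  keep <- cnt > 0L & centers > 0 & centers < L
  r <- (r / pmax(cnt, 1L))[keep]
  xs <- centers[keep]
  # anchor the poles: the radius vanishes at both cell tips
  xs <- c(0, xs, L); r <- c(0, r, 0)
  o <- order(xs)
  xs <- xs[o]; r <- r[o]
  dup <- duplicated(xs)
  structure(list(x = xs[!dup], r = r[!dup], L = L),
            class = "radius_profile")
}

#' Surface area and volume by rotation of the radius profile
#'
#' Treats the cell as the solid of revolution of R(x) about the
#' symmetry axis: A = int 2 pi R sqrt(1 + R'^2) dx and
#' V = int pi R^2 dx, evaluated by the trapezoidal rule with central
#' differences for R'. This is methodology (1): it makes no shape
#' assumption beyond axial symmetry.
#'
#' @param profile A [radius_profile()].
#' @return Named numeric vector `c(A = , V = )` (um^2, um^3).
#' @export
geometry_by_rotation <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  x <- profile$x; r <- profile$r
  n <- length(x)
  if (n < 8L) stop("radius profile has fewer than 8 samples")
  dr <- numeric(n)
  dr[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  dr[1] <- (r[2] - r[1]) / (x[2] - x[1])
  dr[n] <- (r[n] - r[n - 1]) / (x[n] - x[n - 1])
  fA <- 2 * pi * r * sqrt(1 + dr^2)
  fV <- pi * r^2
  trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  c(A = trapz(x, fA), V = trapz(x, fV))
}

#' Spherocylinder surface area and volume (closed form)
#'
#' A rod of length `L` is a cylinder of length `L - 2R` capped by two
#' hemispheres of radius `R`, giving `A = 2 pi R L` and
#' `V = pi R^2 (L - 2R/3)`. Used by methodologies (2) (single-cell mean
#' radius) and (3) (population mean radius).
#'
#' @param L Cell length (um).
#' @param R Cell radius (um).
#' @return Named numeric vector `c(A = , V = )`. Vectorized over `L`, `R`.
#' @export
geometry_spherocylinder <- function(L, R) {
  if (any(L <= 0) || any(R <= 0)) stop("L and R must be positive")
  if (any(L < 2 * R)) stop("not a rod: L < 2R")
  if (any(L == 2 * R)) warning("L == 2R: spherical limit of the rod")
  A <- 2 * pi * R * L
  V <- pi * R^2 * (L - 2 * R / 3)
  if (length(L) == 1L && length(R) == 1L) c(A = A, V = V)
  else data.frame(A = A, V = V)
}

# mean radius of a single cell: average of R(x) over the cylindrical
# mid-zone, excluding one cap-length from each pole (the hemispherical
# caps would otherwise bias the mean downward)
profile_mean_radius <- function(profile) {
  r0 <- stats::quantile(profile$r, 0.9, names = FALSE)
  mid <- profile$x >= r0 & profile$x <= profile$L - r0
  if (!any(mid)) return(max(profile$r))
  mean(profile$r[mid])
}

#' Full geometry of one cell from its contour
#'
#' Runs the axis, profile, rotation and closed-form computations and
#' returns one row per cell: length `L`, single-cell mean radius
#' `R_mean`, rotation-method `A_rot`/`V_rot` (methodology 1) and
#' spherocylinder `A_sc`/`V_sc` with the cell's own radius
#' (methodology 2).
#'
#' @param contour A [cell_contour()] or list of them.
#' @param bin_width Passed to [radius_profile()].
#' @return `data.frame` with columns `cell_id, L, R_mean, A_rot, V_rot,
#'   A_sc, V_sc, methodology`.
#' @export
cell_geometry <- function(contour, bin_width = NULL) {
  if (inherits(contour, "cell_contour")) contour <- list(contour)
  rows <- lapply(contour, function(ct) {
    ax <- compute_symmetry_axis(ct)
    pr <- radius_profile(ct, ax, bin_width)
    rot <- geometry_by_rotation(pr)
    R <- profile_mean_radius(pr)
    sc <- geometry_spherocylinder(pr$L, R)
    data.frame(cell_id = ct$cell_id, L = pr$L, R_mean = R,
               A_rot = rot[["A"]], V_rot = rot[["V"]],
               A_sc = sc[["A"]], V_sc = sc[["V"]],
               methodology = 2L)
  })
  do.call(rbind, rows)
}

#' Population-mean-radius geometry (methodology 3)
#'
#' Replaces each cell's radius by the strain-wide mean radius and
#' recomputes the spherocylinder area and volume, as used for the main
#' strain-level plots. With a `strain` column the mean is taken within
#' strain.
#'
#' @param geom Output of [cell_geometry()] (optionally with a `strain`
#'   column).
#' @return The input with `A_sc`, `V_sc` recomputed at the population
#'   mean radius, `R_bar` attached, `methodology = 3`.
#' @export
population_mean_radius <- function(geom) {
  if (nrow(geom) == 0L) stop("no cells")
  grp <- if ("strain" %in% names(geom)) geom$strain else rep("all", nrow(geom))
  rbar <- ave(geom$R_mean, grp)
  geom$R_bar <- rbar
  geom$A_sc <- 2 * pi * rbar * geom$L
  geom$V_sc <- pi * rbar^2 * (geom$L - 2 * rbar / 3)
  geom$methodology <- 3L
  geom
}

#' Read / write contour tables
#'
#' Contour CSV dialect: columns `cell_id, vertex_index, x_um, y_um`.
#'
#' @param path CSV file path.
#' @return `read_contours()`: a named list of [cell_contour()] objects.
#' @export
read_contours <- function(path) {
  d <- utils::read.csv(path)
  need <- c("cell_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$vertex_index), ]
    cell_contour(g$x_um, g$y_um, cell_id = g$cell_id[1])
  })
  out
}

#' @rdname read_contours
#' @param contours List of [cell_contour()] objects.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "cell_contour")) contours <- list(contours)
  rows <- lapply(contours, function(ct) {
    data.frame(cell_id = ct$cell_id,
               vertex_index = seq_along(ct$x) - 1L,
               x_um = ct$x, y_um = ct$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cell_contour <- function(x, ...) {
  cat("<cell_contour>", x$cell_id, "-", length(x$x), "vertices, area",
      format(abs(polygon_area(x$x, x$y)), digits = 4), "um^2\n")
  invisible(x)
}

#' @export
print.radius_profile <- function(x, ...) {
  cat("<radius_profile> L =", format(x$L, digits = 4), "um,",
      length(x$x), "samples, max R =",
      format(max(x$r), digits = 4), "um\n")
  invisible(x)
}
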