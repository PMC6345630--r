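#' Render a synthetic fluorescence image of one cell
#'
#' Generates the z-sum projection and midplane image of a rod carrying
#' a medial nodal band. The z-sum image is a constant cytoplasmic
#' background plus a constant membrane background inside the cell mask,
#' plus a Gaussian band centred at mid-cell with axial SD
#' `sigma_band = W/4` whose integrated amount equals the steady-state
#' nodal amount of the chosen model times multiplicative lognormal
#' noise. The midplane carries the cytoplasmic concentration signal
#' with the nucleus (a constant midplane-area fraction) excluded.
#'
#' @param L,R Cell length and radius (um), `L > 2R`.
#' @param params A [model_params()] (supplies `W`, hence
#'   `sigma_band = W/4`, and the steady-state amplitude).
#' @param which_model `"wt"` (volume scaling) or `"t166a"` (area
#'   scaling).
#' @param noise CV of the lognormal noise on the nodal amount.
#' @param pixel_size Pixel size (um); must not exceed `sigma_band`.
#' @param cyto_level Midplane cytoplasmic intensity per pixel
#'   (proportional to the Cdr2 concentration).
#' @param cyto_bg,memb_bg Constant z-sum background levels per masked
#'   pixel (cytoplasmic and membrane contributions).
#' @param nucleus_fraction Nucleus area fraction of the midplane mask.
#' @param seed Optional seed (noise only).
#' @return Object of class `synthetic_cell_image`: list with `zsum`,
#'   `midplane` (matrices, rows = y, cols = x), `mask`, `nucleus_mask`
#'   (logical matrices), `x`, `y` (pixel-centre coordinates, um),
#'   `pixel_size`, `axis`, and `truth` (the ground-truth band
#'   parameters `m`, `sigma_band`, `N_nodal`, backgrounds).
#' @export
render_cell <- function(L, R, params, which_model = c("wt", "t166a"),
                        noise = 0, pixel_size = 0.1,
                        cyto_level = 10, cyto_bg = 2, memb_bg = 1,
                        nucleus_fraction = 0.08, seed = NULL) {
  which_model <- match.arg(which_model)
  stopifnot(inherits(params, "model_params"), L > 2 * R)
  sigma_band <- params$W / 4
  if (pixel_size > sigma_band) {
    stop("pixel_size too coarse: exceeds the nodal band SD W/4")
  }
  if (!is.null(seed)) set.seed(seed)
  pad <- 2 * pixel_size
  xs <- seq(-pad, L + pad, by = pixel_size)
  ys <- seq(-R - pad, R + pad, by = pixel_size)
  # rod half-width at axial position x
  halfwidth <- function(x) {
    h <- numeric(length(x))
    incap1 <- x >= 0 & x < R
    incap2 <- x > L - R & x <= L
    mid <- x >= R & x <= L - R
    h[mid] <- R
    h[incap1] <- sqrt(pmax(R^2 - (R - x[incap1])^2, 0))
    h[incap2] <- sqrt(pmax(R^2 - (x[incap2] - (L - R))^2, 0))
    h
  }
  hw <- halfwidth(xs)
  mask <- outer(ys, hw, function(y, h) abs(y) <= h & h > 0)
  N_true <- steady_state_nodal(params, list(L = L, R = R),
                               mode = which_model)
  N_render <- N_true * lognorm_noise(1, noise)
  m <- L / 2
  # distribute the band so each axial pixel column of the mask sums to
  # N * Normal(x; m, sigma) * pixel_size
  colsum <- colSums(mask)
  band_col <- N_render * stats::dnorm(xs, m, sigma_band) * pixel_size
  zsum <- matrix(0, nrow = length(ys), ncol = length(xs))
  zsum[mask] <- cyto_bg + memb_bg
  for (j in which(colsum > 0 & band_col > 0)) {
    zsum[mask[, j], j] <- zsum[mask[, j], j] + band_col[j] / colsum[j]
  }
  # midplane: cytoplasm at cyto_level, nucleus dimmed (GFP excluded),
  # nodal band visible at the cortex rows of the medial region
  midplane <- matrix(0, nrow = length(ys), ncol = length(xs))
  midplane[mask] <- cyto_level
  nuc_r <- sqrt(nucleus_fraction * sum(mask) * pixel_size^2 / pi)
  nucleus_mask <- outer(ys, xs, function(y, x) (x - m)^2 + y^2 <= nuc_r^2) & mask
  midplane[nucleus_mask] <- 0.3 * cyto_level
  edge <- outer(ys, hw, function(y, h) h > 0 & abs(abs(y) - h) <= pixel_size)
  band_mid <- outer(rep(1, length(ys)),
                    exp(-(xs - m)^2 / (2 * sigma_band^2)))
  midplane <- midplane + (edge & mask) * cyto_level * band_mid
  structure(list(zsum = zsum, midplane = midplane, mask = mask,
                 nucleus_mask = nucleus_mask, x = xs, y = ys,
                 pixel_size = pixel_size, axis = c(1, 0),
                 truth = list(m = m, sigma_band = sigma_band,
                              N_nodal = N_render, N_expected = N_true,
                              cyto_bg = cyto_bg, memb_bg = memb_bg,
                              cyto_level = cyto_level, L = L, R = R,
                              which_model = which_model)),
            class = "synthetic_cell_image")
}

#' @export
print.synthetic_cell_image <- function(x, ...) {
  cat("<synthetic_cell_image>", x$truth$which_model, "model, L =",
      format(x$truth$L, digits = 4), "um, R =",
      format(x$truth$R, digits = 4), "um, N_nodal =",
      format(x$truth$N_nodal, digits = 5), "\n")
  invisible(x)
}

#' Write a rendered image to TIFF
#'
#' Optional export for inspection in external viewers; requires the
#' `tiff` package. A JSON sidecar carries the pixel size and ground
#' truth.
#'
#' @param image A `synthetic_cell_image`.
#' @param path Output TIFF path; the sidecar is `paste0(path, ".json")`.
#' @export
write_cell_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  img <- image$zsum / max(image$zsum)
  tiff::writeTIFF(img, path)
  side <- list(pixel_size = image$pixel_size, truth = image$truth)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
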