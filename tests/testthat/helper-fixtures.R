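# shared fixture builders: everything is generated in code at test time

# exact spherocylinder radius profile (no contour discretization error)
exact_profile <- function(L, R, n = 400) {
  x <- seq(0, L, length.out = n)
  r <- numeric(n)
  cap1 <- x < R
  cap2 <- x > L - R
  r[!cap1 & !cap2] <- R
  r[cap1] <- sqrt(pmax(R^2 - (R - x[cap1])^2, 0))
  r[cap2] <- sqrt(pmax(R^2 - (x[cap2] - (L - R))^2, 0))
  structure(list(x = x, r = r, L = L), class = "radius_profile")
}

# analytic axial profile with a Gaussian peak over a flat baseline
gaussian_profile <- function(baseline, amplitude, m, sigma,
                             xlim = c(0, 14), dx = 0.05) {
  x <- seq(xlim[1], xlim[2], by = dx)
  out <- data.frame(x = x,
                    I = baseline + amplitude * exp(-(x - m)^2 / (2 * sigma^2)))
  attr(out, "bin_width") <- dx
  class(out) <- c("axial_profile", "data.frame")
  out
}

# three-strain record sets under a shared rule
three_strain_records <- function(rule, n = 500, seed = 1,
                                 radii = c(1.5, 1.876, 2.2),
                                 names = c("thin", "normal", "fat"),
                                 ...) {
  out <- lapply(seq_along(radii), function(i) {
    simulate_lineages(strain_config(names[i], radii[i], rule, ...),
                      n, seed = seed * 100 + i)
  })
  names(out) <- names
  out
}
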