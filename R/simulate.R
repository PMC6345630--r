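#' Division rules
#'
#' A division rule specifies when a growing rod commits to division.
#' Sizer rules trigger at a threshold on a geometric measure of the
#' cell; `adder` adds a fixed increment of the measure per cycle;
#' `timer` grows for a fixed duration; `competing` divides when the
#' FIRST of its member thresholds is reached.
#'
#' Measures: `length` (L, um), `area` (2 pi R L, um^2), `volume_exact`
#' (pi R^2 (L - 2R/3), um^3), `volume_cylinder` (pi R^2 L, um^3),
#' `general_gamma` (R^gamma L).
#'
#' @param kind One of `"length"`, `"area"`, `"volume_exact"`,
#'   `"volume_cylinder"`, `"general_gamma"`, `"adder"`, `"timer"`,
#'   `"competing"`.
#' @param threshold Threshold (or adder increment, or timer duration in
#'   minutes) in the rule's units.
#' @param gamma Exponent for `general_gamma`.
#' @param measure Measure the `adder` increments (same names as sizer
#'   kinds).
#' @param rules For `competing`: list of sizer rules.
#' @return Object of class `division_rule`.
#' @export
division_rule <- function(kind, threshold = NULL, gamma = NULL,
                          measure = "length", rules = NULL) {
  kinds <- c("length", "area", "volume_exact", "volume_cylinder",
             "general_gamma", "adder", "timer", "competing")
  kind <- match.arg(kind, kinds)
  if (kind == "competing") {
    if (length(rules) < 2L) stop("competing rule needs >= 2 member rules")
    ok <- vapply(rules, function(r) inherits(r, "division_rule") &&
                   !r$kind %in% c("adder", "timer", "competing"), logical(1))
    if (!all(ok)) stop("competing members must be simple sizer rules")
    return(structure(list(kind = kind, rules = rules), class = "division_rule"))
  }
  if (is.null(threshold) || threshold <= 0) stop("threshold must be positive")
  if (kind == "general_gamma" && is.null(gamma)) stop("general_gamma needs gamma")
  structure(list(kind = kind, threshold = threshold, gamma = gamma,
                 measure = measure), class = "division_rule")
}

#' @export
print.division_rule <- function(x, ...) {
  if (x$kind == "competing") {
    cat("<division_rule> competing (first threshold reached):\n")
    for (r in x$rules) { cat("  "); print(r) }
  } else {
    cat("<division_rule>", x$kind,
        if (x$kind == "general_gamma") paste0("(gamma=", x$gamma, ")") else "",
        "threshold", x$threshold,
        if (x$kind == "adder") paste0("on ", x$measure) else "", "\n")
  }
  invisible(x)
}

#' Geometric size measure of a rod
#'
#' @param measure Measure name (see [division_rule()]); `"general"` and
#'   `"general_gamma"` are synonyms.
#' @param L,R Length and radius (um), vectorized.
#' @param gamma Exponent for the generalized measure R^gamma L.
#' @return Numeric vector of sizes in the measure's units.
#' @export
size_measure <- function(measure, L, R, gamma = NULL) {
  switch(measure,
    length = L,
    area = 2 * pi * R * L,
    volume_exact = pi * R^2 * (L - 2 * R / 3),
    volume_cylinder = pi * R^2 * L,
    general = ,
    general_gamma = R^gamma * L,
    stop("unknown measure: ", measure))
}

# length at which a sizer rule's threshold is reached, for radius R
length_at_threshold <- function(rule, R, threshold = rule$threshold) {
  switch(rule$kind,
    length = threshold + 0 * R,
    area = threshold / (2 * pi * R),
    volume_exact = threshold / (pi * R^2) + 2 * R / 3,
    volume_cylinder = threshold / (pi * R^2),
    general_gamma = threshold / R^rule$gamma,
    stop("no length threshold for rule kind ", rule$kind))
}

#' Strain configuration for the synthetic generator
#'
#' @param name Strain label.
#' @param radius_mean Mean cell radius (um).
#' @param radius_cv CV of radius across cells (radius is constant
#'   within a cell cycle).
#' @param growth_rate Length growth rate (um/min), linear in time.
#' @param division_rule A [division_rule()].
#' @param threshold_cv CV of the multiplicative lognormal noise on the
#'   division threshold; the default reproduces the division-size CV
#'   of about 7.5% typical of wild-type sizing.
#' @param division_asymmetry_cv SD of the Gaussian noise on the halving
#'   fraction at division (roughly symmetric division).
#' @param nuclear_fraction Constant nuclear/cell volume fraction c.
#' @param seed Optional per-strain seed.
#' @return Object of class `strain_config`.
#' @export
strain_config <- function(name, radius_mean, division_rule,
                          radius_cv = 0.03, growth_rate = 0.03,
                          threshold_cv = 0.075,
                          division_asymmetry_cv = 0.02,
                          nuclear_fraction = 0.08, seed = NULL) {
  stopifnot(radius_mean > 0, radius_cv >= 0, threshold_cv >= 0,
            division_asymmetry_cv >= 0,
            nuclear_fraction > 0, nuclear_fraction < 1,
            inherits(division_rule, "division_rule"))
  structure(list(name = name, radius_mean = radius_mean,
                 radius_cv = radius_cv, growth_rate = growth_rate,
                 division_rule = division_rule,
                 threshold_cv = threshold_cv,
                 division_asymmetry_cv = division_asymmetry_cv,
                 nuclear_fraction = nuclear_fraction, seed = seed),
            class = "strain_config")
}

#' Thin / normal / fat strain presets
#'
#' Three radius families bracketing the wild-type rod: thin (rga2-like,
#' 1.5 um), normal (wild-type-like, 1.876 um — the radius implied by a
#' division area of 165 um^2 at length 14 um), fat (rga4-like, 2.2 um).
#' The thin and fat radii are plausible defaults, not measured values.
#'
#' @param division_rule Shared [division_rule()]; default area sizer at
#'   165 um^2.
#' @param ... Passed to [strain_config()] for all three presets.
#' @return Named list of three `strain_config`s: `thin`, `normal`, `fat`.
#' @export
strain_presets <- function(division_rule = NULL, ...) {
  if (is.null(division_rule)) division_rule <- division_rule("area", 165)
  list(
    thin   = strain_config("thin",   1.5,   division_rule, ...),
    normal = strain_config("normal", 1.876, division_rule, ...),
    fat    = strain_config("fat",    2.2,   division_rule, ...)
  )
}

# division length for vectors of R under threshold noise (one lognormal
# factor per cell); competing rules take the first threshold reached,
# i.e. the smallest division length, with independent noise per member
division_length <- function(rule, R, threshold_cv) {
  n <- length(R)
  noise <- function() {
    if (threshold_cv <= 0) rep(1, n)
    else {
      sdl <- sqrt(log(1 + threshold_cv^2))
      exp(stats::rnorm(n, -sdl^2 / 2, sdl))
    }
  }
  if (rule$kind == "competing") {
    ls <- sapply(rule$rules, function(r)
      length_at_threshold(r, R, r$threshold * noise()))
    if (is.null(dim(ls))) ls <- matrix(ls, nrow = n)
    apply(ls, 1, min)
  } else {
    length_at_threshold(rule, R, rule$threshold * noise())
  }
}

#' Simulate single-cell cycle records
#'
#' Each lineage grows linearly in length at constant radius, divides
#' when its rule's threshold (with multiplicative lognormal noise of CV
#' `threshold_cv`) is crossed, and splits roughly in half (Gaussian
#' noise of SD `division_asymmetry_cv` on the halving fraction).
#' Lineages are iterated for `generations` cycles so birth sizes are at
#' their stationary distribution; the last cycle is recorded.
#'
#' @param strain A [strain_config()].
#' @param n_cells Number of cells (independent lineages) to record.
#' @param seed Integer seed; falls back to `strain$seed`.
#' @param generations Burn-in cycles before recording (default 8).
#' @param perfect_sizer For sizer rules only: record divisions exactly
#'   at the noiseless threshold while birth sizes keep the inherited
#'   (mother-division and asymmetry) noise. This is the perfect-sizer
#'   limit in which the homeostasis slope is exactly -1; threshold
#'   noise still shapes the birth-size distribution.
#' @return `data.frame` of class `cell_cycle_records` with columns
#'   `strain, cell_id, R, L_birth, A_birth, V_birth, L_div, A_div,
#'   V_div, birth_time, division_time`.
#' @export
simulate_lineages <- function(strain, n_cells, seed = NULL,
                              generations = 8L, perfect_sizer = FALSE) {
  stopifnot(inherits(strain, "strain_config"), n_cells >= 1)
  if (is.null(seed)) seed <- strain$seed
  if (!is.null(seed)) set.seed(seed)
  rule <- strain$division_rule
  R <- strain$radius_mean * (1 + stats::rnorm(n_cells, 0, strain$radius_cv))
  if (any(R <= 0)) stop("radius_cv too large: non-positive radius drawn")
  halve <- function(L_div) {
    f <- 0.5 * (1 + stats::rnorm(n_cells, 0, strain$division_asymmetry_cv))
    L_div * f
  }
  if (rule$kind == "adder") {
    meas <- rule$measure
    # start at one increment of the measure and iterate the adder map
    # to its stationary distribution
    L_b <- length_from_measure(meas, rule$threshold, R)
    for (g in seq_len(generations)) {
      inc <- rule$threshold * lognorm_noise(n_cells, strain$threshold_cv)
      S_d <- size_measure(meas, L_b, R) + inc
      L_d <- length_from_measure(meas, S_d, R)
      L_b <- halve(L_d)
    }
    L_birth <- L_b
    inc <- rule$threshold * lognorm_noise(n_cells, strain$threshold_cv)
    L_div <- length_from_measure(meas, size_measure(meas, L_birth, R) + inc, R)
  } else if (rule$kind == "timer") {
    L_b <- 2.5 * R
    for (g in seq_len(generations)) {
      Tg <- rule$threshold * lognorm_noise(n_cells, strain$threshold_cv)
      L_d <- L_b + strain$growth_rate * Tg
      L_b <- halve(L_d)
    }
    L_birth <- L_b
    Tg <- rule$threshold * lognorm_noise(n_cells, strain$threshold_cv)
    L_div <- L_birth + strain$growth_rate * Tg
  } else {
    # sizer rules: division size is independent of birth size, so the
    # stationary state is reached in one generation — the birth size is
    # half the mother's own (independently drawn) division size
    L_birth <- halve(division_length(rule, R, strain$threshold_cv))
    L_div <- division_length(rule, R,
                             if (perfect_sizer) 0 else strain$threshold_cv)
  }
  if (any(L_div <= L_birth)) {
    stop("division threshold unreachable: division size below birth size")
  }
  if (any(L_birth < 2 * R)) {
    stop("birth length below spherical limit 2R; check rule threshold")
  }
  gb <- geometry_spherocylinder(L_birth, R)
  gd <- geometry_spherocylinder(L_div, R)
  out <- data.frame(
    strain = strain$name,
    cell_id = sprintf("%s_%05d", strain$name, seq_len(n_cells)),
    R = R,
    L_birth = L_birth, A_birth = gb$A, V_birth = gb$V,
    L_div = L_div, A_div = gd$A, V_div = gd$V,
    birth_time = 0,
    division_time = (L_div - L_birth) / strain$growth_rate)
  class(out) <- c("cell_cycle_records", "data.frame")
  out
}

lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

# invert size_measure for L at given R
length_from_measure <- function(measure, S, R, gamma = NULL) {
  switch(measure,
    length = S,
    area = S / (2 * pi * R),
    volume_exact = S / (pi * R^2) + 2 * R / 3,
    volume_cylinder = S / (pi * R^2),
    general = ,
    general_gamma = S / R^gamma,
    stop("unknown measure: ", measure))
}

#' Spherocylinder contour fixture
#'
#' Builds a closed polygon outlining a rod of length `L` and radius
#' `R`, with vertices spaced uniformly in boundary arc length and
#' optional isotropic Gaussian vertex jitter.
#'
#' @param L,R Rod length and radius (um), `L > 2R`.
#' @param n_vertices Number of polygon vertices (>= 12).
#' @param jitter_sd SD of the jitter on each coordinate (um).
#' @param seed Optional seed (jitter only).
#' @param cell_id Identifier.
#' @return A [cell_contour()].
#' @export
make_contour <- function(L, R, n_vertices = 128L, jitter_sd = 0,
                         seed = NULL, cell_id = "synthetic") {
  if (L <= 2 * R) stop("not a rod: L must exceed 2R")
  if (n_vertices < 12L) stop("need at least 12 vertices")
  if (!is.null(seed)) set.seed(seed)
  Lc <- L - 2 * R                       # cylinder length
  per <- 2 * Lc + 2 * pi * R            # perimeter
  s <- seq(0, per, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  x <- numeric(n_vertices); y <- numeric(n_vertices)
  # top edge: x from R to L-R at y = R
  i1 <- s < Lc
  x[i1] <- R + s[i1]; y[i1] <- R
  # right cap: angle from pi/2 to -pi/2
  i2 <- s >= Lc & s < Lc + pi * R
  th <- pi / 2 - (s[i2] - Lc) / R
  x[i2] <- L - R + R * cos(th); y[i2] <- R * sin(th)
  # bottom edge: x from L-R to R at y = -R
  i3 <- s >= Lc + pi * R & s < 2 * Lc + pi * R
  x[i3] <- L - R - (s[i3] - Lc - pi * R); y[i3] <- -R
  # left cap: angle from -pi/2 to -3pi/2
  i4 <- s >= 2 * Lc + pi * R
  th <- -pi / 2 - (s[i4] - 2 * Lc - pi * R) / R
  x[i4] <- R + R * cos(th); y[i4] <- R * sin(th)
  if (jitter_sd > 0) {
    x <- x + stats::rnorm(n_vertices, 0, jitter_sd)
    y <- y + stats::rnorm(n_vertices, 0, jitter_sd)
  }
  cell_contour(x, y, cell_id = cell_id)
}

#' Read / write cell-cycle record tables
#'
#' @param records A `cell_cycle_records` data.frame.
#' @param path CSV path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  d <- utils::read.csv(path)
  need <- c("strain", "R", "L_birth", "A_birth", "V_birth",
            "L_div", "A_div", "V_div")
  if (!all(need %in% names(d))) {
    stop("records CSV must have columns: ", paste(need, collapse = ", "))
  }
  class(d) <- c("cell_cycle_records", "data.frame")
  d
}
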