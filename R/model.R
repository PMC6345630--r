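#' Kinetic parameters of the Cdr2 nodal scaling model
#'
#' The steady-state flux balance for cytoplasmic unphosphorylated Cdr2
#' reads
#'
#'   kp \[Ssp1\] \[Cdr2u\] V_cell + kb \[Cdr2u\] A_memb = lambda N_nodal
#'
#' with `kp` the Ssp1 phosphorylation rate constant, `kb` the direct
#' membrane-binding constant, `lambda` the nodal dissociation rate, and
#' `N_nodal` the total nodal amount. With constant cytoplasmic
#' concentrations the product `kp [Ssp1] [Cdr2]` lumps into a single
#' factor `K`. All units are effective (fluorescence a.u.); only the
#' geometric scalings are meaningful.
#'
#' @param kp,Ssp1,Cdr2 Phosphorylation constant and cytoplasmic
#'   concentrations.
#' @param Cdr2_u Unphosphorylated cytoplasmic Cdr2 concentration
#'   (defaults to `Cdr2`, the fast-membrane-binding limit).
#' @param kb Membrane-binding constant.
#' @param lam Nodal dissociation rate lambda (> 0).
#' @param K Optional lumped constant; if supplied it must equal
#'   `kp * Ssp1 * Cdr2` to within 1e-9 relative.
#' @param f Immobile fraction of the nodal pool, in \[0, 1).
#' @param c Accessible-volume fraction (nucleus and vacuoles excluded),
#'   in (0, 1\].
#' @param W Nodal band width (um).
#' @return Object of class `model_params`.
#' @export
model_params <- function(kp = 1, Ssp1 = 1, Cdr2 = 1, Cdr2_u = Cdr2,
                         kb = 1, lam = 1, K = NULL, f = 0, c = 1,
                         W = 2) {
  stopifnot(kp >= 0, kb >= 0, lam > 0, Ssp1 >= 0, Cdr2 >= 0, W > 0)
  if (f < 0 || f >= 1) stop("immobile fraction f must be in [0, 1)")
  if (c <= 0 || c > 1) stop("accessible-volume fraction c must be in (0, 1]")
  Kcomp <- kp * Ssp1 * Cdr2
  if (!is.null(K)) {
    if (Kcomp > 0 && abs(K - Kcomp) / Kcomp > 1e-9) {
      stop("supplied K disagrees with kp * Ssp1 * Cdr2")
    }
  } else K <- Kcomp
  structure(list(kp = kp, Ssp1 = Ssp1, Cdr2 = Cdr2, Cdr2_u = Cdr2_u,
                 kb = kb, lam = lam, K = K, f = f, c = c, W = W),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> K =", x$K, " kb =", x$kb, " lambda =", x$lam,
      " f =", x$f, " c =", x$c, " W =", x$W, "um\n")
  invisible(x)
}

# Geometry input for the model: a data.frame/list with A and V
# (explicit override), or L and R. Given (L, R) the model adopts the
# rod approximation A = 2 pi R L, V = pi R^2 L: with it the predicted
# scalings are exact algebraic identities (rho_wt a function of A
# alone, rho_t166a of L alone), which is how the model's predictions
# are stated. Measured (exact spherocylinder) volumes can be passed
# explicitly via A/V.
resolve_geometry <- function(geom) {
  g <- as.list(geom)
  if (!is.null(g$A) && !is.null(g$V)) return(list(A = g$A, V = g$V))
  if (!is.null(g$A_sc) && !is.null(g$V_sc)) return(list(A = g$A_sc, V = g$V_sc))
  if (!is.null(g$L) && !is.null(g$R)) {
    return(list(A = 2 * pi * g$R * g$L, V = pi * g$R^2 * g$L))
  }
  stop("geometry must provide A and V, or L and R")
}

#' Steady-state nodal amount
#'
#' Closed-form steady state of the flux balance. `mode = "general"`
#' keeps both influx terms:
#' `N = (kp Ssp1 Cdr2_u c V + kb Cdr2_u A) / lambda`.
#' `mode = "wt"` is the fast-phosphorylation limit (kb -> 0,
#' Cdr2_u -> Cdr2): `N = K c V / lambda`, volume scaling.
#' `mode = "t166a"` removes phosphorylation (kp = 0, Cdr2_u -> Cdr2):
#' `N = kb Cdr2 A / lambda`, area scaling.
#'
#' @param params A [model_params()].
#' @param geom Geometry: anything with fields `A` and `V` (um^2, um^3),
#'   or `L` and `R`, in which case the rod approximation
#'   `A = 2 pi R L`, `V = pi R^2 L` is used — the form in which the
#'   model's scaling predictions are exact. Vectorized.
#' @param mode `"general"`, `"wt"` or `"t166a"`.
#' @return Numeric vector of nodal amounts (a.u.).
#' @export
steady_state_nodal <- function(params, geom, mode = c("general", "wt", "t166a")) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  if (params$lam <= 0) stop("lambda must be positive")
  g <- resolve_geometry(geom)
  switch(mode,
    general = (params$kp * params$Ssp1 * params$Cdr2_u * params$c * g$V +
                 params$kb * params$Cdr2_u * g$A) / params$lam,
    wt = params$K * params$c * g$V / params$lam,
    t166a = params$kb * params$Cdr2 * g$A / params$lam)
}

#' Predicted nodal density
#'
#' The nodal band occupies a membrane annulus of constant axial width
#' `W`, so its area is `A_nodal = 2 pi R W` and the density is
#' `rho = N / (2 pi R W)`. Under the wild-type model rho scales with
#' the total membrane area 2 pi R L; under the T166A model with length.
#'
#' @param N_nodal Nodal amount (a.u.).
#' @param R Cell radius (um).
#' @param W Nodal band width (um).
#' @return Density (a.u. / um^2), vectorized.
#' @export
predicted_density <- function(N_nodal, R, W) {
  stopifnot(all(R > 0), all(W > 0))
  N_nodal / (2 * pi * R * W)
}

#' Mobile nodal fraction
#'
#' FRAP reveals an immobile core in each node; the mobile pool is
#' `(1 - f) N_nodal`. Being a constant factor, it leaves every scaling
#' exponent unchanged.
#'
#' @param N_nodal Nodal amount.
#' @param f Immobile fraction in \[0, 1).
#' @export
apply_mobile_fraction <- function(N_nodal, f) {
  if (f < 0 || f >= 1) stop("immobile fraction f must be in [0, 1)")
  (1 - f) * N_nodal
}

#' Accessible cytoplasmic volume
#'
#' Nucleus and vacuoles occupy a constant fraction of the cell, so the
#' volume accessible to cytoplasmic Cdr2 is `c * V_cell`; volume
#' scaling is preserved.
#'
#' @param V_cell Cell volume (um^3).
#' @param c Accessible fraction in (0, 1\].
#' @export
accessible_volume <- function(V_cell, c) {
  if (c <= 0 || c > 1) stop("accessible-volume fraction c must be in (0, 1]")
  c * V_cell
}

#' Flux-balance residual
#'
#' Influx minus efflux at a candidate nodal amount; zero (to machine
#' precision) at the steady state returned by [steady_state_nodal()].
#'
#' @param params A [model_params()].
#' @param geom Geometry (see [steady_state_nodal()]).
#' @param N_nodal Candidate nodal amount.
#' @param mode Model mode.
#' @return Influx - lambda * N_nodal.
#' @export
flux_balance_residual <- function(params, geom, N_nodal,
                                  mode = c("general", "wt", "t166a")) {
  mode <- match.arg(mode)
  g <- resolve_geometry(geom)
  influx <- switch(mode,
    general = params$kp * params$Ssp1 * params$Cdr2_u * params$c * g$V +
      params$kb * params$Cdr2_u * g$A,
    wt = params$K * params$c * g$V,
    t166a = params$kb * params$Cdr2 * g$A)
  influx - params$lam * N_nodal
}
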