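---
title: "Geometric size sensing in rod-shaped cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric size sensing in rod-shaped cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodsizer)
```

## The question

Fission yeast grows as a rod of nearly constant radius and divides when
it reaches a threshold size. Because area ($A = 2\pi R L$) and volume
($V \approx \pi R^2 L$) both scale with length in a single strain, the
sensed quantity can only be resolved by comparing strains of different
radii (thin, normal, fat): the strains' size-homeostasis statistics
collapse onto one curve only in the measure the cell actually monitors.
`rodsizer` implements that comparison end to end and, because raw
microscopy for such experiments is rarely portable, ships a synthetic
generator that reproduces the statistical structure the analysis
assumes, so every stage is testable from code alone.

## Cell geometry

A cell is a spherocylinder: a cylinder of length $L - 2R$ capped by two
hemispheres, giving the closed forms

$$A = 2\pi R L, \qquad V = \pi R^2 (L - 2R/3).$$

From a segmented contour the package computes geometry three ways:

1. **Rotation** (`geometry_by_rotation`): the radius profile $R(x)$
   along the PCA symmetry axis is revolved, $A = \int 2\pi R
   \sqrt{1+R'^2}\,dx$, $V = \int \pi R^2 dx$ — no shape assumption
   beyond axial symmetry. Quadrature is trapezoidal with central
   differences for $R'$; on exact profiles it agrees with the closed
   forms to better than 0.5%, which the tests assert.
2. **Single-cell radius** (`cell_geometry`): the closed forms with the
   cell's own mid-zone mean radius. The mid-zone excludes one
   cap-length from each pole so the hemispheres do not bias the mean
   downward; the cap length is estimated as the 90th percentile of the
   profile radii.
3. **Population radius** (`population_mean_radius`): every cell of a
   strain is assigned the strain-mean radius. Strain-level plots
   default to this methodology; per-cell radius binning (the log-log
   division fits) uses methodology 2.

The axis comes from exact polygon moments (Green's theorem), the
continuum limit of PCA over interior points; a contour whose principal
axes differ by less than 5% has no defined axis and is rejected. The
profile is binned at `max(0.1, L/100)` um — the paper trail behind the
contour format does not fix a sampling density, so both the bin width
and the contour vertex count are exposed as arguments.

## The synthetic generator and what it does (not) emulate

`simulate_lineages` grows each lineage linearly in length at constant
radius and divides it when its rule's threshold is crossed. Defaults
are the study conditions: multiplicative lognormal threshold noise with
CV 7.5% (the division-size CV reported for wild-type-like sizing),
Gaussian asymmetry noise of SD 2% on the halving fraction, radius CV 3%
across cells, growth 0.03 um/min (about 2 um/h, a typical interphase
elongation rate; size-vs-size analyses are insensitive to it). Radius
presets are 1.5 / 1.876 / 2.2 um: the middle value is implied by a
division area of 165 um^2 at length 14 um; the flanking values are
plausible thin/fat stand-ins, not measured values, and every analysis
treats radius as a free parameter. Division rules cover length, area,
exact and cylinder volume, the generalized measure $R^\gamma L$, adder
and timer controls, and a `competing` rule that divides at the first
threshold reached (the length-to-volume crossover construction).

For sizer rules division size is independent of birth size, so the
stationary distribution is reached in one generation; adder and timer
rules iterate eight burn-in generations. `perfect_sizer = TRUE` records
divisions exactly at the noiseless threshold while births keep the
inherited noise — the limit in which the homeostasis slope is exactly
$-1$, used to calibrate the slope machinery.

`render_cell` draws the z-sum and midplane images of one cell: constant
cytoplasmic and membrane backgrounds inside the mask plus a medial
Gaussian band of axial SD $W/4$ whose integral is the steady-state
nodal amount, and a nucleus occupying a constant midplane-area
fraction (8%, the usual nuclear/cell volume ratio). It deliberately
omits photophysics: no PSF convolution, no shot noise, no 3D stack
(the z-sum is generated directly), no vacuoles. Passing tests
therefore show the quantification recovers what the model injects, not
that segmentation or deconvolution of real images would succeed.

## Nodal quantification

Masked intensities are summed into axial bins and reported as a
density (a.u./um), so the profile integral equals total masked
intensity exactly. The nodal peak is fit as
$I(x) = b + a\,e^{-(x-m)^2/2\sigma^2}$ by Levenberg–Marquardt, started
from the argmax of a 5-point running mean, $\sigma$ from the FWHM,
baseline at the profile median, with $\sigma$ bounded positive; for
multi-peak profiles this start selects the largest peak. A fit whose
amplitude is below twice the residual SD is a "no-peak" error. The
nodal width is $W = 4\sigma$; the nodal intensity $N$ integrates the
profile over $m \pm 2\sigma$ (so a pure Gaussian yields 95.45% of its
mass); the nodal density is $\rho = N / (2\pi R W)$.

Two ambiguities are resolved as follows and exposed as switches.
Baseline subtraction defaults to **on** ($N$ is nodal-specific signal);
off adds a term proportional to the constant $W$, leaving every scaling
conclusion unchanged. The cytoplasmic mean excludes the nucleus and,
by default, also the nodal zone — excluding only the nucleus is the
narrower reading, and the difference is a constant offset. Rendered
cells are fit over the cylindrical mid-zone only, because under the
caps the projected background follows the cap geometry rather than a
flat baseline.

## The steady-state scaling model

Cytoplasmic unphosphorylated Cdr2 either gets phosphorylated by
cytoplasmic Ssp1 (flux $\propto$ volume) or binds the membrane
directly (flux $\propto$ area); nodal Cdr2 dissociates at rate
$\lambda$. At steady state

$$k_p[\mathrm{Ssp1}][\mathrm{Cdr2_u}]\,V + k_b[\mathrm{Cdr2_u}]\,A
  = \lambda N_{nodal}.$$

With fast phosphorylation and constant concentrations this collapses
to $K V = \lambda N$ (wild type, volume scaling); removing
phosphorylation ($k_p = 0$, the T166A limit) leaves
$k_b[\mathrm{Cdr2}] A = \lambda N$ (area scaling). Dividing by the
nodal area $2\pi R W$ (constant $W$) converts these to density
scalings: $\rho \propto RL \propto A$ (wild type) and $\rho \propto L$
(T166A). Steady state is justified by nodal turnover being much faster
than the cell cycle, so the closed form is the implementation; the
relaxation ODE exists only as a test oracle. An immobile nodal
fraction $f$ and an accessible-volume fraction $c$ (nucleus, vacuoles)
enter as constant factors and provably change no exponent.

When given $(L, R)$ the model uses the rod forms $A = 2\pi R L$,
$V = \pi R^2 L$: in these variables the predicted scalings are exact
algebraic identities, which is how the predictions are stated and
tested. Measured (exact spherocylinder) volumes can always be passed
explicitly. Units throughout are effective fluorescence units — only
scalings, never absolute amounts, are meaningful.

## Discrimination statistics

**Homeostasis slope.** Increment from birth to division against birth
size, binned (default 10 equal-width bins over the central 95%, bins
under 5 points merged into their nearest neighbour) and fit by
ordinary least squares on the bin means (the binned regression is
unweighted; a `weighted` switch exists). Slope $-1$ diagnoses a sizer,
$0$ an adder or a timer under linear growth.

**Normalized RMSD.** The three strain regression lines are evaluated
at 20 equally spaced points on their common range; the three pairwise
RMSDs are summed and divided by the mean of all $3 \times 20$ line
values. Taking the mean over the lines' own evaluation points keeps
the statistic self-contained and scale-invariant. Measures in which
the strains share no x range are reported as `NA` — they cannot be the
sensed measure. The Monte-Carlo p value samples slope/intercept
jointly from each line's fitted covariance (default 10,000 draws,
common random numbers across setups) and compares the two RMSD
samples by t test; no multiple-testing correction is applied.

**Exponent scans.** `gamma_scan` repeats the RMSD analysis over
$R^\gamma L$ for $\gamma \in [0, 3]$ (step 0.01): $\gamma = 0$ is
length, $1$ area, and $\approx 1.75$ the effective exponent of
spherocylinder volume, since $V \approx \pi (R^\gamma L)^{2/\gamma}$.
`alpha_beta_scan` fits a nodal quantity as
$Q = a R^\alpha L + b$ over $\alpha \in [-1, 3]$ (step 0.05) with
$\beta = 1$: only the ratio $\alpha/\beta$ is identifiable, so
$\beta$ is a gauge choice. Data spanning a single radius leave
$\alpha$ unidentifiable and trigger a warning.

**Division geometry.** Binned $\log L_{div}$ vs $\log R$ is fit under
fixed-slope hypotheses — flat (length), $-1$ (area, intercept
$\log(A_{div}/2\pi)$), $-2$ (cylinder volume, intercept
$\log(V_{div}/\pi)$) — a free-slope line, or a continuous crossover
(flat then $-2$, $L^* = V^*/\pi R^{*2}$, $R^*$ grid-searched over bin
positions). Fits weight bins by $1/\mathrm{SE}^2$;
$\chi^2 = \sum((y - \hat y)/\mathrm{SE})^2$ with dof = bins −
parameters and an upper-tail p value. Under the generating model the
tests verify $\mathrm{E}[\chi^2/\mathrm{dof}] \approx 1$ over 200
replicates.

**Segmented homeostasis.** Two-regime fits place the break either at
60% of the mean division size or by grid search over birth-size
quantiles minimizing total SSE of two independent lines. Continuity at
the break is *not* enforced by default — the break marks a regime
change, not necessarily a kink on one curve — and both behaviours are
available.

## Numerical and design notes

* Determinism: every stochastic stage takes a seed; the pipeline
  derives per-stage seeds from the run seed, and identical configs
  give byte-identical summary JSON.
* The division-size CV is the population (1/n-divisor) statistic.
* Degenerate inputs error early with specific messages: non-rod
  `L <= 2R`, near-circular contours, empty masks, unreachable
  thresholds, bands outside the profile support, zero-variance
  regressions.
* Problem sizes in the tests and the acceptance script — 1,000-cell
  strains, 500 per strain for scans, 400 per strain through the
  contour pipeline, 200 replicates for the $\chi^2$ calibration — are
  chosen so each statistic's sampling error is well inside the band it
  is checked against.

## Worked example

```{r example}
rule <- division_rule("area", 165)
strains <- list(
  thin   = strain_config("thin",   1.5,   rule, threshold_cv = 0.05),
  normal = strain_config("normal", 1.876, rule, threshold_cv = 0.05),
  fat    = strain_config("fat",    2.2,   rule, threshold_cv = 0.05))
records <- lapply(seq_along(strains), function(i)
  simulate_lineages(strains[[i]], 500, seed = 10 + i))

# per-strain sizer slope in the generating measure
homeostasis_fit(records[[2]], "area")

# which exponent collapses the three strains?
gamma_scan(records)
```

## Limitations

The generator's noise structure (lognormal threshold, Gaussian
asymmetry, constant radius within a cycle) is the simplest model
consistent with the reported division-size CV; real lineages carry
correlated noise, septum-position biases and segmentation artifacts
that are out of scope. The renderer omits optics, so absolute
intensity calibration is untested. The exponent scans assume the
strain families differ only in radius; confounds such as growth-rate
or expression differences between real mutants are not modelled.
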