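---
title: "Survival-yield thermokinetics of non-covalent protein oligomers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-yield thermokinetics of non-covalent protein oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itemfive)
```

## The experiment this package models

In an ITEM-type (Intact Transition Epitope Mapping) tandem native MS
experiment a non-covalent protein complex — here the homo-trimer of a
27-residue trimerization domain and its engineered variants — is
electrosprayed intact, one charge state of the complex is mass-selected, and
the collision cell voltage difference (dCV) is raised stepwise, e.g. over
the schedule 0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50 V.  At each step the
surviving complex ("educt", the trimer 5+ ion) and the dissociation
products (dimer 3+, monomer 2+) are quantified from the centroided peak
list, and the normalized educt fraction — the *survival yield* (SY) — is
plotted against dCV.  The resulting sigmoid is the central observable: its
midpoint dCV50 is the voltage at which half of the complex population has
dissociated, and its shape carries the apparent kinetics of dissociation.

The package covers the complete chain:

1. **peptide masses** (`parse_sequence()`, `monoisotopic_mass()`,
   `oligomer_mz()`): monoisotopic masses and multiply protonated n-mer m/z
   values for sequences containing D-amino acids (lowercase letters,
   mass-neutral) and non-natural residues (`{Nal}`, `{Dip}`), with free-acid
   or amidated C-termini;
2. **spectra** (`read_peaklist()`, `extract_target_intensity()`,
   `normalize_species()`): target-ion extraction within a +/- 0.5 Da window
   and normalization of all monitored species to 100 %;
3. **survival yield** (`assemble_curve()`, `fit_boltzmann()`): replicate
   averaging and sigmoid fitting;
4. **thermokinetics** (`analyze_thermokinetics()`): tangent sampling,
   voltage-to-temperature transform, Arrhenius and Ellingham fits,
   extrapolation to ambient temperature;
5. **ion mobility** (`fit_calibration()`, `apply_calibration()`):
   travelling-wave CCS calibration against published calibrant values;
6. **structure metrics** (`classify_contacts()`, `ca_distance_stats()`,
   `sasa()`): interface contact classification, interchain C-alpha
   distances and solvent-accessible surface areas of trimer coordinates;
7. **synthetic data** (`generate_dissociation_series()` and friends):
   ground-truthed simulated inputs for every stage.

## The model

The educt decay is fitted with the four-parameter Boltzmann sigmoid

$$ y(x) = A_2 + \frac{A_1 - A_2}{1 + e^{(x - x_0)/dx}} $$

where $A_1$ and $A_2$ are the initial and final plateaus (percent), $x_0$
is the midpoint voltage (dCV50) and $dx > 0$ the width.  Plateaus are
fitted free by default because sodium-adduct satellites and residual
signals shift them away from 100/0 in real spectra; `pin_plateaus = TRUE`
fixes them.  The analytic tangent at the midpoint has slope
$(A_2 - A_1)/(4\,dx)$ and passes through $(x_0, (A_1+A_2)/2)$; the
downstream analysis samples `n_points` evenly spaced voltages on this
tangent between configurable survival-yield bounds.

Each sampled survival yield $s \in (0, 1)$ is converted to a dimensionless
apparent rate constant of quasi-first-order decay over the fixed residence
interval in the collision cell,

$$ k^\# = -\ln s, $$

and each voltage to an effective collision temperature through the
center-of-mass collision energy,

$$ T_{coll} = T_{amb} + \frac{z e\,\Delta CV\; m_{gas}/(m_{gas}+m_{ion})}{f\,k_B}, $$

with $z$ the precursor charge, $m_{gas}$ the collision gas mass (argon by
default for a trap-cell CID) and $f$ the effective degrees-of-freedom
divisor (`dof_factor`).  The Eyring form then gives an apparent activation
free energy $\Delta G^\#(T) = -R T \ln(k^\# h / k_B T)$.  A least-squares
line of $\ln k^\#$ against $1/T$ (Arrhenius) yields $\ln A$ and $E_a$; a
line of $\Delta G^\#$ against $T$ (Ellingham) yields the apparent
activation enthalpy $\Delta H^\#$ (intercept) and entropy $\Delta S^\#$
(negative slope).  Evaluating both lines at $T_{amb}$ — dissociation
without external energy contributions — produces the reported constants
$k^\#_{m0g}$, $K_D^{\#}{}_{m0g} = e^{-\Delta G^\#/RT_{amb}}$,
$\Delta G^\#_{m0g}$, $\Delta H^\#_{m0g}$ and $T_{amb}\Delta S^\#_{m0g}$,
which satisfy $\Delta G = \Delta H - T\Delta S$ exactly by construction.

```{r}
cv  <- c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50)
crv <- sy_curve(cv, boltzmann(cv, 100, 0, 13.5, 1.2))
fit <- fit_boltzmann(crv)
cond <- collision_conditions(z = 5, ion_mass = 3 * monoisotopic_mass(
  foldon_sequences()[["foldon0"]]), T_amb = 295)
analyze_thermokinetics(fit, cond)
```

## Parameters that matter, and their defaults

* **Extraction tolerance** (`tolerance`, u/charge): 0.5, i.e. the
  +/- 0.5 Da convention; the window is *closed*, so a peak exactly on the
  boundary is counted.
* **Target set**: trimer 5+ educt, dimer 3+ and monomer 2+ products, at the
  m/z values computed from the sequence; both the species set and the m/z
  values (e.g. observed centroids) are overridable in `target_ion_set()`.
* **Ambient temperature** (`T_amb`, K): 298.15 by default.  The worked
  reproduction of published constants pins 295 K, the value at which the
  published $k^\#$, $K_D^\#$ and $\Delta G^\#$ columns are mutually
  consistent under the Eyring relation.
* **Collision gas** (`gas_mass`, u): argon, 39.948 (trap-cell CID on the
  relevant instrument family); set 28.0134 for nitrogen.
* **Degrees-of-freedom divisor** (`dof_factor`, dimensionless): 1, meaning
  the full single-collision center-of-mass energy is converted to an
  effective temperature rise.  This is the package's largest lever: the
  *absolute* scale of the extrapolated constants depends directly on it
  (and on the tangent-sampling window), while *relative* comparisons
  between analytes measured under identical settings are insensitive to
  it.  Published absolute values obtained with a different (undisclosed)
  coefficient set will generally not be reproduced digit-for-digit by the
  default; every constant lives in `collision_conditions()` precisely so a
  known coefficient set can be dropped in without code changes.
* **Tangent sampling** (`n_points`, `sy_bounds`): 5 points between 10 % and
  90 % survival.  Because $\ln(-\ln s)$ is curved in $s$, the width of the
  window controls how collinear the derived Arrhenius/Ellingham points
  are: at the default 10–90 % window the oracle-computed $R^2$ values are
  0.989 (Arrhenius) and 0.997 (Ellingham); an interior 25–75 % window
  gives $\ge 0.998$ and $\ge 0.9998$.  Estimates should be (and in the
  test suite are) checked for insensitivity to `n_points`.

## The voltage-to-temperature transform and its assumptions

Treating the center-of-mass collision energy as a thermal bath temperature
is the standard effective-temperature shortcut of survival-yield methods;
it ignores the number of activating collisions, the internal
degree-of-freedom count of a 1299-atom trimer, and radiative/collisional
cooling.  The resulting constants are therefore *apparent* and
*pseudo-thermodynamic*: they are meaningful for ranking complexes measured
on one instrument under one parameterization, not as transferable absolute
gas-phase quantities.  This is also why the package reports the full
resolved constant set alongside every result bundle (`conditions.tsv`).

## What the synthetic generator emulates — and what it does not

`generate_dissociation_series()` reproduces the *structure* of the
experiment: the 11-step voltage schedule, two independent replicate series,
Boltzmann-shaped educt decay with complementary product rise (dimer share
peaking mid-curve, monomer dominating late), Gaussian peak clusters at the
calculated m/z positions, and Gaussian noise on the normalized educt
fraction (default sd 1 %, consistent with sigmoid fits of $R^2 \ge 0.99$;
noise is applied to the normalized fractions because those are the analyzed
quantity).  Every dataset carries a machine-readable truth manifest.

It deliberately does **not** simulate isotope patterns, adduct satellites,
charge stripping, detector saturation, drifting baselines or profile-mode
peak shapes.  Passing the recovery tests therefore demonstrates that the
analysis chain is correct and unbiased on data matching its model
assumptions — it does not certify robustness against instrument artifacts,
which must be handled upstream (e.g. via `denoise_baseline()` and observed
centroid overrides).

## Numerical choices

* Boltzmann fitting uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  initialization $A_1 = \max y$, $A_2 = \min y$ (swapped for rising data),
  $x_0$ at the point nearest the mid-level, $dx$ = voltage range / 10.
  Fits are re-expressed canonically with $dx > 0$.  Non-convergence is an
  error that reports the initializer used.
* Tangent-sampled survival yields are clipped to $(10^{-9}, 100 - 10^{-9})$
  percent so logarithms stay finite.
* `denoise_baseline()` removes intensities $\le$ threshold in absolute mode
  but uses *strict* removal in percentile mode, so a flat spectrum is not
  annihilated by its own median.
* Drift-profile FWHM is obtained by linear interpolation of the
  half-maximum crossings; a single-bin profile reports one grid spacing.
* SASA uses the Shrake–Rupley construction with a deterministic
  golden-section spiral of 960 points per atom (2000 in the analytic-sphere
  checks), probe radius 1.4 A, and Bondi-style radii (C 1.70, N 1.55,
  O 1.52, S 1.80, H 1.20, P 1.80 A).  Quadrature error on an isolated
  sphere is below 0.1 %.
* Contact classification counts unique unordered atom pairs; pairs within
  one residue, and same-chain pairs of directly neighboring residues, are
  excluded as bonded/1-3 neighborhoods (coordinate files carry no bond
  topology).  Hydrogen bonds are heavy-atom N/O pairs within 3.5 A without
  an angle term, since the relevant crystal structures lack hydrogens.
  Salt bridges pair Asp/Glu carboxylate oxygens (and OXT) with Arg/Lys/His
  basic nitrogens within 4.0 A.
* Chains are matched position-by-position after renumbering each chain from
  its first resolved residue; insertion codes are unsupported.

## Design choices where the design was open

* **Free vs pinned plateaus**: free by default (adducts shift plateaus), the
  pinned variant is one flag.
* **Closed tolerance window**: "+/- 0.5 Da" is read as inclusive; with
  centroided data the boundary case is measure-zero but must be
  deterministic.
* **Contact-count validation is qualitative.**  Published per-type interface
  counts from third-party tools depend on undisclosed per-type cutoffs;
  this package fixes its own documented criteria and validates the
  classifier against an exhaustive brute-force oracle instead of chasing a
  foreign tool's exact totals.
* **Interface metrics need user-supplied coordinates.**  No coordinate
  files are redistributed; `read_structure()` takes local PDB paths, and
  the reproduction checks for the deposited trimer entries activate when
  the files are placed in `inst/extdata/`.

## Problem sizes used in the shipped tests

Eleven-point curves with two replicates; recovery ensembles of 100 seeds at
2 % noise (midpoint recovered within 0.3 V in ≥ 95/100 series, median
error ~0.05 V); ten-point calibrant tables at 2 % noise (exponent within
5 %); synthetic trimers of 4–27 residues per chain; SASA quadrature up to
2000 points per atom.  These sizes were chosen so the complete suite and
the reproduction script each run in well under a minute on one core while
keeping every statistical assertion comfortably powered.

## Known limitations

* Absolute extrapolated constants are parameterization- and
  instrument-dependent (see above); only within-configuration differences
  between analytes should be interpreted.
* Single-sigmoid model only: multi-step dissociation (double sigmoids) and
  product-ion rise curves are out of scope.
* Peak lists must be centroided; there is no profile-mode peak picking,
  charge deconvolution or isotope-cluster fitting.
* The travelling-wave calibration is empirical (log-log or linear dialect);
  no first-principles Mason–Schamp inversion is attempted.
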