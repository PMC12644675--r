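#' Collision conditions and physical constants
#'
#' Bundles everything the voltage-to-temperature transform and the
#' Eyring-type free-energy expressions need: precursor charge and mass,
#' collision gas, ambient temperature, the effective degrees-of-freedom
#' divisor, and the physical constants themselves.  All constants are
#' explicit fields so a pipeline run can be made to agree digit-for-digit
#' with any published coefficient set without code changes, and so the
#' resolved configuration can be dumped for audit.
#'
#' @param z precursor charge state (protons).
#' @param ion_mass neutral n-mer mass in u.
#' @param gas_mass collision gas mass in u; default argon (39.948), the trap
#'   cell gas of the Synapt instrument family; set 28.0134 for nitrogen.
#' @param T_amb ambient temperature in K (default 298.15).
#' @param dof_factor dimensionless divisor distributing the center-of-mass
#'   collision energy over effective internal degrees of freedom; default 1
#'   (the full single-collision center-of-mass energy heats the ion).
#' @param e,k_B,h,R elementary charge (C), Boltzmann constant (J/K), Planck
#'   constant (J s), molar gas constant (J/(mol K)); 2019 SI exact values.
#' @return list of class `collision_conditions`.
#' @examples
#' collision_conditions(z = 5, ion_mass = 3 * 3079.58)
#' @export
collision_conditions <- function(z, ion_mass,
                                 gas_mass = 39.948,
                                 T_amb = 298.15,
                                 dof_factor = 1,
                                 e = 1.602176634e-19,
                                 k_B = 1.380649e-23,
                                 h = 6.62607015e-34,
                                 R = 8.31446261815324) {
  vals <- list(z = z, ion_mass = ion_mass, gas_mass = gas_mass,
               T_amb = T_amb, dof_factor = dof_factor,
               e = e, k_B = k_B, h = h, R = R)
  if (any(vapply(vals, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all collision condition fields must be positive numbers")
  structure(vals, class = "collision_conditions")
}

#' @export
print.collision_conditions <- function(x, ...) {
  cat(sprintf(
    "<collision_conditions> z = %g, ion %.1f u, gas %.3f u, T_amb = %.2f K, dof_factor = %g\n",
    x$z, x$ion_mass, x$gas_mass, x$T_amb, x$dof_factor))
  invisible(x)
}

#' Effective collision temperature from the collision voltage step
#'
#' Converts the acceleration voltage offset to an effective reaction
#' temperature via the center-of-mass collision energy:
#' \deqn{T_{coll} = T_{amb} + \frac{z e \,\Delta CV \; m_{gas}/(m_{gas}+m_{ion})}
#'   {f \, k_B}}
#' with `f` the effective degrees-of-freedom divisor.  The transform is
#' affine and strictly increasing in the voltage.
#'
#' @param delta_cv collision voltage difference(s) in V, non-negative.
#' @param cond a [collision_conditions()].
#' @return effective temperature(s) in K.
#' @export
dcv_to_temperature <- function(delta_cv, cond) {
  stopifnot(inherits(cond, "collision_conditions"))
  if (any(delta_cv < 0)) stop("delta_cv must be >= 0")
  frac <- cond$gas_mass / (cond$gas_mass + cond$ion_mass)
  cond$T_amb + cond$z * cond$e * delta_cv * frac / (cond$dof_factor * cond$k_B)
}

#' Apparent dissociation rate constant from the survival yield
#'
#' Quasi-first-order decay over the fixed (unitless) residence interval in
#' the collision cell: `k# = -ln(SY)` for SY as a fraction in (0, 1].
#' `k#` is dimensionless, zero at full survival and strictly decreasing in SY.
#'
#' @param sy survival yield fraction(s) in (0, 1]; values must be clipped
#'   away from 0 upstream (see [sample_tangent()]).
#' @return dimensionless apparent rate constant(s).
#' @export
rate_from_survival <- function(sy) {
  if (any(sy <= 0)) stop("survival yield must be > 0 (clip upstream)")
  if (any(sy > 1)) stop("survival yield must be <= 1 (fraction, not percent)")
  -log(sy)
}

#' Eyring-form apparent activation free energy
#'
#' \deqn{\Delta G^\# (T) = -R T \ln\left(\frac{k^\# h}{k_B T}\right)}
#' in kJ/mol.  `k# = k_B T / h` corresponds to a vanishing barrier.
#'
#' @param k_sharp dimensionless apparent rate constant(s), > 0.
#' @param T_coll temperature(s) in K.
#' @param cond a [collision_conditions()] providing the constants.
#' @return activation free energy in kJ/mol.
#' @export
free_energy_from_rate <- function(k_sharp, T_coll, cond) {
  stopifnot(inherits(cond, "collision_conditions"))
  if (any(k_sharp <= 0)) stop("k_sharp must be > 0 (infinite barrier at 0)")
  if (any(T_coll <= 0)) stop("temperature must be > 0")
  -cond$R * T_coll * log(k_sharp * cond$h / (cond$k_B * T_coll)) / 1000
}

# R^2 without summary.lm (which warns on numerically perfect fits);
# a zero-variance response is a perfect fit by convention.
.lm_r2 <- function(m, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::resid(m)^2) / sst
}

#' Arrhenius fit of apparent rate constants
#'
#' Least squares of `ln k#` against `1/T`: the slope is `-E_a / R`, the
#' intercept `ln A`.
#'
#' @param T_coll temperatures in K (>= 2 distinct values).
#' @param k_sharp apparent rate constants, > 0.
#' @param R molar gas constant (J/(mol K)).
#' @return list of class `arrhenius_fit` with `ln_A`, `E_a` (kJ/mol),
#'   `r_squared`.
#' @export
fit_arrhenius <- function(T_coll, k_sharp, R = 8.31446261815324) {
  if (length(T_coll) != length(k_sharp)) stop("length mismatch")
  if (length(unique(T_coll)) < 2)
    stop("need >= 2 distinct temperatures (singular design)")
  if (any(k_sharp <= 0)) stop("k_sharp must be > 0")
  m <- stats::lm(log(k_sharp) ~ I(1 / T_coll))
  co <- stats::coef(m)
  structure(list(ln_A = unname(co[1]),
                 E_a = -unname(co[2]) * R / 1000,
                 r_squared = .lm_r2(m, log(k_sharp)),
                 n = length(T_coll)),
            class = "arrhenius_fit")
}

#' Ellingham fit of activation free energies
#'
#' Least squares of `dG#` against `T`: the intercept is the apparent
#' activation enthalpy `dH#`, the slope is `-dS#`, so that
#' `dG(T) = dH - T dS` reproduces the fitted line exactly.
#'
#' @param T_coll temperatures in K (>= 2 distinct values).
#' @param dG activation free energies in kJ/mol.
#' @return list of class `ellingham_fit` with `dH` (kJ/mol), `dS`
#'   (kJ/(mol K)), `r_squared`.
#' @export
fit_ellingham <- function(T_coll, dG) {
  if (length(T_coll) != length(dG)) stop("length mismatch")
  if (length(unique(T_coll)) < 2)
    stop("need >= 2 distinct temperatures (singular design)")
  m <- stats::lm(dG ~ T_coll)
  co <- stats::coef(m)
  structure(list(dH = unname(co[1]), dS = -unname(co[2]),
                 r_squared = .lm_r2(m, dG), n = length(T_coll)),
            class = "ellingham_fit")
}

#' Extrapolate fitted lines to ambient temperature
#'
#' Evaluates the Arrhenius and Ellingham lines at the ambient temperature,
#' i.e. the condition of complex dissociation without external energy
#' contributions, and returns the apparent kinetic and pseudo-thermodynamic
#' constants:
#' `k#_m0g = exp(ln A - E_a / (R T_amb))`,
#' `dG#_m0g = dH# - T_amb dS#`,
#' `T_amb dS#`, and `K_D#_m0g = exp(-dG#_m0g / (R T_amb))`.
#' By construction `dG = dH - TdS` holds exactly before rounding.
#'
#' @param arr an `arrhenius_fit`.
#' @param ell an `ellingham_fit`.
#' @param cond a [collision_conditions()] (supplies `T_amb` and `R`).
#' @return list of class `thermo_result` with fields `k_m0g`, `KD_m0g`,
#'   `dG_m0g`, `dH_m0g`, `TdS_m0g` (energies in kJ/mol).
#' @export
extrapolate_ambient <- function(arr, ell, cond) {
  stopifnot(inherits(arr, "arrhenius_fit"), inherits(ell, "ellingham_fit"),
            inherits(cond, "collision_conditions"))
  Ta <- cond$T_amb
  k <- exp(arr$ln_A - arr$E_a * 1000 / (cond$R * Ta))
  dG <- ell$dH - Ta * ell$dS
  structure(list(
    k_m0g = k,
    KD_m0g = exp(-dG * 1000 / (cond$R * Ta)),
    dG_m0g = dG,
    dH_m0g = ell$dH,
    TdS_m0g = Ta * ell$dS,
    T_amb = Ta),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result at %.2f K> k# = %.3g, KD# = %.3g, dG# = %.1f, dH# = %.1f, TdS# = %.1f kJ/mol\n",
    x$T_amb, x$k_m0g, x$KD_m0g, x$dG_m0g, x$dH_m0g, x$TdS_m0g))
  invisible(x)
}

#' Full thermokinetic analysis of a fitted survival-yield curve
#'
#' Runs the complete chain from a Boltzmann fit to the ambient-temperature
#' constants: tangent at the midpoint, evenly spaced tangent samples within
#' the survival-yield bounds, voltage-to-temperature transform, apparent
#' rates, Eyring free energies, Arrhenius and Ellingham lines, and the
#' extrapolation to ambient temperature.
#'
#' @param fit a `boltzmann_fit`.
#' @param cond a [collision_conditions()].
#' @param n_points,sy_bounds tangent sampling controls (see
#'   [sample_tangent()]).
#' @return list of class `thermo_analysis` with elements `points` (the
#'   per-sample table: delta_cv, sy, T_coll, k_sharp, dG), `arrhenius`,
#'   `ellingham`, `result` (the ambient extrapolation) and the inputs.
#' @export
analyze_thermokinetics <- function(fit, cond, n_points = 5L, sy_bounds = c(10, 90)) {
  stopifnot(inherits(fit, "boltzmann_fit"))
  line <- tangent_at_midpoint(fit)
  pts <- sample_tangent(fit, line, n_points = n_points, sy_bounds = sy_bounds)
  pts$T_coll <- dcv_to_temperature(pts$delta_cv, cond)
  pts$k_sharp <- rate_from_survival(pts$sy / 100)
  pts$dG <- free_energy_from_rate(pts$k_sharp, pts$T_coll, cond)
  arr <- fit_arrhenius(pts$T_coll, pts$k_sharp, R = cond$R)
  ell <- fit_ellingham(pts$T_coll, pts$dG)
  structure(list(fit = fit, tangent = line, points = pts,
                 arrhenius = arr, ellingham = ell,
                 conditions = cond,
                 result = extrapolate_ambient(arr, ell, cond)),
            class = "thermo_analysis")
}

#' @export
print.thermo_analysis <- function(x, ...) {
  cat("Thermokinetic analysis\n")
  print(x$fit)
  cat(sprintf("  Arrhenius: ln A = %.3f, E_a = %.2f kJ/mol (R^2 = %.5f)\n",
              x$arrhenius$ln_A, x$arrhenius$E_a, x$arrhenius$r_squared))
  cat(sprintf("  Ellingham: dH = %.2f kJ/mol, dS = %.5f kJ/(mol K) (R^2 = %.5f)\n",
              x$ellingham$dH, x$ellingham$dS, x$ellingham$r_squared))
  print(x$result)
  invisible(x)
}
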