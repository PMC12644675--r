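# itemfive

Survival-yield analysis of gas-phase dissociation of non-covalent protein
oligomers by tandem native mass spectrometry.

## What it is for

Protein engineers who modify small oligomerization domains — here the
27-residue trimerization domain of bacteriophage T4 fibritin ("foldon") and
chemically engineered variants carrying D-amino acids, C-terminal amides and
non-natural residues with large aromatic side chains — need a quantitative
readout of how the modifications change the stability of the non-covalent
complex.  In an ITEM-type (Intact Transition Epitope Mapping) experiment the
intact homo-trimer ion is mass-selected and dissociated by stepwise
collision-induced dissociation; the fraction of surviving complex (the
*survival yield*, SY) is tracked against the collision cell voltage
difference (dCV).  `itemfive` turns the exported per-voltage peak lists into
those numbers:

* monoisotopic masses, formulas, atom counts and multiply protonated n-mer
  m/z values from sequence strings with D- (lowercase) and non-natural
  (`{Nal}`, `{Dip}`) residues;
* target-ion extraction (+/- 0.5 Da window) and normalization to 100 % for
  the monitored educt (trimer 5+) and products (dimer 3+, monomer 2+);
* replicate-averaged survival-yield curves and Boltzmann sigmoid fits
  `y(x) = A2 + (A1 - A2)/(1 + exp((x - x0)/dx))`, with the midpoint `x0`
  (dCV50) as the stability observable;
* apparent kinetic and pseudo-thermodynamic constants: tangent sampling at
  the midpoint, the center-of-mass transform
  `T_coll = T_amb + z e dCV (m_gas/(m_gas+m_ion)) / (f k_B)`, the
  dimensionless rate `k# = -ln SY`, Eyring free energies
  `dG#(T) = -RT ln(k# h / k_B T)`, Arrhenius (`ln k#` vs `1/T`) and
  Ellingham (`dG#` vs `T`) lines, and their extrapolation to ambient
  temperature: `k#_m0g`, `KD#_m0g`, `dG#_m0g`, `dH#_m0g`, `T dS#_m0g`;
* travelling-wave ion mobility CCS calibration (corrected drift times,
  log-log power law or linear dialect) and drift-peak statistics;
* trimer interface metrics from PDB coordinates: intra- vs intercatenane
  van der Waals / hydrogen-bond / salt-bridge contacts at documented
  cutoffs, per-position interchain C-alpha distances, and Shrake-Rupley
  solvent-accessible surface areas;
* a fully ground-truthed synthetic-data generator
  (`generate_dissociation_series()`, `generate_calibrant_table()`,
  `generate_symmetric_trimer()`) so every stage is testable end to end.

See the vignette (`vignettes/survival-yield-thermokinetics.Rmd`) for the
model, assumptions, defaults and limitations.

## Worked example

```r
library(itemfive)

# sequence characterization of the seven variants: trimer 5+ m/z, atom counts
mass_table(foldon_sequences(), n_mer = 3, z = 5)
#>      name n_residues monomer_mass atoms_nmer      mz
#> 1 foldon0         27      3079.58       1299 1848.75
#> 2 foldon1         27      3124.65       1332 1875.80
#> 3 foldon2         27      3124.65       1332 1875.80
#> 4 foldon3         26      3067.63       1311 1841.58
#> 5 foldon4         26      3067.63       1311 1841.58
#> 6 foldon5         26      3101.65       1326 1862.00
#> 7 foldon6         26      3127.66       1338 1877.61

# a simulated dissociation series with known truth (dCV50 = 13.5 V), analyzed
# exactly like real exported peak lists
seq0 <- foldon_sequences()[["foldon0"]]
sim  <- generate_dissociation_series(dissociation_series_spec(seq0, seed = 42))
run  <- run_item5(sim$spectra, seq0, analyte = "foldon0",
                  conditions = collision_conditions(
                    z = 5, ion_mass = 3 * monoisotopic_mass(seq0), T_amb = 295))
run
#> ITEM run for 'foldon0' (66 spectra rows)
#> Thermokinetic analysis
#> <boltzmann_fit> A1 = 99.82%, A2 = 0.55%, x0 (dCV50) = 13.464 V, dx = 1.168 V, R^2 = 0.99986
#>   Arrhenius: ln A = 10.968, E_a = 346.92 kJ/mol (R^2 = 0.98877)
#>   Ellingham: dH = 312.99 kJ/mol, dS = -0.18389 kJ/(mol K) (R^2 = 0.99719)
#> <thermo_result at 295.00 K> k# = 2.17e-57, KD# = 9.44e-66, dG# = 367.2, dH# = 313.0, TdS# = -54.2 kJ/mol
```

Reading the output: the fitted midpoint (13.46 V) recovers the simulated
truth (13.5 V) within the replicate noise, and the fit quality matches
experimental practice (R^2 > 0.999).  The dimensionless `m0g` constants are
the Arrhenius/Ellingham lines evaluated at ambient temperature, i.e.
dissociation without external energy input; `dG# = dH# - T dS#` holds by
construction.  Their *absolute* scale depends on the voltage-to-temperature
coefficient set (charge, gas, degrees-of-freedom divisor — all explicit in
`collision_conditions()`), so they are comparable between analytes measured
under one configuration rather than transferable constants; the vignette
discusses this at length.

For real data, replace the simulated spectra with a manifest TSV
(`file`, `delta_cv`, `replicate_id`) pointing at two-column m/z-intensity
text exports, and pass `out_dir =` to persist every intermediate table
(intensities, curve, fit, thermokinetic points, constants, resolved
configuration) as TSV files.

Interface metrics work on any local PDB file:

```r
tri <- generate_symmetric_trimer(n_residues = 27, ca_distance = 4.5)
ca_distance_stats(tri$model)$total_sum   # 364.5 (closed form: 27 x 3 x 4.5)
classify_contacts(tri$model)$summary
sasa(tri$model)$total
```

## Layout

```
R/                 implementation (one file per analysis stage)
tests/testthat/    unit, property and acceptance tests (oracle-driven)
scripts/           acceptance.R reproduction script
vignettes/         methods vignette
inst/extdata/      small plain-text example peak list
```
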