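#' Specification for a synthetic dissociation series
#'
#' Defines the ground truth and acquisition layout for a simulated
#' collision-voltage dissociation experiment.  The defaults are the study
#' conditions of a typical trimer experiment: the 11-step voltage schedule
#' 0-50 V, two independent replicate series, and Gaussian replicate noise of
#' 1 percent on the normalized intensities (commensurate with sigmoid fits
#' of R^2 >= 0.99).
#'
#' @param sequence monomer sequence string or `peptide_sequence`.
#' @param truth named vector with Boltzmann truth `A1`, `A2`, `x0`, `dx`.
#' @param dcv_schedule collision voltage steps (V).
#' @param n_replicates independent measurement series.
#' @param noise_sd Gaussian noise sd on the educt percentage.
#' @param peak_width m/z standard deviation of the simulated Gaussian peak
#'   shapes (u/charge).
#' @param intensity_scale total ion counts per spectrum.
#' @param seed RNG seed; the generator is deterministic per seed.
#' @return list of class `dissociation_series_spec`.
#' @export
dissociation_series_spec <- function(sequence,
                                     truth = c(A1 = 100, A2 = 0, x0 = 13.5, dx = 1.2),
                                     dcv_schedule = c(0, 2, 5, 7, 10, 12, 15, 20, 30, 40, 50),
                                     n_replicates = 2L,
                                     noise_sd = 1,
                                     peak_width = 0.05,
                                     intensity_scale = 1e4,
                                     seed = 1L) {
  stopifnot(all(c("A1", "A2", "x0", "dx") %in% names(truth)),
            truth[["dx"]] > 0, noise_sd >= 0, n_replicates >= 1,
            length(dcv_schedule) >= 3)
  structure(list(sequence = .as_peptide(sequence), truth = truth,
                 dcv_schedule = sort(dcv_schedule),
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd, peak_width = peak_width,
                 intensity_scale = intensity_scale, seed = as.integer(seed)),
            class = "dissociation_series_spec")
}

# Gaussian peak cluster: grid of 17 centroids within +/- 4 sd of the center,
# heights summing exactly to `total` so window extraction is lossless.
.gaussian_peaks <- function(center, total, width) {
  grid <- center + seq(-4, 4, by = 0.5) * width
  g <- exp(-((grid - center)^2) / (2 * width^2))
  data.frame(mz = grid, intensity = total * g / sum(g))
}

#' Generate a synthetic collision-voltage dissociation series
#'
#' Simulates per-voltage peak-list spectra for a trimeric analyte whose educt
#' survival follows a known Boltzmann truth.  At every (replicate, voltage)
#' the educt percentage is the Boltzmann value plus seeded Gaussian noise
#' (clipped to \[0, 100\]); the dissociated remainder is split between the
#' dimer and monomer products with a voltage-dependent share (dimer peaking
#' mid-curve, monomer dominating late).  Peaks are Gaussian clusters centered
#' at the m/z values computed from the sequence, so the whole analysis chain
#' can be scored against the recorded truth.
#'
#' @param spec a [dissociation_series_spec()].
#' @param out_dir optional directory; when given, one two-column peak-list
#'   text file per (replicate, voltage) is written together with
#'   `manifest.tsv` (file, delta_cv, replicate_id) and `truth.tsv` (the
#'   machine-readable ground-truth manifest).  When `NULL` (default) the
#'   spectra are returned in memory.
#' @return list with `spectra` (list of [spectrum()]), `targets` (the
#'   [target_ion_set()] used), `truth` (generator parameters incl. true
#'   `x0`), and, if written, `manifest` with file paths.
#' @examples
#' sim <- generate_dissociation_series(
#'   dissociation_series_spec(foldon_sequences()[["foldon0"]], seed = 7))
#' length(sim$spectra)  # 22 spectra: 11 voltages x 2 replicates
#' @export
generate_dissociation_series <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "dissociation_series_spec"))
  set.seed(spec$seed)
  tr <- spec$truth
  targets <- target_ion_set(spec$sequence)
  sy_true <- boltzmann(spec$dcv_schedule, tr[["A1"]], tr[["A2"]],
                       tr[["x0"]], tr[["dx"]])

  spectra <- list()
  clipped <- 0L; total_pts <- 0L
  for (r in seq_len(spec$n_replicates)) {
    for (k in seq_along(spec$dcv_schedule)) {
      v <- spec$dcv_schedule[k]
      f <- sy_true[k] + stats::rnorm(1, 0, spec$noise_sd)
      total_pts <- total_pts + 1L
      if (f < 0 || f > 100) clipped <- clipped + 1L
      f <- min(max(f, 0), 100)
      rest <- 100 - f
      w_dimer <- 0.5 * exp(-((v - tr[["x0"]])^2) / (8 * tr[["dx"]]^2))
      pct <- c(trimer = f, dimer = rest * w_dimer, monomer = rest * (1 - w_dimer))
      pk <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
        .gaussian_peaks(targets$target_mz[i],
                        pct[[targets$species[i]]] / 100 * spec$intensity_scale,
                        spec$peak_width)
      }))
      pk <- pk[pk$intensity > 0, , drop = FALSE]
      if (nrow(pk) == 0) pk <- data.frame(mz = targets$target_mz[3], intensity = 0)
      spectra[[length(spectra) + 1L]] <-
        spectrum(pk$mz, pk$intensity, delta_cv = v,
                 replicate_id = paste0("r", r))
    }
  }
  if (clipped == total_pts)
    stop("noise_sd so large that every educt point clipped; reduce noise")

  truth <- list(A1 = tr[["A1"]], A2 = tr[["A2"]], x0 = tr[["x0"]], dx = tr[["dx"]],
                noise_sd = spec$noise_sd, n_replicates = spec$n_replicates,
                seed = spec$seed,
                monomer_mass = monoisotopic_mass(spec$sequence))
  out <- list(spectra = spectra, targets = targets, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- data.frame(file = character(), delta_cv = numeric(),
                           replicate_id = character())
    for (s in spectra) {
      fn <- sprintf("peaks_%s_dcv%02g.txt", s$replicate_id, s$delta_cv)
      utils::write.table(s$peaks, file.path(out_dir, fn),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      manifest <- rbind(manifest, data.frame(
        file = fn, delta_cv = s$delta_cv, replicate_id = s$replicate_id))
    }
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tdf <- data.frame(key = names(truth),
                      value = vapply(truth, function(v) format(v, digits = 15),
                                     character(1)))
    utils::write.table(tdf, file.path(out_dir, "truth.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$manifest <- manifest
    out$out_dir <- out_dir
  }
  out
}

#' Generate a synthetic TWIM calibrant table
#'
#' Emulates the shape of a published-CCS calibrant table: corrected drift
#' times spread over a stated range and published cross sections derived
#' from a known power law `ccs' = a * t'^b` with optional relative noise.
#'
#' @param a,b power-law coefficient and exponent (truth).
#' @param n number of calibrant entries (>= 2).
#' @param noise relative standard deviation on the published CCS (0 = exact).
#' @param seed RNG seed.
#' @param drift_range drift-time range sampled, ms.
#' @param gas_mass buffer gas mass, u.
#' @return list with `table` (data.frame: name, z, neutral_mass,
#'   published_ccs, drift_time) and `truth` (list a, b).
#' @export
generate_calibrant_table <- function(a = 280, b = 0.55, n = 8L, noise = 0,
                                     seed = 1L, drift_range = c(2, 12),
                                     gas_mass = 28.0134) {
  if (n < 2) stop("need n >= 2 calibrants")
  set.seed(seed)
  td <- seq(drift_range[1], drift_range[2], length.out = n)
  z <- pmax(1L, round(seq(5, 16, length.out = n)))
  mass <- seq(8500, 66000, length.out = n)
  op_true <- a * td^b
  op <- op_true * (1 + stats::rnorm(n, 0, noise))
  mu <- mass * gas_mass / (mass + gas_mass)
  published <- op * z / sqrt(mu)
  list(table = data.frame(name = paste0("cal", seq_len(n)), z = z,
                          neutral_mass = mass, published_ccs = published,
                          drift_time = td),
       truth = list(a = a, b = b))
}

#' Generate a rotationally symmetric synthetic trimer
#'
#' Builds one synthetic backbone (C-alpha plus a C-beta-like side-chain
#' carbon per residue) and replicates it by 120 and 240 degree rotations
#' about the z axis.  Because the three chains are exact rotations, the
#' three interchain C-alpha distances at every position equal
#' `ring_radius * sqrt(3)` in closed form, which is recorded as ground
#' truth.
#'
#' @param n_residues residues per chain (>= 2).
#' @param ca_distance target interchain C-alpha distance (A); the ring
#'   radius is `ca_distance / sqrt(3)`.
#' @param rise z step between consecutive residues (A).
#' @param twist rotation per residue about z, degrees.
#' @param cb_offset radial offset of the side-chain carbon (A); set 0 to
#'   generate a C-alpha-only model.
#' @return list with `model` (a [structure_model()]) and `truth` (list with
#'   `interchain_ca_distance` and `ca_distance_sum`).
#' @export
generate_symmetric_trimer <- function(n_residues = 27L, ca_distance = 4.5,
                                      rise = 1.5, twist = 10, cb_offset = 1.5) {
  if (n_residues < 2) stop("need >= 2 residues")
  r0 <- ca_distance / sqrt(3)
  ang <- (seq_len(n_residues) - 1) * twist * pi / 180
  zc <- (seq_len(n_residues) - 1) * rise
  chains <- c("A", "B", "C")
  rows <- list()
  for (ci in seq_along(chains)) {
    rot <- (ci - 1) * 2 * pi / 3
    for (i in seq_len(n_residues)) {
      a <- ang[i] + rot
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chains[ci], resno = i, resid = "ALA",
        elety = "CA", elesy = "C",
        x = r0 * cos(a), y = r0 * sin(a), z = zc[i])
      if (cb_offset > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chains[ci], resno = i, resid = "ALA",
          elety = "CB", elesy = "C",
          x = (r0 + cb_offset) * cos(a), y = (r0 + cb_offset) * sin(a), z = zc[i])
      }
    }
  }
  model <- structure_model(do.call(rbind, rows))
  list(model = model,
       truth = list(interchain_ca_distance = ca_distance,
                    ca_distance_sum = 3 * n_residues * ca_distance))
}
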