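.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full dissociation analysis end to end
#'
#' Orchestrates the complete chain for one analyte: target-ion definition
#' from the sequence, per-spectrum intensity extraction and normalization,
#' replicate-averaged survival-yield curve assembly, Boltzmann fit, and the
#' thermokinetic analysis (tangent sampling, voltage-to-temperature
#' transform, Arrhenius/Ellingham fits, ambient extrapolation).  Errors
#' carry the name of the failing stage.
#'
#' @param input either a list of [spectrum()] objects, or a manifest
#'   data.frame with columns `file`, `delta_cv`, `replicate_id`, or the path
#'   to such a manifest TSV (file paths resolved relative to the manifest).
#' @param sequence monomer sequence string or `peptide_sequence`.
#' @param analyte analyte name used in outputs.
#' @param conditions a [collision_conditions()]; by default derived from the
#'   educt target (charge) and sequence (trimer neutral mass) with argon
#'   collision gas.
#' @param targets a [target_ion_set()]; defaults to trimer 5+ educt, dimer
#'   3+ and monomer 2+ products at the calculated m/z values.
#' @param noise_threshold absolute baseline threshold applied before
#'   extraction (default 0 = off).
#' @param educt_label species treated as the surviving complex.
#' @param n_points,sy_bounds tangent sampling controls.
#' @param pin_plateaus,weighted Boltzmann fit options (see
#'   [fit_boltzmann()]).
#' @param out_dir optional output directory: persists the tidy intensity
#'   table, the curve, the fit parameters, the thermokinetic point table,
#'   the final constants and the resolved configuration as TSV files, so the
#'   bundle alone reconstructs every reported number.
#' @return list of class `item5_run` with `analyte`, `targets`,
#'   `intensities`, `curve`, `fit`, `analysis` (a `thermo_analysis`), and
#'   `result`.
#' @examples
#' sim <- generate_dissociation_series(
#'   dissociation_series_spec(foldon_sequences()[["foldon0"]], seed = 42))
#' run <- run_item5(sim$spectra, foldon_sequences()[["foldon0"]])
#' run$fit$x0   # recovered midpoint voltage, close to the 13.5 V truth
#' @export
run_item5 <- function(input, sequence, analyte = "analyte",
                      conditions = NULL, targets = NULL,
                      noise_threshold = 0, educt_label = "trimer",
                      n_points = 5L, sy_bounds = c(10, 90),
                      pin_plateaus = FALSE, weighted = FALSE,
                      out_dir = NULL) {
  seqp <- .stage("parse_sequence", .as_peptide(sequence))
  if (is.null(targets))
    targets <- .stage("target_ion_set", target_ion_set(seqp))

  spectra <- .stage("read_spectra", {
    if (is.character(input) && length(input) == 1L) {
      man <- utils::read.delim(input, stringsAsFactors = FALSE)
      input <- list(manifest = man, dir = dirname(input))
      NULL
    }
    if (is.data.frame(input))
      input <- list(manifest = input, dir = ".")
    if (is.list(input) && !is.null(input$manifest)) {
      man <- input$manifest
      need <- c("file", "delta_cv", "replicate_id")
      if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
      paths <- ifelse(file.exists(man$file), man$file,
                      file.path(input$dir, man$file))
      missing <- !file.exists(paths)
      if (any(missing))
        stop("missing peak list file(s): ",
             paste(sprintf("%s (delta_cv %g, %s)", man$file[missing],
                           man$delta_cv[missing], man$replicate_id[missing]),
                   collapse = ", "))
      mapply(function(p, v, r) read_peaklist(p, delta_cv = v, replicate_id = r),
             paths, man$delta_cv, man$replicate_id, SIMPLIFY = FALSE)
    } else {
      stopifnot(all(vapply(input, inherits, logical(1), "spectrum")))
      input
    }
  })

  if (is.null(conditions)) {
    ed <- targets[targets$role == "educt", , drop = FALSE][1, ]
    conditions <- collision_conditions(
      z = ed$z, ion_mass = ed$n_mer * monoisotopic_mass(seqp))
  }

  intensities <- .stage("normalize_spectra",
                        normalize_spectra(spectra, targets, noise_threshold))
  curve <- .stage("assemble_curve",
                  assemble_curve(intensities, educt_label, analyte = analyte))
  fit <- .stage("fit_boltzmann",
                fit_boltzmann(curve, pin_plateaus = pin_plateaus,
                              weighted = weighted))
  analysis <- .stage("thermokinetics",
                     analyze_thermokinetics(fit, conditions,
                                            n_points = n_points,
                                            sy_bounds = sy_bounds))

  run <- structure(
    list(analyte = analyte, targets = targets, conditions = conditions,
         intensities = intensities, curve = curve, fit = fit,
         analysis = analysis, result = analysis$result),
    class = "item5_run")

  if (!is.null(out_dir)) .stage("write_bundle", .write_bundle(run, out_dir))
  run
}

.write_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(run$targets, "targets.tsv")
  wt(run$intensities, "intensities.tsv")
  wt(as.data.frame(run$curve), "curve.tsv")
  fitdf <- data.frame(analyte = run$analyte, A1 = run$fit$A1, A2 = run$fit$A2,
                      x0 = run$fit$x0, dx = run$fit$dx,
                      r_squared = run$fit$r_squared)
  wt(fitdf, "boltzmann_fit.tsv")
  wt(run$analysis$points, "thermo_points.tsv")
  res <- run$result
  wt(data.frame(analyte = run$analyte, k_m0g = res$k_m0g, KD_m0g = res$KD_m0g,
                dG_m0g = res$dG_m0g, dH_m0g = res$dH_m0g,
                TdS_m0g = res$TdS_m0g, T_amb = res$T_amb),
     "thermo_result.tsv")
  cond <- run$conditions
  wt(data.frame(key = names(unclass(cond)),
                value = vapply(unclass(cond), function(v)
                  format(v, digits = 15), character(1))),
     "conditions.tsv")
  invisible(out_dir)
}

#' @export
print.item5_run <- function(x, ...) {
  cat(sprintf("ITEM run for '%s' (%d spectra rows)\n",
              x$analyte, nrow(x$intensities)))
  print(x$analysis)
  invisible(x)
}

#' Summarize several runs as one constants table
#'
#' @param runs list of `item5_run` objects.
#' @return data.frame with one row per analyte: midpoint voltage, fit
#'   quality, and the ambient-temperature kinetic and pseudo-thermodynamic
#'   constants.
#' @export
summarize_runs <- function(runs) {
  do.call(rbind, lapply(runs, function(r) {
    stopifnot(inherits(r, "item5_run"))
    data.frame(analyte = r$analyte, dcv50 = r$fit$x0, dx = r$fit$dx,
               boltzmann_r2 = r$fit$r_squared,
               k_m0g = r$result$k_m0g, KD_m0g = r$result$KD_m0g,
               dG_m0g = r$result$dG_m0g, dH_m0g = r$result$dH_m0g,
               TdS_m0g = r$result$TdS_m0g)
  }))
}
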