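#' Construct a spectrum object
#'
#' A spectrum is a peak list (centroided m/z-intensity pairs) tagged with the
#' collision cell voltage difference at which it was acquired and a replicate
#' label.  Peaks are stored sorted ascending by m/z.
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param delta_cv collision cell voltage difference (V).
#' @param replicate_id replicate label.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, delta_cv = NA_real_, replicate_id = NA_character_) {
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity")
  if (any(mz <= 0)) stop("m/z values must be strictly positive")
  o <- order(mz)
  structure(
    list(delta_cv = delta_cv,
         replicate_id = replicate_id,
         peaks = data.frame(mz = mz[o], intensity = intensity[o])),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d peaks, delta_cv = %s V, replicate = %s\n",
              nrow(x$peaks), format(x$delta_cv), format(x$replicate_id)))
  invisible(x)
}

#' Read a two-column m/z-intensity peak list
#'
#' Reads plain-text exports of centroided peak lists: two numeric columns
#' (m/z, intensity) separated by whitespace, tabs or commas.  Header lines
#' and other malformed rows are skipped; their count is reported via a
#' message so silent truncation is visible.
#'
#' @param path text file path.
#' @param delta_cv,replicate_id metadata attached to the returned spectrum.
#' @return a [spectrum()] with peaks sorted ascending by m/z.
#' @examples
#' f <- system.file("extdata", "example_peaklist.txt", package = "itemfive")
#' read_peaklist(f, delta_cv = 15, replicate_id = "r1")
#' @export
read_peaklist <- function(path, delta_cv = NA_real_, replicate_id = NA_character_) {
  if (!file.exists(path)) stop("peak list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[,;\t ]+")
  mz <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1])), numeric(1))
  it <- vapply(fields, function(f)
    suppressWarnings(as.numeric(if (length(f) >= 2) f[2] else NA)), numeric(1))
  ok <- is.finite(mz) & is.finite(it) & mz > 0
  n_bad <- sum(!ok)
  if (!any(ok)) stop("no numeric m/z-intensity rows in ", path)
  if (n_bad > 0)
    message(sprintf("read_peaklist: skipped %d malformed line(s) in %s",
                    n_bad, basename(path)))
  spectrum(mz[ok], it[ok], delta_cv = delta_cv, replicate_id = replicate_id)
}

#' Remove baseline/noise peaks from a spectrum
#'
#' In `"absolute"` mode, peaks with intensity at or below `threshold` are
#' removed.  In `"percentile"` mode the cutoff is the given percentile of the
#' peak intensities and removal is strict (`intensity < cutoff`), so ties at
#' the cutoff survive.  The input spectrum is not modified.
#'
#' @param s a [spectrum()].
#' @param threshold non-negative intensity threshold (absolute mode) or
#'   percentile in \[0, 100\] (percentile mode).
#' @param mode `"absolute"` (default) or `"percentile"`.
#' @return a new denoised `spectrum`; warns if every peak was removed.
#' @export
denoise_baseline <- function(s, threshold = 0, mode = c("absolute", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "spectrum"))
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- if (mode == "absolute") {
    s$peaks$intensity > threshold
  } else {
    if (threshold > 100) stop("percentile threshold must be in [0, 100]")
    cutoff <- stats::quantile(s$peaks$intensity, probs = threshold / 100,
                              names = FALSE)
    s$peaks$intensity >= cutoff
  }
  if (!any(keep)) warning("denoise_baseline removed every peak")
  spectrum(s$peaks$mz[keep], s$peaks$intensity[keep],
           delta_cv = s$delta_cv, replicate_id = s$replicate_id)
}

#' Summed intensity of a target ion within a tolerance window
#'
#' Sums the intensities of all peaks with `|mz - target_mz| <= tolerance`.
#' The window is closed: a peak exactly at the boundary is included.  Absence
#' of peaks is data, not an error: the extracted intensity is then 0.
#'
#' @param s a [spectrum()].
#' @param target_mz target ion m/z.
#' @param tolerance half-width of the extraction window in u/charge
#'   (default 0.5, i.e. the +/- 0.5 Da convention).
#' @return summed intensity (0 if no peak lies in the window).
#' @export
extract_target_intensity <- function(s, target_mz, tolerance = 0.5) {
  stopifnot(inherits(s, "spectrum"))
  if (tolerance <= 0) stop("tolerance must be > 0")
  sum(s$peaks$intensity[abs(s$peaks$mz - target_mz) <= tolerance])
}

#' Define the monitored educt/product ion set
#'
#' The default monitoring scheme for a trimeric analyte follows the standard
#' target choice: the surviving complex (educt) is the trimer 5+ ion, the
#' products are the dimer 3+ and monomer 2+ ions.  Target m/z values default
#' to the calculated values from the sequence but can be overridden with
#' observed centroids.
#'
#' @param seq a `peptide_sequence` or sequence string (used to compute the
#'   default target m/z values); ignored if `target_mz` is given.
#' @param species species labels.
#' @param n_mer,z oligomer sizes and charges, parallel to `species`.
#' @param role `"educt"` or `"product"` per species.
#' @param target_mz optional observed m/z values overriding the calculated ones.
#' @param tolerance extraction half-window (u/charge).
#' @return data.frame of class `target_ion_set` with columns `species`,
#'   `n_mer`, `z`, `target_mz`, `tolerance`, `role`.
#' @examples
#' target_ion_set(foldon_sequences()[["foldon0"]])
#' @export
target_ion_set <- function(seq,
                           species = c("trimer", "dimer", "monomer"),
                           n_mer = c(3L, 2L, 1L),
                           z = c(5L, 3L, 2L),
                           role = c("educt", "product", "product"),
                           target_mz = NULL,
                           tolerance = 0.5) {
  stopifnot(length(species) == length(n_mer), length(species) == length(z),
            length(species) == length(role))
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (is.null(target_mz)) {
    p <- .as_peptide(seq)
    target_mz <- mapply(function(n, zz) oligomer_mz(p, n_mer = n, z = zz),
                        n_mer, z)
  }
  out <- data.frame(species = species, n_mer = n_mer, z = z,
                    target_mz = target_mz, tolerance = tolerance, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("target_ion_set", "data.frame")
  out
}

#' Extract all target-ion intensities from a spectrum
#'
#' @param s a [spectrum()].
#' @param targets a [target_ion_set()].
#' @return named numeric vector of raw summed intensities, one per species.
#' @export
extract_species <- function(s, targets) {
  stopifnot(inherits(targets, "target_ion_set"))
  out <- mapply(function(mz, tol) extract_target_intensity(s, mz, tol),
                targets$target_mz, targets$tolerance)
  names(out) <- targets$species
  out
}

#' Normalize species intensities to 100 percent
#'
#' Each species fraction is `100 * intensity / sum(intensities)`.  An all-zero
#' input has no defined fractions; the corresponding curve point must be
#' treated as missing, so this raises an error rather than returning 0/0.
#' Normalization is scale-invariant: multiplying all raw intensities by a
#' positive constant leaves the fractions unchanged.
#'
#' @param raw named numeric vector of non-negative raw intensities.
#' @return named numeric vector of percentages summing to 100.
#' @export
normalize_species <- function(raw) {
  if (is.null(names(raw))) stop("raw intensities must be named by species")
  if (any(raw < 0)) stop("negative intensity")
  tot <- sum(raw)
  if (tot <= 0)
    stop("all target intensities are zero: fraction undefined, flag point as missing")
  100 * raw / tot
}

#' Tidy per-spectrum normalized intensities
#'
#' Applies target extraction and normalization to a list of spectra and
#' returns the tidy long table consumed by [assemble_curve()].  Spectra whose
#' target intensities are all zero are dropped with a warning (missing curve
#' points).
#'
#' @param spectra list of [spectrum()] objects with `delta_cv` and
#'   `replicate_id` set.
#' @param targets a [target_ion_set()].
#' @param noise_threshold optional baseline threshold applied with
#'   [denoise_baseline()] (absolute mode) before extraction.
#' @return data.frame with columns `delta_cv`, `replicate_id`, `species`,
#'   `raw_intensity`, `percent`.
#' @export
normalize_spectra <- function(spectra, targets, noise_threshold = 0) {
  rows <- lapply(spectra, function(s) {
    stopifnot(inherits(s, "spectrum"))
    if (noise_threshold > 0) s <- denoise_baseline(s, noise_threshold)
    raw <- extract_species(s, targets)
    if (sum(raw) <= 0) {
      warning(sprintf(
        "all target intensities zero at delta_cv = %s (replicate %s); point dropped",
        format(s$delta_cv), format(s$replicate_id)))
      return(NULL)
    }
    pct <- normalize_species(raw)
    data.frame(delta_cv = s$delta_cv, replicate_id = s$replicate_id,
               species = names(raw), raw_intensity = unname(raw),
               percent = unname(pct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
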