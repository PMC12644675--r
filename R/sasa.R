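# van der Waals radii (Angstrom) for SASA; a Bondi-style set.
.default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                        H = 1.20, P = 1.80)

# deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); the same point set is used for every atom, so results are exactly
# reproducible for a fixed n.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by the Shrake-Rupley rolling-probe algorithm: each atom is
#' inflated by the probe radius, covered with a deterministic quasi-uniform
#' point set, and the accessible fraction is the share of points not buried
#' inside any neighboring inflated sphere.  Deterministic for a fixed
#' `n_sphere_points`; quadrature error shrinks roughly as 1/n.
#'
#' @param model a [structure_model()].
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points quadrature points per atom (default 960).
#' @param radii named vector of van der Waals radii by element symbol;
#'   defaults cover C, N, O, S, H, P.  An atom whose element has no radius
#'   raises an error naming the atom.
#' @return list of class `sasa_result` with `total` (A^2), `per_atom`
#'   (numeric vector) and `per_residue` (data.frame: chain, resno, resid,
#'   area).
#' @examples
#' one <- structure_model(data.frame(chain = "A", resno = 1, resid = "GLY",
#'   elety = "CA", elesy = "C", x = 0, y = 0, z = 0))
#' sasa(one)$total            # ~ 4*pi*(1.7+1.4)^2
#' @export
sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960L,
                 radii = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  rtab <- .default_vdw_radii
  if (!is.null(radii)) rtab[names(radii)] <- radii
  el <- model$elesy
  unknown <- which(!el %in% names(rtab))
  if (length(unknown) > 0)
    stop(sprintf("no van der Waals radius for element '%s' (atom %s %s%d %s)",
                 el[unknown[1]], model$chain[unknown[1]],
                 model$resid[unknown[1]], model$resno[unknown[1]],
                 model$elety[unknown[1]]))
  r <- unname(rtab[el]) + probe_radius
  xyz <- as.matrix(model[, c("x", "y", "z")])
  n_atoms <- nrow(xyz)
  pts <- .sphere_points(n_sphere_points)

  areas <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & seq_len(n_atoms) != i)
    acc <- rep(TRUE, n_sphere_points)
    if (length(nb) > 0) {
      sp <- pts * r[i]
      sp[, 1] <- sp[, 1] + xyz[i, 1]
      sp[, 2] <- sp[, 2] + xyz[i, 2]
      sp[, 3] <- sp[, 3] + xyz[i, 3]
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > r[j]^2
      }
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_sphere_points
  }

  key <- paste(model$chain, model$resno)
  agg <- stats::aggregate(areas, by = list(key = key), FUN = sum)
  first <- !duplicated(key)
  per_res <- data.frame(chain = model$chain[first], resno = model$resno[first],
                        resid = model$resid[first],
                        area = agg$x[match(key[first], agg$key)])
  structure(list(total = sum(areas), per_atom = areas, per_residue = per_res,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total = %.1f A^2 (%d atoms, %d sphere points, probe %.2f A)\n",
              x$total, length(x$per_atom), x$n_sphere_points, x$probe_radius))
  invisible(x)
}
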